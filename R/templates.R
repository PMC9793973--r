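# Ideal-geometry side-chain templates. Each supported amino acid has a
# small internal-coordinate table (bond / angle / torsion per heavy atom);
# side chains are constructed atom by atom with the NeRF rule, attaching
# at the residue's N/CA/C frame. Torsions are either fixed (ring and
# terminal branches) or a chi variable plus a fixed offset, so a requested
# chi is reproduced exactly by construction. Templates are heavy-atom
# only.

# Columns: atom, tref, aref, parent (reference atom names), bond (A),
# angle (deg), chi (0 = fixed torsion), off (torsion offset, deg).
sc_row <- function(atom, tref, aref, parent, bond, angle, chi, off) {
  data.frame(atom = atom, tref = tref, aref = aref, parent = parent,
             bond = bond, angle = angle, chi = chi, off = off,
             stringsAsFactors = FALSE)
}

# L-amino-acid CB: improper torsion C-N-CA-CB ~ +122.5 deg.
CB_ROW <- sc_row("CB", "C", "N", "CA", 1.530, 110.5, 0, 122.5)

SIDE_CHAIN_TEMPLATES <- list(
  GLY = NULL,
  ALA = CB_ROW,
  SER = rbind(CB_ROW, sc_row("OG", "N", "CA", "CB", 1.417, 110.8, 1, 0)),
  CYS = rbind(CB_ROW, sc_row("SG", "N", "CA", "CB", 1.808, 113.8, 1, 0)),
  THR = rbind(CB_ROW,
              sc_row("OG1", "N", "CA", "CB", 1.433, 109.6, 1, 0),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -120)),
  VAL = rbind(CB_ROW,
              sc_row("CG1", "N", "CA", "CB", 1.521, 110.5, 1, 0),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1, 120)),
  LEU = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.530, 116.3, 1, 0),
              sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, 2, 0),
              sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, 2, 120)),
  ILE = rbind(CB_ROW,
              sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, 1, 0),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -120),
              sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2, 0)),
  ASP = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.516, 112.6, 1, 0),
              sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 2, 0),
              sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 2, 180)),
  ASN = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.516, 112.6, 1, 0),
              sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 2, 0),
              sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 2, 180)),
  GLU = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.530, 114.1, 1, 0),
              sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, 2, 0),
              sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 3, 0),
              sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 3, 180)),
  GLN = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.530, 114.1, 1, 0),
              sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, 2, 0),
              sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 3, 0),
              sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 3, 180)),
  MET = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.530, 114.1, 1, 0),
              sc_row("SD", "CA", "CB", "CG", 1.807, 112.7, 2, 0),
              sc_row("CE", "CB", "CG", "SD", 1.789, 100.9, 3, 0)),
  LYS = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.530, 114.1, 1, 0),
              sc_row("CD", "CA", "CB", "CG", 1.530, 111.3, 2, 0),
              sc_row("CE", "CB", "CG", "CD", 1.530, 111.3, 3, 0),
              sc_row("NZ", "CG", "CD", "CE", 1.489, 111.7, 4, 0)),
  ARG = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.530, 114.1, 1, 0),
              sc_row("CD", "CA", "CB", "CG", 1.530, 111.3, 2, 0),
              sc_row("NE", "CB", "CG", "CD", 1.461, 112.0, 3, 0),
              sc_row("CZ", "CG", "CD", "NE", 1.329, 124.2, 4, 0),
              sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0, 0),
              sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 0, 180)),
  PHE = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.502, 113.8, 1, 0),
              sc_row("CD1", "CA", "CB", "CG", 1.384, 120.8, 2, 0),
              sc_row("CD2", "CA", "CB", "CG", 1.384, 120.8, 2, 180),
              sc_row("CE1", "CB", "CG", "CD1", 1.382, 120.0, 0, 180),
              sc_row("CE2", "CB", "CG", "CD2", 1.382, 120.0, 0, 180),
              sc_row("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0, 0)),
  HIS = rbind(CB_ROW,
              sc_row("CG", "N", "CA", "CB", 1.497, 113.7, 1, 0),
              sc_row("ND1", "CA", "CB", "CG", 1.378, 122.7, 2, 0),
              sc_row("CD2", "CA", "CB", "CG", 1.354, 129.7, 2, 180),
              sc_row("CE1", "CB", "CG", "ND1", 1.321, 109.0, 0, 180),
              sc_row("NE2", "CG", "ND1", "CE1", 1.321, 111.7, 0, 0))
)
SIDE_CHAIN_TEMPLATES$TYR <- rbind(
  SIDE_CHAIN_TEMPLATES$PHE,
  sc_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 0, 180))

# Dihedral quadruple (atom names) defining chi k of an amino acid.
chi_quadruple <- function(aa, k) {
  g <- switch(aa, SER = "OG", CYS = "SG", THR = "OG1", VAL = "CG1",
              ILE = "CG1", "CG")
  quads <- list(c("N", "CA", "CB", g))
  if (CHI_COUNTS[[aa]] >= 2) {
    d <- switch(aa, LEU = "CD1", ILE = "CD1", ASP = "OD1", ASN = "OD1",
                PHE = "CD1", TYR = "CD1", HIS = "ND1", MET = "SD", "CD")
    quads[[2]] <- c("CA", "CB", if (aa == "ILE") "CG1" else "CG", d)
  }
  if (CHI_COUNTS[[aa]] >= 3) {
    e <- switch(aa, MET = "CE", GLU = "OE1", GLN = "OE1", LYS = "CE",
                ARG = "NE")
    quads[[3]] <- c("CB", "CG", if (aa == "MET") "SD" else "CD", e)
  }
  if (CHI_COUNTS[[aa]] >= 4)
    quads[[4]] <- switch(aa, LYS = c("CG", "CD", "CE", "NZ"),
                         ARG = c("CG", "CD", "NE", "CZ"))
  quads[[k]]
}

#' Build a side chain from ideal geometry
#'
#' Constructs the heavy-atom side chain of `aa` on the backbone frame
#' given by the N, CA and C positions, with the supplied chi dihedrals
#' applied exactly.
#'
#' @param aa 3-letter amino-acid code (supported set: see `CHI_COUNTS`).
#' @param N,CA,C Backbone atom positions (3-vectors, Angstrom).
#' @param chis Numeric vector of chi angles in degrees; its length must
#'   equal the amino acid's rotatable-dihedral count.
#' @return data.frame with columns `atom`, `element`, `x`, `y`, `z`
#'   (zero rows for GLY).
#' @export
build_side_chain <- function(aa, N, CA, C, chis = numeric(0)) {
  aa <- toupper(aa)
  if (!aa %in% names(SIDE_CHAIN_TEMPLATES))
    stop("no side-chain template for ", aa)
  if (length(chis) != CHI_COUNTS[[aa]])
    stop(sprintf("%s takes %d chi angles, got %d", aa, CHI_COUNTS[[aa]],
                 length(chis)))
  tmpl <- SIDE_CHAIN_TEMPLATES[[aa]]
  pos <- list(N = N, CA = CA, C = C)
  if (is.null(tmpl))
    return(data.frame(atom = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  for (i in seq_len(nrow(tmpl))) {
    row <- tmpl[i, ]
    tors <- row$off + if (row$chi > 0) chis[row$chi] else 0
    pos[[row$atom]] <- place_atom(pos[[row$tref]], pos[[row$aref]],
                                  pos[[row$parent]], row$bond, row$angle,
                                  tors)
  }
  nm <- tmpl$atom
  xyz <- do.call(rbind, pos[nm])
  data.frame(atom = nm, element = element_from_name(nm),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# Measure chi k from a named coordinate lookup (list name -> 3-vector).
measure_chi <- function(aa, k, coords) {
  q <- chi_quadruple(toupper(aa), k)
  dihedral_angle(coords[[q[1]]], coords[[q[2]]], coords[[q[3]]],
                 coords[[q[4]]])
}
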