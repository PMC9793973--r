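# Atom tables are the package currency: one data.frame row per atom with
# bio3d-style naming (elety = atom name, resid = 3-letter residue code,
# resno = author residue number). Force-field and scoring parameters are
# attached as extra columns so downstream energy code never looks anything
# up.

ATOM_COLS <- c("elety", "elesy", "chain", "resid", "resno",
               "x", "y", "z", "charge", "rmin_half", "epsilon",
               "vdw_radius", "class", "is_h", "backbone")

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA",
                    "HA2", "HA3")

ATOM_CLASSES <- c("hydrophobic", "donor", "acceptor", "none")

new_atom_table <- function(df) {
  miss <- setdiff(ATOM_COLS, names(df))
  if (length(miss) > 0)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  df <- df[, ATOM_COLS]
  rownames(df) <- NULL
  df
}

#' Extract coordinates from an atom table
#' @param atoms Atom table (data.frame).
#' @return n x 3 numeric matrix.
#' @export
atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

set_atom_xyz <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

# Residue key "chain:resno", used wherever residues are identified.
residue_key <- function(chain, resno) paste(chain, resno, sep = ":")

atom_res_key <- function(atoms) residue_key(atoms$chain, atoms$resno)

is_backbone_name <- function(elety) elety %in% BACKBONE_NAMES

element_from_name <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  two <- toupper(substr(e, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
         substr(e, 1, 2), substr(e, 1, 1))
}

#' Protein scaffold
#'
#' Bundles an atom table with its residue order and segment structure. A
#' segment is a run of consecutive residues in one chain with no chain
#' break; residues at segment ends are treated as termini by the static
#' rules.
#'
#' @param atoms Atom table.
#' @return Object of class `scaffold` with elements `atoms` (atom table),
#'   `residues` (data.frame chain/resno/resid, in file order) and
#'   `segment_of` (integer segment id per residue).
#' @export
scaffold <- function(atoms) {
  atoms <- new_atom_table(atoms)
  key <- atom_res_key(atoms)
  ord <- !duplicated(key)
  residues <- data.frame(chain = atoms$chain[ord], resno = atoms$resno[ord],
                         resid = atoms$resid[ord], stringsAsFactors = FALSE)
  if (anyDuplicated(residue_key(residues$chain, residues$resno)))
    stop("duplicate (chain, resno) residue identifiers in scaffold")
  # segment break where the chain changes or numbering is non-consecutive
  n <- nrow(residues)
  brk <- c(FALSE, residues$chain[-1] != residues$chain[-n] |
             residues$resno[-1] != residues$resno[-n] + 1)
  structure(list(atoms = atoms, residues = residues,
                 segment_of = cumsum(c(1L, as.integer(brk[-1])))),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat("scaffold:", nrow(x$residues), "residues,", nrow(x$atoms), "atoms,",
      max(x$segment_of), "segment(s)\n")
  invisible(x)
}

# Index of a residue (row in $residues) by chain/resno; NA if absent.
residue_index <- function(scaf, chain, resno) {
  match(residue_key(chain, resno),
        residue_key(scaf$residues$chain, scaf$residues$resno))
}

# Atom-table rows belonging to residue index i.
residue_atoms <- function(scaf, i) {
  r <- scaf$residues[i, ]
  which(scaf$atoms$chain == r$chain & scaf$atoms$resno == r$resno)
}

#' Nonbonded interaction constants
#'
#' Constants of the packing-track force field: the Coulomb prefactor and
#' the 1-4 scaling factors applied to atom pairs separated by exactly
#' three bonds (AMBER-style defaults).
#'
#' @param coulomb_constant kcal A / (mol e^2).
#' @param lj_14_scale,coulomb_14_scale Dimensionless 1-4 scale factors.
#' @return Object of class `ff_params`.
#' @export
ff_params <- function(coulomb_constant = 332.0636,
                      lj_14_scale = 0.5, coulomb_14_scale = 1 / 1.2) {
  stopifnot(coulomb_constant > 0, lj_14_scale >= 0, coulomb_14_scale >= 0)
  structure(list(coulomb_constant = coulomb_constant,
                 lj_14_scale = lj_14_scale,
                 coulomb_14_scale = coulomb_14_scale),
            class = "ff_params")
}

#' Read a per-atom parameter table
#'
#' Tab-separated file with columns `res atom charge rmin_half epsilon
#' vdw_radius class`; one row per (residue name, atom name). Ligand
#' parameter files use the ligand residue name with atom names in record
#' order (the atom index keys the row through its generated name).
#'
#' @param path Path to the TSV file.
#' @return data.frame keyed by (res, atom).
#' @export
read_param_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("res", "atom", "charge", "rmin_half", "epsilon", "vdw_radius",
            "class")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("parameter table ", path, " missing columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(paste(tab$res, tab$atom)))
    stop("parameter table ", path, " has duplicate (res, atom) rows")
  bad <- !tab$class %in% ATOM_CLASSES
  if (any(bad))
    stop("unknown atom class(es): ", paste(unique(tab$class[bad]),
                                           collapse = ", "))
  if (any(tab$epsilon < 0)) stop("negative Lennard-Jones epsilon in ", path)
  tab
}

# Attach parameters to an atom table; every atom must resolve to exactly
# one row of the table (hard error naming the offender otherwise).
attach_params <- function(atoms, params) {
  idx <- match(paste(atoms$resid, atoms$elety), paste(params$res, params$atom))
  if (anyNA(idx)) {
    k <- which(is.na(idx))[1]
    stop(sprintf("no parameter row for atom %s of residue %s %s%s",
                 atoms$elety[k], atoms$resid[k], atoms$chain[k],
                 atoms$resno[k]))
  }
  atoms$charge <- params$charge[idx]
  atoms$rmin_half <- params$rmin_half[idx]
  atoms$epsilon <- params$epsilon[idx]
  atoms$vdw_radius <- params$vdw_radius[idx]
  atoms$class <- params$class[idx]
  if (any(!atoms$is_h & !(atoms$vdw_radius > 0)))
    stop("heavy atom with non-positive vdw_radius after parameter attachment")
  atoms
}
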