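# Rotamer sampling: measure the backbone conformation at each design
# position, instantiate library chi sets on ideal-geometry templates, and
# prune candidates that clash with the fixed scaffold.

#' Backbone phi/psi dihedrals of a residue
#'
#' phi = C'(i-1)-N-CA-C, psi = N-CA-C-N'(i+1), IUPAC sign convention,
#' degrees in (-180, 180].
#'
#' @param scaf A [scaffold()].
#' @param chain,resno Residue identifier.
#' @return Named numeric vector `c(phi=, psi=)`.
#' @export
backbone_dihedrals <- function(scaf, chain, resno) {
  i <- residue_index(scaf, chain, resno)
  if (is.na(i)) stop("residue not in scaffold: ", residue_key(chain, resno))
  n <- nrow(scaf$residues)
  same_seg <- function(j) j >= 1 && j <= n &&
    scaf$segment_of[j] == scaf$segment_of[i]
  if (!same_seg(i - 1) || !same_seg(i + 1))
    stop("residue ", residue_key(chain, resno),
         " is at a segment terminus; phi/psi undefined")
  bb <- function(j, name) {
    rows <- residue_atoms(scaf, j)
    k <- rows[scaf$atoms$elety[rows] == name]
    if (length(k) != 1) stop("missing backbone atom ", name, " in residue ",
                             residue_key(scaf$residues$chain[j],
                                         scaf$residues$resno[j]))
    as.numeric(scaf$atoms[k, c("x", "y", "z")])
  }
  c(phi = dihedral_angle(bb(i - 1, "C"), bb(i, "N"), bb(i, "CA"), bb(i, "C")),
    psi = dihedral_angle(bb(i, "N"), bb(i, "CA"), bb(i, "C"), bb(i + 1, "N")))
}

#' Build candidate rotamers for one amino acid at one position
#'
#' Looks up the library bin for the position's phi/psi, then constructs
#' one side-chain group per library entry on the position's backbone
#' frame. No minimization is applied; clash relief is delegated to
#' pruning.
#'
#' @param scaf A [scaffold()].
#' @param position A design position (see [select_flexible()]).
#' @param aa 3-letter code to build.
#' @param library A `rotamer_library`.
#' @param params Parameter table (see [read_param_table()]).
#' @return List of rotamers: `list(aa, chis, prob, atoms, frame)`. Empty
#'   (with a warning) when the library has no entries for the bin.
#' @export
build_rotamers <- function(scaf, position, aa, library, params) {
  aa <- toupper(aa)
  entries <- if (CHI_COUNTS[[aa]] == 0) {
    list(list(chis = numeric(0), prob = 1))
  } else {
    pp <- backbone_dihedrals(scaf, position$chain, position$resno)
    library_lookup(library, aa, pp[["phi"]], pp[["psi"]])
  }
  if (length(entries) == 0) {
    warning("library has no ", aa, " entries for bin of ",
            residue_key(position$chain, position$resno))
    return(list())
  }
  i <- residue_index(scaf, position$chain, position$resno)
  rows <- residue_atoms(scaf, i)
  coord <- function(name) {
    k <- rows[scaf$atoms$elety[rows] == name]
    as.numeric(scaf$atoms[k, c("x", "y", "z")])
  }
  frame <- list(N = coord("N"), CA = coord("CA"), C = coord("C"))
  lapply(entries, function(e) {
    sc <- build_side_chain(aa, frame$N, frame$CA, frame$C, e$chis)
    atoms <- if (nrow(sc) == 0) {
      new_atom_table(scaf$atoms[0, ])
    } else {
      attach_params(new_atom_table(data.frame(
        elety = sc$atom, elesy = sc$element,
        chain = position$chain, resid = aa, resno = position$resno,
        x = sc$x, y = sc$y, z = sc$z,
        charge = NA_real_, rmin_half = NA_real_, epsilon = NA_real_,
        vdw_radius = NA_real_, class = "none",
        is_h = FALSE, backbone = FALSE, stringsAsFactors = FALSE)), params)
    }
    list(aa = aa, chis = e$chis, prob = e$prob, atoms = atoms, frame = frame)
  })
}

#' Build the full rotamer set of a pocket
#'
#' Concatenates rotamers over the allowed amino acids of every design
#' position (optionally prepending the native crystal side chain) and
#' prunes against the fixed scaffold.
#'
#' @param pocket A [build_pocket()] result.
#' @param library A `rotamer_library`.
#' @param params Parameter table.
#' @param ff [ff_params()] used for the pruning energy.
#' @param vdw_prune_threshold Scaffold Lennard-Jones threshold in
#'   kcal/mol; candidates at or above it are discarded.
#' @param include_native Keep the crystal-native side-chain conformation
#'   as an extra rotamer (default FALSE: ideal-geometry rebuilds only).
#' @return Object of class `rotamer_set`: per position, `rotamers` (kept,
#'   order preserved), `scaffold_vdw` (their pruning energies) and
#'   `n_pruned`.
#' @export
build_rotamer_set <- function(pocket, library, params, ff = ff_params(),
                              vdw_prune_threshold = 100.0,
                              include_native = FALSE) {
  scaf <- pocket$scaffold
  sets <- vector("list", length(pocket$positions))
  for (k in seq_along(pocket$positions)) {
    p <- pocket$positions[[k]]
    rots <- list()
    if (include_native && nrow(pocket$native_side_chains[[k]]) > 0) {
      rots <- list(list(aa = p$native, chis = numeric(0), prob = NA_real_,
                        atoms = pocket$native_side_chains[[k]],
                        frame = NULL, native = TRUE))
    }
    for (aa in p$allowed_aas)
      rots <- c(rots, build_rotamers(scaf, p, aa, library, params))
    if (length(rots) == 0)
      stop("no rotamers could be built at position ",
           residue_key(p$chain, p$resno))
    vdw <- vapply(rots, function(r)
      scaffold_vdw_energy(r$atoms, pocket$fixed, ff), numeric(1))
    keep <- vdw < vdw_prune_threshold
    if (!any(keep))
      stop("position ", residue_key(p$chain, p$resno),
           " has no viable rotamers (all pruned at threshold ",
           vdw_prune_threshold, " kcal/mol)")
    sets[[k]] <- list(position = p, rotamers = rots[keep],
                      scaffold_vdw = vdw[keep], n_pruned = sum(!keep))
  }
  structure(list(by_position = sets), class = "rotamer_set")
}

#' @export
print.rotamer_set <- function(x, ...) {
  for (s in x$by_position)
    cat(sprintf("  %s:%d  %d rotamer(s) kept, %d pruned\n",
                s$position$chain, s$position$resno, length(s$rotamers),
                s$n_pruned))
  invisible(x)
}

# Lennard-Jones-only interaction of one variable group with the fixed
# scaffold (the pruning energy). Bonded exclusions across the CA/CB cut
# of the group's own residue are applied; groups with no atoms (GLY)
# score zero.
scaffold_vdw_energy <- function(group_atoms, fixed_atoms, ff = ff_params()) {
  if (nrow(group_atoms) == 0) return(0)
  excl <- group_exclusions(group_atoms, fixed_atoms)
  ff_interaction(group_atoms, fixed_atoms, ff, exclusions = excl,
                 terms = "lj")
}
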