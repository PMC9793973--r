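# Pocket definition: which residues are flexible/designable, and the
# partition of the structure into variable side-chain groups and the
# fixed scaffold.

#' Select flexible pocket positions
#'
#' A residue becomes flexible when the minimum distance from any of its
#' side-chain heavy atoms to any ligand heavy atom, or to the CA atom of
#' any mutation position, is at most `radius`. Mutation positions are
#' always flexible (zero distance to their own CA). Static rules
#' ([apply_static_rules()]) are applied afterwards; mutation positions are
#' exempt from removal by distance but not from the static rules.
#'
#' @param scaf A [scaffold()].
#' @param ligand_atoms Ligand atom table placed in the pocket.
#' @param mutations Named list: `"chain:resno"` -> character vector of
#'   allowed 3-letter codes (the native is always added). May be empty.
#' @param radius Selection radius in Angstrom (default 4).
#' @return List of design positions, each
#'   `list(chain, resno, native, allowed_aas, is_mutable)`.
#' @export
select_flexible <- function(scaf, ligand_atoms, mutations = list(),
                            radius = 4.0) {
  stopifnot(inherits(scaf, "scaffold"), radius >= 0)
  res <- scaf$residues
  mut_keys <- names(mutations)
  mut_idx <- match(mut_keys, residue_key(res$chain, res$resno))
  if (anyNA(mut_idx))
    stop("mutation position(s) absent from scaffold: ",
         paste(mut_keys[is.na(mut_idx)], collapse = ", "))
  lig_xyz <- atom_xyz(ligand_atoms[!ligand_atoms$is_h, , drop = FALSE])
  mut_ca <- do.call(rbind, lapply(mut_idx, function(i) {
    rows <- residue_atoms(scaf, i)
    atom_xyz(scaf$atoms[rows[scaf$atoms$elety[rows] == "CA"], , drop = FALSE])
  }))
  targets <- rbind(lig_xyz, mut_ca)
  flex <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    rows <- residue_atoms(scaf, i)
    sc <- rows[!scaf$atoms$backbone[rows] & !scaf$atoms$is_h[rows] &
                 scaf$atoms$elety[rows] != "CA"]
    if (length(sc) == 0) next  # GLY: no side-chain heavy atoms
    flex[i] <- min(cross_dist(atom_xyz(scaf$atoms[sc, , drop = FALSE]),
                              targets)) <= radius
  }
  flex[mut_idx] <- TRUE
  positions <- lapply(which(flex), function(i) {
    key <- residue_key(res$chain[i], res$resno[i])
    muts <- if (key %in% mut_keys) toupper(mutations[[key]]) else character(0)
    list(chain = res$chain[i], resno = res$resno[i], native = res$resid[i],
         allowed_aas = unique(c(res$resid[i], muts)),
         is_mutable = length(setdiff(muts, res$resid[i])) > 0)
  })
  apply_static_rules(positions, scaf)
}

#' Remove statically constrained positions
#'
#' Positions at the ends of protein segments, cysteines in disulfide
#' bridges (SG-SG distance <= 2.3 A) and prolines are removed from the
#' flexible set.
#'
#' @param positions List of design positions (see [select_flexible()]).
#' @param scaf The [scaffold()].
#' @return Filtered position list.
#' @export
apply_static_rules <- function(positions, scaf) {
  if (length(positions) == 0) return(positions)
  seg <- scaf$segment_of
  n <- nrow(scaf$residues)
  first_of_seg <- c(TRUE, seg[-1] != seg[-n])
  last_of_seg <- c(seg[-1] != seg[-n], TRUE)
  terminal <- first_of_seg | last_of_seg
  ss <- disulfide_residues(scaf)
  keep <- vapply(positions, function(p) {
    i <- residue_index(scaf, p$chain, p$resno)
    !(terminal[i] || i %in% ss || scaf$residues$resid[i] == "PRO")
  }, logical(1))
  positions[keep]
}

disulfide_residues <- function(scaf) {
  sg <- which(scaf$atoms$elety == "SG" & scaf$atoms$resid == "CYS")
  if (length(sg) < 2) return(integer(0))
  d <- cross_dist(atom_xyz(scaf$atoms[sg, , drop = FALSE]),
                  atom_xyz(scaf$atoms[sg, , drop = FALSE]))
  diag(d) <- Inf
  bonded <- sg[apply(d <= 2.3, 1, any)]
  unique(vapply(bonded, function(k)
    residue_index(scaf, scaf$atoms$chain[k], scaf$atoms$resno[k]),
    integer(1)))
}

#' Partition a scaffold into fixed part and variable design positions
#'
#' The fixed scaffold keeps the full backbone of every residue and the
#' complete side chains of non-design residues; side-chain atoms (CB and
#' beyond, plus side-chain hydrogens) of design positions are removed and
#' will be supplied by rotamer groups.
#'
#' @param scaf A [scaffold()].
#' @param positions Design position list.
#' @return Object of class `pocket_model`: `positions`, `fixed` (atom
#'   table), `native_side_chains` (list of removed atom tables, one per
#'   position).
#' @export
build_pocket <- function(scaf, positions) {
  atoms <- scaf$atoms
  variable <- rep(FALSE, nrow(atoms))
  native <- vector("list", length(positions))
  for (k in seq_along(positions)) {
    p <- positions[[k]]
    i <- residue_index(scaf, p$chain, p$resno)
    if (is.na(i)) stop("design position not in scaffold: ",
                       residue_key(p$chain, p$resno))
    rows <- residue_atoms(scaf, i)
    sc <- rows[!atoms$backbone[rows] & atoms$elety[rows] != "CA"]
    variable[sc] <- TRUE
    native[[k]] <- atoms[sc, , drop = FALSE]
  }
  structure(list(positions = positions,
                 fixed = atoms[!variable, , drop = FALSE],
                 native_side_chains = native,
                 scaffold = scaf),
            class = "pocket_model")
}

#' @export
print.pocket_model <- function(x, ...) {
  cat("pocket_model:", length(x$positions), "design position(s),",
      nrow(x$fixed), "fixed atoms\n")
  for (p in x$positions)
    cat(sprintf("  %s:%d %s -> {%s}%s\n", p$chain, p$resno, p$native,
                paste(p$allowed_aas, collapse = ","),
                if (p$is_mutable) " (mutable)" else ""))
  invisible(x)
}
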