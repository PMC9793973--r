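# Energy-table assembly: the pocket is decomposed into self energies
# (variable group vs fixed scaffold) and pairwise energies (variable
# group vs variable group) on the packing track (force field) and the
# binding track (empirical score). Pair blocks are independent, so they
# are computed in parallel; the block list and its order are fixed, so
# results are identical for any worker count.

#' Compute self and pairwise energy tables
#'
#' @param pocket A [build_pocket()] result.
#' @param rotamer_set A pruned [build_rotamer_set()].
#' @param pose_set A pruned [prune_poses()] result.
#' @param ff [ff_params()] for the packing track.
#' @param weights [vina_weights()] for the binding track.
#' @param binding_scale Factor applied to binding-track entries when they
#'   enter the solver objective (default 50).
#' @param workers Number of parallel workers for pair blocks (results are
#'   bit-identical for any value).
#' @param progress Emit a message per completed block.
#' @return Object of class `energy_tables`.
#' @export
compute_tables <- function(pocket, rotamer_set, pose_set,
                           ff = ff_params(), weights = vina_weights(),
                           binding_scale = 50.0, workers = 1L,
                           progress = FALSE) {
  sets <- rotamer_set$by_position
  n_pos <- length(sets)
  if (n_pos == 0) stop("pocket has no design positions")
  for (s in sets) {
    if (length(s$rotamers) == 0)
      stop("empty rotamer list at position ",
           residue_key(s$position$chain, s$position$resno))
  }
  poses <- pose_set$poses
  if (length(poses) == 0) stop("empty pose set")
  fixed <- pocket$fixed
  note <- function(...) if (progress) message(sprintf(...))

  self_packing <- lapply(seq_len(n_pos), function(p) {
    e <- vapply(sets[[p]]$rotamers, function(rot) {
      excl <- group_exclusions(rot$atoms, fixed)
      ff_interaction(rot$atoms, fixed, ff, exclusions = excl)
    }, numeric(1))
    note("self block %d/%d done", p, n_pos)
    e
  })
  lig_self <- vapply(poses, function(po) vina_score(po$atoms, fixed, weights),
                     numeric(1))
  note("ligand self block done (%d poses)", length(poses))

  # pair blocks: (p, q) rotamer-rotamer for p < q, then (p, ligand)
  blocks <- list()
  if (n_pos >= 2) {
    for (p in seq_len(n_pos - 1)) for (q in (p + 1):n_pos)
      blocks[[length(blocks) + 1]] <- c(p, q)
  }
  for (p in seq_len(n_pos)) blocks[[length(blocks) + 1]] <- c(p, 0L)
  run_block <- function(b) {
    p <- b[1]; q <- b[2]
    rot_p <- sets[[p]]$rotamers
    if (q > 0) {
      rot_q <- sets[[q]]$rotamers
      m <- matrix(0, length(rot_p), length(rot_q))
      for (r in seq_along(rot_p)) for (s in seq_along(rot_q))
        m[r, s] <- ff_interaction(rot_p[[r]]$atoms, rot_q[[s]]$atoms, ff)
    } else {
      m <- matrix(0, length(poses), length(rot_p))
      for (l in seq_along(poses)) for (r in seq_along(rot_p))
        m[l, r] <- vina_score(poses[[l]]$atoms, rot_p[[r]]$atoms, weights)
    }
    m
  }
  res <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(blocks, run_block, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(blocks, run_block)
  }
  note("%d pair block(s) done", length(blocks))
  pair_packing <- list()
  lig_pair <- vector("list", n_pos)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (b[2] > 0) {
      pair_packing[[paste(b[1], b[2], sep = "|")]] <- res[[i]]
    } else {
      lig_pair[[b[1]]] <- res[[i]]
    }
  }
  structure(list(
    positions = lapply(sets, function(s) s$position),
    rot_info = lapply(sets, function(s) data.frame(
      aa = vapply(s$rotamers, `[[`, character(1), "aa"),
      chis = vapply(s$rotamers, function(r)
        paste(round(r$chis, 1), collapse = ","), character(1)),
      prob = vapply(s$rotamers, function(r)
        as.numeric(r$prob %||% NA_real_), numeric(1)),
      stringsAsFactors = FALSE)),
    n_rot = vapply(sets, function(s) length(s$rotamers), integer(1)),
    n_pose = length(poses),
    self_packing = self_packing,
    pair_packing = pair_packing,
    lig_self = lig_self,
    lig_pair = lig_pair,
    binding_scale = binding_scale),
    class = "energy_tables")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.energy_tables <- function(x, ...) {
  cat("energy_tables:", length(x$n_rot), "position(s) with",
      paste(x$n_rot, collapse = "/"), "rotamers,", x$n_pose, "pose(s),",
      "binding scale", x$binding_scale, "\n")
  invisible(x)
}

#' Energy of one full assignment from the tables
#'
#' Sums the table entries selected by one rotamer index per position and
#' a pose index: packing = self + pairwise packing terms; raw binding =
#' ligand self + ligand-rotamer terms; total = packing + binding_scale *
#' raw binding.
#'
#' @param tables An `energy_tables` object.
#' @param rot_idx Integer vector, one kept-rotamer index per position.
#' @param pose_idx Kept-pose index.
#' @return Named list: `total`, `packing`, `binding_raw`,
#'   `binding_scaled`.
#' @export
assignment_energy <- function(tables, rot_idx, pose_idx) {
  n_pos <- length(tables$n_rot)
  stopifnot(length(rot_idx) == n_pos,
            all(rot_idx >= 1 & rot_idx <= tables$n_rot),
            pose_idx >= 1, pose_idx <= tables$n_pose)
  packing <- sum(vapply(seq_len(n_pos), function(p)
    tables$self_packing[[p]][rot_idx[p]], numeric(1)))
  if (n_pos >= 2) {
    for (p in seq_len(n_pos - 1)) for (q in (p + 1):n_pos)
      packing <- packing +
        tables$pair_packing[[paste(p, q, sep = "|")]][rot_idx[p], rot_idx[q]]
  }
  binding <- tables$lig_self[pose_idx] +
    sum(vapply(seq_len(n_pos), function(p)
      tables$lig_pair[[p]][pose_idx, rot_idx[p]], numeric(1)))
  list(total = packing + tables$binding_scale * binding,
       packing = packing, binding_raw = binding,
       binding_scaled = tables$binding_scale * binding)
}

#' Direct whole-system energy of one assignment
#'
#' Recomputes the assignment energy from the structures rather than the
#' tables: every inter-group interaction (fixed scaffold, each chosen
#' rotamer, the chosen pose) is evaluated directly. Used to verify the
#' exactness of the self/pairwise decomposition.
#'
#' @inheritParams compute_tables
#' @param rot_idx One kept-rotamer index per position.
#' @param pose_idx Kept-pose index.
#' @return Same shape as [assignment_energy()].
#' @export
direct_assignment_energy <- function(pocket, rotamer_set, pose_set,
                                     rot_idx, pose_idx, ff = ff_params(),
                                     weights = vina_weights(),
                                     binding_scale = 50.0) {
  sets <- rotamer_set$by_position
  n_pos <- length(sets)
  stopifnot(length(rot_idx) == n_pos)
  groups <- lapply(seq_len(n_pos), function(p)
    sets[[p]]$rotamers[[rot_idx[p]]]$atoms)
  pose <- pose_set$poses[[pose_idx]]$atoms
  fixed <- pocket$fixed
  packing <- 0
  for (p in seq_len(n_pos)) {
    excl <- group_exclusions(groups[[p]], fixed)
    packing <- packing + ff_interaction(groups[[p]], fixed, ff,
                                        exclusions = excl)
    if (p < n_pos) for (q in (p + 1):n_pos)
      packing <- packing + ff_interaction(groups[[p]], groups[[q]], ff)
  }
  # one evaluation of the pose against the whole assembled protein
  protein <- rbind(fixed, do.call(rbind, groups))
  binding <- vina_score(pose, protein, weights)
  list(total = packing + binding_scale * binding, packing = packing,
       binding_raw = binding, binding_scaled = binding_scale * binding)
}
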