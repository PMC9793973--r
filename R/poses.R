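# Ligand pose sampling: every conformer is rigidly rotated and translated
# over a user-defined grid around its heavy-atom centroid, then poses
# clashing with the fixed scaffold are pruned (same vdW threshold rule as
# rotamers).

# Per-axis sample values {-max, ..., -step, 0, step, ..., max}. A step
# exceeding max degenerates to {0} with a warning.
grid_axis_values <- function(max, step, what) {
  stopifnot(step > 0, max >= 0)
  if (max == 0) return(0)
  if (step > max) {
    warning("grid step ", step, " exceeds max ", max, " for ", what,
            "; sampling 0 only")
    return(0)
  }
  s <- seq(step, max, by = step)
  c(-rev(s), 0, s)
}

#' Generate the ligand pose grid
#'
#' Each conformer is rotated intrinsically about its heavy-atom centroid
#' in fixed axis order x -> y -> z by every combination of per-axis
#' angles, then translated by every combination of per-axis offsets.
#' Output order is lexicographic in (conformer, rot_x, rot_y, rot_z,
#' trans_x, trans_y, trans_z).
#'
#' @param conformers List of ligand conformers
#'   ([read_ligand_conformers()]).
#' @param rot_max,rot_step Rotation extreme and step per axis, degrees
#'   (default +/-20, step 20: values -20, 0, 20).
#' @param trans_max,trans_step Translation extreme and step per axis,
#'   Angstrom (default +/-0.5, step 0.5).
#' @return Object of class `pose_set`: `poses` (list of
#'   `list(conformer_id, rot, trans, atoms)`) plus the grid description.
#' @export
generate_pose_grid <- function(conformers, rot_max = 20.0, rot_step = 20.0,
                               trans_max = 0.5, trans_step = 0.5) {
  rv <- grid_axis_values(rot_max, rot_step, "rotation")
  tv <- grid_axis_values(trans_max, trans_step, "translation")
  poses <- list()
  n <- 0L
  for (conf in conformers) {
    xyz0 <- atom_xyz(conf$atoms)
    for (rx in rv) for (ry in rv) for (rz in rv) {
      R <- euler_xyz_matrix(rx, ry, rz)
      rot_xyz <- sweep(sweep(xyz0, 2, conf$centroid) %*% t(R), 2,
                       conf$centroid, "+")
      for (tx in tv) for (ty in tv) for (tz in tv) {
        n <- n + 1L
        atoms <- set_atom_xyz(conf$atoms,
                              sweep(rot_xyz, 2, c(tx, ty, tz), "+"))
        poses[[n]] <- list(conformer_id = conf$conformer_id,
                           rot = c(rx, ry, rz), trans = c(tx, ty, tz),
                           atoms = atoms)
      }
    }
  }
  structure(list(poses = poses, rot_values = rv, trans_values = tv,
                 n_conformers = length(conformers)),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat("pose_set:", length(x$poses), "pose(s) from", x$n_conformers,
      "conformer(s)\n")
  invisible(x)
}

#' Prune poses clashing with the fixed scaffold
#'
#' Identical contract to rotamer pruning: a pose is kept iff its
#' Lennard-Jones interaction with the fixed scaffold is below the
#' threshold.
#'
#' @param pose_set A [generate_pose_grid()] result.
#' @param fixed_atoms Fixed-scaffold atom table.
#' @param ff [ff_params()].
#' @param vdw_prune_threshold kcal/mol (default 100).
#' @return `pose_set` with pruned poses removed (order preserved),
#'   `scaffold_vdw` energies of kept poses and `n_pruned`.
#' @export
prune_poses <- function(pose_set, fixed_atoms, ff = ff_params(),
                        vdw_prune_threshold = 100.0) {
  vdw <- vapply(pose_set$poses, function(p)
    scaffold_vdw_energy(p$atoms, fixed_atoms, ff), numeric(1))
  keep <- vdw < vdw_prune_threshold
  if (!any(keep))
    stop("no viable ligand poses (all pruned at threshold ",
         vdw_prune_threshold, " kcal/mol)")
  pose_set$poses <- pose_set$poses[keep]
  pose_set$scaffold_vdw <- vdw[keep]
  pose_set$n_pruned <- sum(!keep)
  pose_set
}
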