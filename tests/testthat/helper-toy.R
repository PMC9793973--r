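# Shared fixtures. Toy systems are generated into tempdirs and memoised
# per seed so test files can reuse them without re-building.

.toy_cache <- new.env(parent = emptyenv())

# Generated files plus parsed objects for one toy-system seed.
toy_bundle <- function(seed = 7, n_pocket = 4) {
  key <- paste0("s", seed, "n", n_pocket)
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  dir <- file.path(tempdir(), paste0("toy_", key))
  paths <- make_toy_system(toy_spec(seed = seed,
                                    n_pocket_residues = n_pocket), dir)
  scaf <- read_scaffold(paths$scaffold_pdb, paths$scaffold_params)
  conformers <- read_ligand_conformers(paths$ligand_sdf,
                                       paths$ligand_params)
  lib <- read_rotamer_library(paths$rotamer_lib)
  params <- read_param_table(paths$scaffold_params)
  mutations <- stats::setNames(
    lapply(paths$config_data$positions, function(p) unlist(p$mutations)),
    vapply(paths$config_data$positions, function(p)
      paste0(p$chain, ":", p$resid), character(1)))
  bundle <- list(paths = paths, scaffold = scaf, conformers = conformers,
                 library = lib, params = params, mutations = mutations)
  .toy_cache[[key]] <- bundle
  bundle
}

# Pocket + pruned rotamers + small pruned pose grid + tables, memoised.
toy_design <- function(seed = 7, rot_max = 0, trans_max = 0.5,
                       binding_scale = 50) {
  key <- paste0("d", seed, "r", rot_max, "t", trans_max, "b", binding_scale)
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  b <- toy_bundle(seed)
  positions <- select_flexible(b$scaffold, b$conformers[[1]]$atoms,
                               b$mutations)
  pocket <- build_pocket(b$scaffold, positions)
  rotamers <- build_rotamer_set(pocket, b$library, b$params)
  poses <- prune_poses(generate_pose_grid(b$conformers, rot_max = rot_max,
                                          trans_max = trans_max),
                       pocket$fixed)
  tables <- compute_tables(pocket, rotamers, poses,
                           binding_scale = binding_scale)
  d <- list(bundle = b, pocket = pocket, rotamers = rotamers,
            poses = poses, tables = tables)
  .toy_cache[[key]] <- d
  d
}

# Scalar pair-loop force-field evaluation: the independent oracle for
# ff_interaction and the energy decomposition (never vectorized).
brute_ff <- function(atoms_a, atoms_b, ff = ff_params(),
                     exclusions = NULL) {
  e <- 0
  for (i in seq_len(nrow(atoms_a))) for (j in seq_len(nrow(atoms_b))) {
    f_lj <- 1
    f_c <- 1
    if (!is.null(exclusions)) {
      if (nrow(exclusions$excl) > 0 &&
          any(exclusions$excl[, 1] == i & exclusions$excl[, 2] == j)) {
        f_lj <- 0
        f_c <- 0
      } else if (nrow(exclusions$pair14) > 0 &&
                 any(exclusions$pair14[, 1] == i &
                       exclusions$pair14[, 2] == j)) {
        f_lj <- ff$lj_14_scale
        f_c <- ff$coulomb_14_scale
      }
    }
    if (f_lj == 0 && f_c == 0) next
    r <- sqrt(sum((as.numeric(atoms_a[i, c("x", "y", "z")]) -
                     as.numeric(atoms_b[j, c("x", "y", "z")]))^2))
    e <- e + f_lj * lj_energy(atoms_a[i, ], atoms_b[j, ], r) +
      f_c * coulomb_energy(atoms_a[i, ], atoms_b[j, ], r,
                           ff$coulomb_constant)
  }
  e
}

# Minimal atom table builder for constructed test cases.
mk_atoms <- function(xyz, elety = NULL, charge = 0, rmin_half = 1.9,
                     epsilon = 0.1, vdw_radius = 1.9, class = "none",
                     resid = "XXX", chain = "A", resno = 1L,
                     is_h = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(elety)) elety <- paste0("X", seq_len(n))
  data.frame(elety = elety, elesy = "C", chain = chain, resid = resid,
             resno = resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             charge = rep_len(charge, n),
             rmin_half = rep_len(rmin_half, n),
             epsilon = rep_len(epsilon, n),
             vdw_radius = rep_len(vdw_radius, n),
             class = rep_len(class, n), is_h = rep_len(is_h, n),
             backbone = FALSE, stringsAsFactors = FALSE)
}

# Random rigid transform applied to an n x 3 matrix (fixed seed outside).
rigid_transform <- function(xyz, angles, shift) {
  R <- pocketdesign:::euler_xyz_matrix(angles[1], angles[2], angles[3])
  sweep(xyz %*% t(R), 2, shift, "+")
}
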