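# Deterministic toy-system generation. These fixtures are chemically
# naive but geometrically valid: residues on an ideal helical backbone,
# a small rigid ligand at the pocket mouth, parameter tables with
# element-typed charges/radii, and a small backbone-dependent rotamer
# library that includes one deliberately scaffold-clashing rotamer (so
# pruning always has work to do) and rotamers in ligand contact (so the
# binding track is exercised). Everything is a pure function of the seed.

#' Toy-system specification
#'
#' @param n_pocket_residues Number of pocket residues between the two
#'   terminal glycines (3-6 is typical).
#' @param aas Amino acids cycled over the pocket residues.
#' @param ligand_atom_count Ligand heavy atoms (2-5).
#' @param seed Integer seed; the system is a pure function of it.
#' @param geometry Backbone geometry (`helix` only).
#' @return Object of class `toy_system_spec`.
#' @export
toy_spec <- function(n_pocket_residues = 4,
                     aas = c("LEU", "SER", "ASP", "VAL"),
                     ligand_atom_count = 4, seed = 1,
                     geometry = c("helix")) {
  geometry <- match.arg(geometry)
  stopifnot(n_pocket_residues >= 3, ligand_atom_count >= 2,
            ligand_atom_count <= 5)
  structure(list(n_pocket_residues = n_pocket_residues,
                 aas = toupper(aas),
                 ligand_atom_count = ligand_atom_count,
                 seed = as.integer(seed), geometry = geometry),
            class = "toy_system_spec")
}

# Ideal backbone: N/CA/C/O per residue for given phi/psi (degrees).
build_backbone <- function(n, phi = -57, psi = -47, omega = 180) {
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- place_atom(c(0, 0, 1), N, CA, 1.525, 111.2, -35)
  for (i in seq_len(n)) {
    Nn <- place_atom(N, CA, C, 1.329, 116.2, psi)
    O <- place_atom(N, CA, C, 1.231, 120.8, psi + 180)
    res[[i]] <- list(N = N, CA = CA, C = C, O = O)
    CAn <- place_atom(CA, C, Nn, 1.458, 121.7, omega)
    Cn <- place_atom(C, Nn, CAn, 1.525, 111.2, phi)
    N <- Nn; CA <- CAn; C <- Cn
  }
  res
}

ELEMENT_PARAMS <- data.frame(
  element = c("C", "N", "O", "S"),
  charge = c(0.08, -0.38, -0.42, -0.12),
  rmin_half = c(1.908, 1.824, 1.661, 2.000),
  epsilon = c(0.1094, 0.1700, 0.2100, 0.2500),
  vdw_radius = c(1.9, 1.8, 1.7, 2.0),
  class = c("hydrophobic", "donor", "acceptor", "none"),
  stringsAsFactors = FALSE)

# Backbone N is an amide donor, backbone O a carbonyl acceptor; CA/C are
# plain carbons (not hydrophobic: they sit at the cut and in the amide).
param_rows_for <- function(res, atoms, elements, jitter) {
  p <- ELEMENT_PARAMS[match(elements, ELEMENT_PARAMS$element), ]
  data.frame(res = res, atom = atoms,
             charge = round(p$charge + jitter, 4),
             rmin_half = p$rmin_half, epsilon = p$epsilon,
             vdw_radius = p$vdw_radius, class = p$class,
             stringsAsFactors = FALSE)
}

toy_rotamer_entries <- function() {
  # chi sets per amino acid at the helix bin (-60, -50); LEU's second
  # entry points back across the helix face and clashes with the fixed
  # scaffold by construction (pruning fixture).
  list(
    LEU = list(list(chis = c(-60, 175), prob = 0.5),
               list(chis = c(65, 95), prob = 0.3),
               list(chis = c(180, 65), prob = 0.2)),
    SER = list(list(chis = -65, prob = 0.45),
               list(chis = 65, prob = 0.3),
               list(chis = 180, prob = 0.25)),
    ASP = list(list(chis = c(-70, -20), prob = 0.55),
               list(chis = c(170, 15), prob = 0.35)),
    VAL = list(list(chis = 175, prob = 0.6),
               list(chis = -60, prob = 0.25)),
    PHE = list(list(chis = c(-65, 90), prob = 0.5),
               list(chis = c(180, 75), prob = 0.4)))
}

write_rotamer_tsv <- function(path, entries, phi_bin = -60, psi_bin = -50) {
  lines <- c("# bin_width: 10", "aa\tphi_bin\tpsi_bin\tprob\tchi1\tchi2")
  for (aa in names(entries)) for (e in entries[[aa]]) {
    chi <- c(e$chis, rep(NA, 2 - length(e$chis)))
    lines <- c(lines, paste(aa, phi_bin, psi_bin, e$prob,
                            ifelse(is.na(chi[1]), "NA", chi[1]),
                            ifelse(is.na(chi[2]), "NA", chi[2]),
                            sep = "\t"))
  }
  writeLines(lines, path)
}

write_sdf_v2000 <- function(path, conformers, elements, bonds, title) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(conformers)) {
    xyz <- conformers[[i]]
    writeLines(c(sprintf("%s_conf%d", title, i), "  toy", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(xyz), nrow(bonds)), con)
    writeLines(sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      xyz[, 1], xyz[, 2], xyz[, 3], elements), con)
    writeLines(sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], 1),
               con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Generate a complete toy design system on disk
#'
#' Writes `scaffold.pdb`, `ligand.sdf`, `scaffold_params.tsv`,
#' `ligand_params.tsv`, `rotamers.tsv` and `config.yaml` into `out_dir`.
#' Output is byte-identical for identical specs.
#'
#' @param spec A [toy_spec()].
#' @param out_dir Output directory (created).
#' @return Named list of file paths plus the config list, invisibly.
#' @export
make_toy_system <- function(spec = toy_spec(), out_dir) {
  stopifnot(inherits(spec, "toy_system_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n_pocket <- spec$n_pocket_residues
  seq_aa <- c("GLY", rep_len(spec$aas, n_pocket), "GLY")
  n <- length(seq_aa)
  bb <- build_backbone(n)
  # native side chains: first toy-library chi set (ALA/GLY: none)
  lib <- toy_rotamer_entries()
  rows <- list()
  for (i in seq_len(n)) {
    aa <- seq_aa[i]
    f <- bb[[i]]
    for (nm in c("N", "CA", "C", "O")) {
      rows[[length(rows) + 1]] <- data.frame(
        elety = nm, elesy = substr(nm, 1, 1), chain = "A", resid = aa,
        resno = i, x = f[[nm]][1], y = f[[nm]][2], z = f[[nm]][3],
        stringsAsFactors = FALSE)
    }
    if (CHI_COUNTS[[aa]] > 0 || aa == "ALA") {
      chis <- if (CHI_COUNTS[[aa]] > 0) lib[[aa]][[1]]$chis else numeric(0)
      sc <- build_side_chain(aa, f$N, f$CA, f$C, chis)
      if (nrow(sc) > 0)
        rows[[length(rows) + 1]] <- data.frame(
          elety = sc$atom, elesy = sc$element, chain = "A", resid = aa,
          resno = i, x = sc$x, y = sc$y, z = sc$z, stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  # seeded coordinate jitter, small enough to keep the geometry class
  at$x <- at$x + stats::runif(nrow(at), -0.005, 0.005)
  at$y <- at$y + stats::runif(nrow(at), -0.005, 0.005)
  at$z <- at$z + stats::runif(nrow(at), -0.005, 0.005)
  at[c("x", "y", "z")] <- round(at[c("x", "y", "z")], 3)
  atoms <- new_atom_table(data.frame(
    at, charge = NA_real_, rmin_half = NA_real_, epsilon = NA_real_,
    vdw_radius = NA_real_, class = "none", is_h = FALSE,
    backbone = is_backbone_name(at$elety), stringsAsFactors = FALSE))

  # design positions: the two central pocket residues
  mid <- floor(n / 2)
  design_resno <- c(mid, mid + 1)

  # ligand placed off the design residues' CB direction
  cb <- atoms[atoms$elety == "CB" & atoms$resno %in% design_resno, ]
  ca <- atoms[atoms$elety == "CA" & atoms$resno %in% design_resno, ]
  dir <- colMeans(atom_xyz(cb)) - colMeans(atom_xyz(ca))
  dir <- dir / sqrt(sum(dir^2))
  center <- colMeans(atom_xyz(cb)) + 4.2 * dir
  k <- spec$ligand_atom_count
  elements <- rep_len(c("C", "O", "N", "C", "O"), k)
  local_xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(-0.75, 1.3, 0),
                     c(-0.75, -1.3, 0), c(0, 0, 1.5))[seq_len(k), ,
                                                      drop = FALSE]
  bonds <- cbind(1, seq_len(k))[-1, , drop = FALSE]
  jit <- matrix(stats::runif(3 * k, -0.02, 0.02), k, 3)
  conf1 <- round(sweep(local_xyz + jit, 2, center, "+"), 4)
  # second conformer: internal twist of the substituents about x
  R <- euler_xyz_matrix(25, 0, 0)
  conf2 <- round(sweep(sweep(conf1, 2, center) %*% t(R), 2, center, "+"), 4)

  paths <- list(
    scaffold_pdb = file.path(out_dir, "scaffold.pdb"),
    ligand_sdf = file.path(out_dir, "ligand.sdf"),
    scaffold_params = file.path(out_dir, "scaffold_params.tsv"),
    ligand_params = file.path(out_dir, "ligand_params.tsv"),
    rotamer_lib = file.path(out_dir, "rotamers.tsv"),
    config = file.path(out_dir, "config.yaml"))
  write_pdb(atoms, paths$scaffold_pdb)
  write_sdf_v2000(paths$ligand_sdf, list(conf1, conf2), elements, bonds,
                  "toylig")

  # scaffold parameters: every (aa, atom) that can occur, i.e. backbone
  # atoms of every residue type plus all template side-chain atoms
  aas_all <- unique(c(seq_aa, names(lib), names(SIDE_CHAIN_TEMPLATES)))
  prow <- list()
  for (aa in aas_all) {
    bbn <- c("N", "CA", "C", "O")
    prow[[length(prow) + 1]] <- param_rows_for(
      aa, bbn, substr(bbn, 1, 1),
      round(stats::runif(length(bbn), -0.01, 0.01), 4))
    tmpl <- SIDE_CHAIN_TEMPLATES[[aa]]
    if (!is.null(tmpl))
      prow[[length(prow) + 1]] <- param_rows_for(
        aa, tmpl$atom, element_from_name(tmpl$atom),
        round(stats::runif(nrow(tmpl), -0.01, 0.01), 4))
  }
  sp <- do.call(rbind, prow)
  utils::write.table(sp, paths$scaffold_params, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lp <- param_rows_for("LIG", paste0(elements, seq_len(k)), elements,
                       round(stats::runif(k, -0.01, 0.01), 4))
  utils::write.table(lp, paths$ligand_params, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_rotamer_tsv(paths$rotamer_lib, lib)

  mutations <- stats::setNames(
    list(c(seq_aa[design_resno[1]], "PHE"),
         c(seq_aa[design_resno[2]], "SER")),
    residue_key("A", design_resno))
  config <- list(
    scaffold_pdb = "scaffold.pdb", ligand_sdf = "ligand.sdf",
    scaffold_params = "scaffold_params.tsv",
    ligand_params = "ligand_params.tsv", rotamer_lib = "rotamers.tsv",
    flex_radius = 4.0, vdw_prune_threshold = 100.0, binding_scale = 50.0,
    rot_max = 20.0, rot_step = 20.0, trans_max = 0.5, trans_step = 0.5,
    positions = lapply(seq_along(design_resno), function(j)
      list(chain = "A", resid = design_resno[j],
           mutations = as.list(mutations[[j]]))))
  yaml::write_yaml(config, paths$config)
  invisible(c(paths, list(config_data = config,
                          design_resno = design_resno)))
}

#' Random energy tables (solver stress fixture)
#'
#' Uniform(-1, 1) self and pair entries for an instance with the given
#' candidate counts; no structures behind it.
#'
#' @param seed Integer seed.
#' @param n_rot Integer vector of rotamer counts per position.
#' @param n_pose Pose count.
#' @param binding_scale Scale stored in the tables (default 1).
#' @return `energy_tables` object.
#' @export
random_energy_tables <- function(seed, n_rot, n_pose, binding_scale = 1) {
  set.seed(seed)
  n_pos <- length(n_rot)
  pair <- list()
  if (n_pos >= 2) {
    for (p in seq_len(n_pos - 1)) for (q in (p + 1):n_pos)
      pair[[paste(p, q, sep = "|")]] <-
        matrix(stats::runif(n_rot[p] * n_rot[q], -1, 1), n_rot[p], n_rot[q])
  }
  structure(list(
    positions = lapply(seq_len(n_pos), function(p)
      list(chain = "A", resno = p)),
    rot_info = lapply(seq_len(n_pos), function(p)
      data.frame(aa = rep("XXX", n_rot[p]), chis = "", prob = NA_real_)),
    n_rot = as.integer(n_rot), n_pose = as.integer(n_pose),
    self_packing = lapply(n_rot, function(k) stats::runif(k, -1, 1)),
    pair_packing = pair,
    lig_self = stats::runif(n_pose, -1, 1),
    lig_pair = lapply(seq_len(n_pos), function(p)
      matrix(stats::runif(n_pose * n_rot[p], -1, 1), n_pose, n_rot[p])),
    binding_scale = binding_scale), class = "energy_tables")
}

#' Planted-optimum instance
#'
#' Builds random tables, picks a random assignment and lowers every table
#' entry it touches by a margin large enough to make it the strictly
#' dominant GMEC (entries are bounded by 1 in magnitude, so a margin
#' exceeding twice the term count guarantees strict dominance).
#'
#' @param seed Integer seed.
#' @param n_rot,n_pose Candidate counts.
#' @param margin `NULL` for the guaranteed-dominance margin `2K + 1`
#'   (K = number of objective terms); `0` plants a tie instead.
#' @return List: `tables`, `planted` (`list(rot_idx, pose_idx)`),
#'   `margin`.
#' @export
make_known_optimum_instance <- function(seed, n_rot = c(3, 3, 3),
                                        n_pose = 4, margin = NULL) {
  tab <- random_energy_tables(seed, n_rot, n_pose)
  n_pos <- length(n_rot)
  set.seed(seed + 777L)
  rot_idx <- vapply(n_rot, function(k) sample.int(k, 1), integer(1))
  pose_idx <- sample.int(n_pose, 1)
  K <- n_pos + choose(n_pos, 2) + 1 + n_pos
  if (is.null(margin)) margin <- 2 * K + 1
  for (p in seq_len(n_pos))
    tab$self_packing[[p]][rot_idx[p]] <-
      tab$self_packing[[p]][rot_idx[p]] - margin
  if (n_pos >= 2) {
    for (p in seq_len(n_pos - 1)) for (q in (p + 1):n_pos) {
      k <- paste(p, q, sep = "|")
      tab$pair_packing[[k]][rot_idx[p], rot_idx[q]] <-
        tab$pair_packing[[k]][rot_idx[p], rot_idx[q]] - margin
    }
  }
  tab$lig_self[pose_idx] <- tab$lig_self[pose_idx] - margin
  for (p in seq_len(n_pos))
    tab$lig_pair[[p]][pose_idx, rot_idx[p]] <-
      tab$lig_pair[[p]][pose_idx, rot_idx[p]] - margin
  list(tables = tab, planted = list(rot_idx = rot_idx,
                                    pose_idx = pose_idx),
       margin = margin)
}
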