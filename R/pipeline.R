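# End-to-end design driver: pocket definition -> rotamer sampling ->
# pose sampling -> energy tables -> GMEC + N-best, with per-stage cache
# manifests. This is the function the command-line entry point wraps.

#' Run a complete pocket design
#'
#' @param scaffold_pdb,scaffold_params Scaffold PDB and parameter TSV.
#' @param ligand_sdf,ligand_params Ligand conformer SDF and parameter TSV.
#' @param rotamer_lib Rotamer library TSV.
#' @param mutations Named list `"chain:resno" -> c("AAA", ...)` of allowed
#'   mutations (native always included).
#' @param flex_radius Flexible-shell radius, Angstrom (default 4).
#' @param rot_max,rot_step,trans_max,trans_step Pose grid (degrees /
#'   Angstrom; defaults +/-20 deg and +/-0.5 A with step = max).
#' @param vdw_prune_threshold Scaffold vdW pruning threshold, kcal/mol.
#' @param binding_scale Binding-track upscaling factor in the objective.
#' @param n_best Number of ranked solutions to return.
#' @param ff,weights Force-field constants and scoring weights.
#' @param include_native Keep crystal-native side chains as rotamers.
#' @param workers Parallel workers for pair-energy blocks.
#' @param cache_dir Stage cache directory (`NULL`: no caching).
#' @param force Ignore cached stages.
#' @param progress Emit progress messages.
#' @return List: `pocket`, `rotamers`, `poses`, `tables`, `solutions`,
#'   `report`, `stage_cached` (named logicals).
#' @export
design_pocket <- function(scaffold_pdb, scaffold_params, ligand_sdf,
                          ligand_params, rotamer_lib, mutations = list(),
                          flex_radius = 4.0, rot_max = 20.0,
                          rot_step = 20.0, trans_max = 0.5,
                          trans_step = 0.5, vdw_prune_threshold = 100.0,
                          binding_scale = 50.0, n_best = 1L,
                          ff = ff_params(), weights = vina_weights(),
                          include_native = FALSE, workers = 1L,
                          cache_dir = NULL, force = FALSE,
                          progress = FALSE) {
  scaf <- read_scaffold(scaffold_pdb, scaffold_params)
  conformers <- read_ligand_conformers(ligand_sdf, ligand_params)
  library <- read_rotamer_library(rotamer_lib)
  input_hash <- config_hash(file_checksum(scaffold_pdb),
                            file_checksum(scaffold_params),
                            file_checksum(ligand_sdf),
                            file_checksum(ligand_params),
                            file_checksum(rotamer_lib))
  cached <- c()
  stage <- function(name, hash, fun) {
    if (is.null(cache_dir)) {
      cached[name] <<- FALSE
      return(fun())
    }
    st <- run_stage(cache_dir, name, hash, fun, force = force)
    cached[name] <<- st$cached
    if (progress && st$cached) message("stage ", name, ": cached, skipped")
    st$result
  }

  h_pocket <- config_hash("pocket", input_hash, mutations, flex_radius)
  pocket <- stage("pocket", h_pocket, function() {
    positions <- select_flexible(scaf, conformers[[1]]$atoms, mutations,
                                 radius = flex_radius)
    if (length(positions) == 0) stop("no flexible positions selected")
    build_pocket(scaf, positions)
  })

  h_rot <- config_hash("rotamers", h_pocket, vdw_prune_threshold,
                       include_native, unclass(ff))
  rotamers <- stage("rotamers", h_rot, function()
    build_rotamer_set(pocket, library,
                      read_param_table(scaffold_params), ff = ff,
                      vdw_prune_threshold = vdw_prune_threshold,
                      include_native = include_native))

  h_pose <- config_hash("poses", h_pocket, rot_max, rot_step, trans_max,
                        trans_step, vdw_prune_threshold, unclass(ff))
  poses <- stage("poses", h_pose, function()
    prune_poses(generate_pose_grid(conformers, rot_max, rot_step,
                                   trans_max, trans_step),
                pocket$fixed, ff = ff,
                vdw_prune_threshold = vdw_prune_threshold))

  h_tab <- config_hash("tables", h_rot, h_pose, binding_scale,
                       unclass(weights))
  tables <- stage("tables", h_tab, function()
    compute_tables(pocket, rotamers, poses, ff = ff, weights = weights,
                   binding_scale = binding_scale, workers = workers,
                   progress = progress))

  h_sol <- config_hash("solutions", h_tab, n_best)
  solutions <- stage("solutions", h_sol, function()
    enumerate_best(tables, n_best))

  report <- design_report(tables, solutions,
                          provenance = list(config = h_sol,
                                            inputs = input_hash))
  list(pocket = pocket, rotamers = rotamers, poses = poses,
       tables = tables, solutions = solutions, report = report,
       stage_cached = cached)
}
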