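# Ligand conformer input. Conformer ensembles come as multi-record V2000
# SDF files (one record per conformer, identical atom count and element
# order); parsing is done by ChemmineR.

#' Read a ligand conformer ensemble
#'
#' @param sdf_path Multi-record V2000 SDF; every record must have the same
#'   atom count and element order (conformers of one molecule).
#' @param param_path Parameter TSV; rows keyed by the ligand residue name
#'   (`res` column, default `LIG`) and generated atom names
#'   `<element><index>` in record atom order.
#' @param resid Residue name used for the ligand atoms.
#' @return List of ligand conformers; each element has `conformer_id`,
#'   `atoms` (atom table with parameters) and `centroid` (heavy-atom mean).
#' @export
read_ligand_conformers <- function(sdf_path, param_path, resid = "LIG") {
  sdfs <- ChemmineR::read.SDFset(sdf_path)
  params <- read_param_table(param_path)
  blocks <- lapply(seq_along(sdfs@SDF), function(i)
    ChemmineR::atomblock(sdfs@SDF[[i]]))
  elems <- lapply(blocks, function(b) sub("_.*$", "", rownames(b)))
  for (i in seq_along(elems)) {
    if (length(elems[[i]]) != length(elems[[1]]) ||
        any(elems[[i]] != elems[[1]]))
      stop("SDF records differ in atom count or element order (record ", i,
           " vs 1): conformers must share one atom graph")
  }
  lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    el <- elems[[i]]
    atoms <- new_atom_table(data.frame(
      elety = paste0(el, seq_along(el)), elesy = el,
      chain = "L", resid = resid, resno = 1L,
      x = b[, 1], y = b[, 2], z = b[, 3],
      charge = NA_real_, rmin_half = NA_real_, epsilon = NA_real_,
      vdw_radius = NA_real_, class = "none",
      is_h = toupper(el) == "H", backbone = FALSE,
      stringsAsFactors = FALSE))
    atoms <- attach_params(atoms, params)
    ligand_conformer(i, atoms)
  })
}

ligand_conformer <- function(conformer_id, atoms) {
  heavy <- !atoms$is_h
  structure(list(conformer_id = as.integer(conformer_id), atoms = atoms,
                 centroid = colMeans(atom_xyz(atoms)[heavy, , drop = FALSE])),
            class = "ligand_conformer")
}
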