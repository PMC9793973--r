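# PDB input (via bio3d) and output. Reading keeps ATOM/HETATM records
# only, rejects insertion codes and multi-model files, and resolves
# alternate locations to the highest occupancy (ties: first encountered).

#' Read a protein scaffold with parameters
#'
#' @param pdb_path Single-model PDB file (protonation state as supplied).
#' @param param_path Per-atom parameter TSV covering every atom
#'   (see [read_param_table()]).
#' @return A [scaffold()] with parameters attached.
#' @export
read_scaffold <- function(pdb_path, param_path) {
  atoms <- read_pdb_atoms(pdb_path, hetatm = FALSE)
  params <- read_param_table(param_path)
  scaffold(attach_params(atoms, params))
}

#' Read ligand atoms from a placed-ligand PDB
#'
#' Reads HETATM (and ATOM) records of a single-model PDB containing the
#' ligand in its pocket position, attaching parameters.
#'
#' @inheritParams read_scaffold
#' @return Atom table for the ligand.
#' @export
read_ligand_pdb <- function(pdb_path, param_path) {
  atoms <- read_pdb_atoms(pdb_path, hetatm = TRUE)
  attach_params(atoms, read_param_table(param_path))
}

read_pdb_atoms <- function(pdb_path, hetatm = FALSE) {
  if (sum(grepl("^MODEL ", readLines(pdb_path))) > 1)
    stop("multi-model PDB not supported as a scaffold: ", pdb_path)
  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no atom records read from ", pdb_path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported: ", pdb_path)
  at <- resolve_altloc(at)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  elesy <- ifelse(is.na(at$elesy) | at$elesy == "",
                  element_from_name(at$elety), at$elesy)
  new_atom_table(data.frame(
    elety = at$elety, elesy = elesy, chain = chain,
    resid = at$resid, resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    charge = NA_real_, rmin_half = NA_real_, epsilon = NA_real_,
    vdw_radius = NA_real_, class = "none",
    is_h = toupper(elesy) == "H",
    backbone = is_backbone_name(at$elety),
    stringsAsFactors = FALSE))
}

# Keep, per (chain, resno, atom name), the highest-occupancy alternate
# location; ties resolved to the first record encountered.
resolve_altloc <- function(at) {
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(occ[idx])]   # which.max: first on ties
    keep[setdiff(idx, best)] <- FALSE
  }
  at[keep, , drop = FALSE]
}

format_pdb_records <- function(atoms, het = FALSE, serial_start = 1L) {
  rec <- ifelse(rep_len(het, nrow(atoms)), "HETATM", "ATOM  ")
  serial <- seq_len(nrow(atoms)) + serial_start - 1L
  name <- vapply(atoms$elety, function(n) {
    if (nchar(n) >= 4) substr(n, 1, 4) else sprintf(" %-3s", n)
  }, character(1))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, atoms$resid, substr(atoms$chain, 1, 1),
          atoms$resno, atoms$x, atoms$y, atoms$z, 1, 0,
          toupper(atoms$elesy))
}

#' Write an atom table (or scaffold) to a PDB file
#'
#' @param x Atom table or [scaffold()].
#' @param path Output path.
#' @param het_resid Residue names written as HETATM records (ligands).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, het_resid = character(0)) {
  atoms <- if (inherits(x, "scaffold")) x$atoms else x
  lines <- format_pdb_records(atoms, het = atoms$resid %in% het_resid)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a conformational ensemble as a multi-model PDB
#'
#' One MODEL/ENDMDL block per ensemble member, for visual inspection of
#' pose or rotamer ensembles.
#'
#' @param atom_tables List of atom tables with identical atom order.
#' @param path Output path.
#' @param het Logical: write HETATM records (default TRUE; ensembles are
#'   typically ligand poses).
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(atom_tables, path, het = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(atom_tables)) {
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(format_pdb_records(atom_tables[[i]], het = het), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
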