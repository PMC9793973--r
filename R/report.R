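# Design output and evaluation operators: designed-structure PDB export,
# the affinity-pair ranking criterion, backbone-superposed heavy-atom
# RMSD, and deterministic text/HTML energy reports.

#' Write the designed structure for one solution
#'
#' Fixed scaffold plus the chosen rotamer side chains (merged into their
#' residues) plus the chosen ligand pose (HETATM records, own chain).
#'
#' @param pocket A [build_pocket()] result.
#' @param solution A `design_solution`.
#' @param rotamer_set,pose_set The pruned sets the solution indexes into.
#' @param out_path Output PDB path.
#' @return Invisibly, the assembled atom table.
#' @export
write_design_structure <- function(pocket, solution, rotamer_set, pose_set,
                                   out_path) {
  atoms <- assemble_design(pocket, solution, rotamer_set, pose_set)
  lig_resid <- unique(pose_set$poses[[1]]$atoms$resid)
  write_pdb(atoms, out_path, het_resid = lig_resid)
  invisible(atoms)
}

#' Assemble the atom table of one solution
#'
#' Fixed scaffold with the chosen rotamer side chains merged back into
#' their residues (scaffold residue order), ligand pose last.
#'
#' @inheritParams write_design_structure
#' @return Atom table.
#' @export
assemble_design <- function(pocket, solution, rotamer_set, pose_set) {
  sets <- rotamer_set$by_position
  chosen <- lapply(seq_along(sets), function(p)
    sets[[p]]$rotamers[[solution$rotamer_choice[p]]]$atoms)
  prot <- rbind(pocket$fixed, do.call(rbind, chosen))
  # restore residue order: sort by scaffold residue rank, side chain after
  # backbone within a residue
  key <- residue_key(prot$chain, prot$resno)
  rank <- match(key, residue_key(pocket$scaffold$residues$chain,
                                 pocket$scaffold$residues$resno))
  prot <- prot[order(rank, !prot$backbone & prot$elety != "CA"), ]
  rbind(prot, pose_set$poses[[solution$pose_choice]]$atoms)
}

#' Rank an experimentally ordered design pair
#'
#' A prediction is correct when the computed binding energy of the
#' variant with experimentally higher affinity is lower than that of the
#' weaker binder; exact ties are conservatively scored incorrect (with a
#' warning). The same criterion applied to total energies is reported
#' alongside.
#'
#' @param low_affinity,high_affinity `design_solution` objects (or lists
#'   with `binding_energy_raw` / `total_energy`) for the experimentally
#'   weaker and stronger binder, respectively.
#' @return List: `correct_binding`, `correct_total` (logicals).
#' @export
rank_pair <- function(low_affinity, high_affinity) {
  cmp <- function(hi, lo, what) {
    if (hi == lo) {
      warning("exact tie on ", what, " energies; scored incorrect")
      return(FALSE)
    }
    hi < lo
  }
  list(correct_binding = cmp(high_affinity$binding_energy_raw,
                             low_affinity$binding_energy_raw, "binding"),
       correct_total = cmp(high_affinity$total_energy,
                           low_affinity$total_energy, "total"))
}

match_atoms <- function(ref, other, rows_ref, what) {
  key_r <- paste(ref$chain[rows_ref], ref$resno[rows_ref],
                 ref$elety[rows_ref])
  key_o <- paste(other$chain, other$resno, other$elety)
  idx <- match(key_r, key_o)
  if (anyNA(idx))
    stop("atom-name mismatch in ", what, ": ",
         paste(key_r[is.na(idx)], collapse = "; "))
  idx
}

#' Pocket side-chain RMSD after backbone superposition
#'
#' Superposes the designed structure onto the reference by least squares
#' over all shared backbone heavy atoms (N, CA, C, O), then reports the
#' heavy-atom RMSD over the side chains of the flexible residues only.
#'
#' @param reference,designed Atom tables (e.g. from [read_pdb_atoms]
#'   readers or [assemble_design] output) with matching residue
#'   numbering.
#' @param flexible_keys Character vector of `"chain:resno"` residue keys
#'   that were allowed to move.
#' @return RMSD in Angstrom.
#' @export
pocket_rmsd <- function(reference, designed, flexible_keys) {
  sup <- superpose_on_backbone(reference, designed)
  ref <- sup$reference
  des <- sup$designed
  sel <- which(atom_res_key(ref) %in% flexible_keys &
                 !ref$backbone & !ref$is_h & ref$elety != "CA")
  if (length(sel) == 0) stop("no flexible side-chain heavy atoms to compare")
  idx <- match_atoms(ref, des, sel, "flexible side chains")
  rmsd_points(atom_xyz(ref[sel, , drop = FALSE]),
              atom_xyz(des[idx, , drop = FALSE]))
}

#' Ligand RMSD after backbone superposition
#'
#' Same protein-backbone superposition as [pocket_rmsd()]; the RMSD is
#' computed over ligand heavy atoms.
#'
#' @inheritParams pocket_rmsd
#' @param lig_resid Ligand residue name (default `LIG`).
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(reference, designed, lig_resid = "LIG") {
  sup <- superpose_on_backbone(reference, designed)
  ref <- sup$reference
  des <- sup$designed
  sel <- which(ref$resid %in% lig_resid & !ref$is_h)
  if (length(sel) == 0) stop("no ligand heavy atoms in reference")
  idx <- match_atoms(ref, des, sel, "ligand")
  rmsd_points(atom_xyz(ref[sel, , drop = FALSE]),
              atom_xyz(des[idx, , drop = FALSE]))
}

superpose_on_backbone <- function(reference, designed) {
  bb_names <- c("N", "CA", "C", "O")
  sel_r <- which(reference$elety %in% bb_names & !reference$is_h &
                   reference$backbone)
  idx <- match_atoms(reference, designed, sel_r, "backbone")
  xyz_d <- kabsch_superpose(atom_xyz(reference), atom_xyz(designed),
                            fit_fixed = sel_r, fit_mobile = idx)
  list(reference = reference, designed = set_atom_xyz(designed, xyz_d))
}

rmsd_points <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Assemble a design report
#'
#' @param tables The `energy_tables` used for solving.
#' @param solutions List of `design_solution` (e.g. [enumerate_best()]).
#' @param provenance Named list recorded verbatim (config hash, file
#'   checksums).
#' @return Object of class `design_report`.
#' @export
design_report <- function(tables, solutions, provenance = list()) {
  structure(list(tables = tables, solutions = solutions,
                 provenance = provenance),
            class = "design_report")
}

fmt_num <- function(x) sprintf("%.4f", x)

report_lines <- function(report) {
  tb <- report$tables
  n_pos <- length(tb$n_rot)
  pos_label <- vapply(tb$positions, function(p)
    residue_key(p$chain, p$resno), character(1))
  out <- c("pocket design report",
           sprintf("positions: %s", paste(pos_label, collapse = ", ")),
           sprintf("rotamers per position: %s",
                   paste(tb$n_rot, collapse = "/")),
           sprintf("poses: %d", tb$n_pose),
           sprintf("binding scale: %s", fmt_num(tb$binding_scale)),
           "")
  for (i in seq_along(report$solutions)) {
    s <- report$solutions[[i]]
    out <- c(out, sprintf("solution %d", i),
             sprintf("  rotamer indices: %s",
                     paste(s$rotamer_choice, collapse = ",")),
             sprintf("  pose index: %d", s$pose_choice))
    for (p in seq_len(n_pos)) {
      info <- tb$rot_info[[p]][s$rotamer_choice[p], ]
      out <- c(out, sprintf("  %s -> %s [%s]  self_packing=%s", pos_label[p],
                            info$aa, info$chis,
                            fmt_num(tb$self_packing[[p]][s$rotamer_choice[p]])))
    }
    if (n_pos >= 2) {
      for (p in seq_len(n_pos - 1)) for (q in (p + 1):n_pos)
        out <- c(out, sprintf("  pair %s-%s: %s", pos_label[p], pos_label[q],
                              fmt_num(tb$pair_packing[[paste(p, q, sep = "|")]][
                                s$rotamer_choice[p], s$rotamer_choice[q]])))
    }
    out <- c(out, sprintf("  ligand self (raw): %s",
                          fmt_num(tb$lig_self[s$pose_choice])))
    for (p in seq_len(n_pos))
      out <- c(out, sprintf("  ligand-%s (raw): %s", pos_label[p],
                            fmt_num(tb$lig_pair[[p]][s$pose_choice,
                                                     s$rotamer_choice[p]])))
    out <- c(out,
             sprintf("  packing energy: %s", fmt_num(s$packing_energy)),
             sprintf("  binding energy (raw): %s",
                     fmt_num(s$binding_energy_raw)),
             sprintf("  binding energy (scaled): %s",
                     fmt_num(s$binding_energy_scaled)),
             sprintf("  total energy: %s", fmt_num(s$total_energy)),
             "")
  }
  if (length(report$provenance) > 0) {
    out <- c(out, "provenance:")
    for (k in sort(names(report$provenance)))
      out <- c(out, sprintf("  %s: %s", k, report$provenance[[k]]))
  }
  out
}

#' Render a design report to text or HTML
#'
#' Rendering is deterministic: stable ordering and fixed 4-decimal float
#' formatting, so identical inputs give byte-identical files.
#'
#' @param report A [design_report()].
#' @param path Output path.
#' @param fmt `"text"` or `"html"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, fmt = c("text", "html")) {
  fmt <- match.arg(fmt)
  lines <- report_lines(report)
  if (fmt == "html") {
    esc <- gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", lines)))
    lines <- c("<!DOCTYPE html>", "<html><head><title>pocket design report",
               "</title></head><body><pre>", esc, "</pre></body></html>")
  }
  writeLines(lines, path)
  invisible(path)
}
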