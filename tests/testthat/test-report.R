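# Design output: structure writing with round-trip rescoring, the
# ranking operator, RMSD operators and deterministic report rendering.

toy_solution <- function() {
  d <- toy_design()
  sol <- solve_gmec(d$tables)
  list(d = d, sol = sol)
}

test_that("designed structure contains scaffold + chosen rotamers +
           ligand", {
  ts <- toy_solution()
  d <- ts$d
  f <- tempfile(fileext = ".pdb")
  atoms <- write_design_structure(d$pocket, ts$sol, d$rotamers, d$poses, f)
  n_rot_atoms <- sum(vapply(seq_along(d$rotamers$by_position), function(p)
    nrow(d$rotamers$by_position[[p]]$rotamers[[
      ts$sol$rotamer_choice[p]]]$atoms), integer(1)))
  expect_equal(nrow(atoms),
               nrow(d$pocket$fixed) + n_rot_atoms +
                 nrow(d$poses$poses[[1]]$atoms))
  lines <- readLines(f)
  expect_equal(sum(grepl("^HETATM", lines)),
               nrow(d$poses$poses[[1]]$atoms))
})

test_that("re-reading and re-scoring a written design reproduces the
           solution energies", {
  ts <- toy_solution()
  d <- ts$d
  sol <- ts$sol
  f <- tempfile(fileext = ".pdb")
  write_design_structure(d$pocket, sol, d$rotamers, d$poses, f)
  at <- pocketdesign:::read_pdb_atoms(f, hetatm = TRUE)
  prot <- at[at$resid != "LIG", ]
  lig <- at[at$resid == "LIG", ]
  prot <- attach_params(prot, d$bundle$params)
  ligp <- read_param_table(d$bundle$paths$ligand_params)
  lig <- attach_params(lig, ligp)
  # rebuild variable/fixed split from the known design positions
  design_keys <- vapply(d$pocket$positions, function(p)
    paste0(p$chain, ":", p$resno), character(1))
  keys <- paste0(prot$chain, ":", prot$resno)
  fixed <- prot[!(keys %in% design_keys) | prot$backbone |
                  prot$elety == "CA", ]
  packing <- 0
  groups <- list()
  for (k in design_keys) {
    g <- prot[keys == k & !prot$backbone & prot$elety != "CA", ]
    groups[[k]] <- g
    packing <- packing +
      ff_interaction(g, fixed, exclusions = group_exclusions(g, fixed))
  }
  packing <- packing + ff_interaction(groups[[1]], groups[[2]])
  binding <- vina_score(lig, prot)
  # 1e-3 A coordinate precision in PDB limits agreement
  expect_equal(packing, sol$packing_energy, tolerance = 2e-2)
  expect_equal(binding, sol$binding_energy_raw, tolerance = 1e-3)
})

test_that("rank_pair implements the affinity criterion with tie and swap
           properties", {
  mk <- function(binding, total) list(binding_energy_raw = binding,
                                      total_energy = total)
  # stronger binder scored lower -> correct
  v <- rank_pair(low_affinity = mk(-8.0, -3), high_affinity = mk(-12.1, -5))
  expect_true(v$correct_binding)
  expect_true(v$correct_total)
  # swap flips the verdict
  v2 <- rank_pair(low_affinity = mk(-12.1, -5), high_affinity = mk(-8.0, -3))
  expect_false(v2$correct_binding)
  expect_false(v2$correct_total)
  # exact tie: conservative incorrect with warning
  expect_warning(v3 <- rank_pair(mk(-5, 0), mk(-5, 1)), "tie")
  expect_false(v3$correct_binding)
  # binding and total verdicts are independent columns
  v4 <- rank_pair(low_affinity = mk(-8, -10), high_affinity = mk(-12, -4))
  expect_true(v4$correct_binding)
  expect_false(v4$correct_total)
})

test_that("pocket RMSD is zero for rigid copies and matches the direct
           formula for a constructed displacement", {
  ts <- toy_solution()
  d <- ts$d
  ref <- assemble_design(d$pocket, ts$sol, d$rotamers, d$poses)
  flex <- vapply(d$pocket$positions, function(p)
    paste0(p$chain, ":", p$resno), character(1))
  expect_equal(pocket_rmsd(ref, ref, flex), 0, tolerance = 1e-12)
  # rigidly moved copy: superposition removes the motion
  set.seed(51)
  moved <- set_atom_xyz(ref, rigid_transform(atom_xyz(ref),
                                             runif(3, -180, 180),
                                             rnorm(3, sd = 8)))
  expect_lt(pocket_rmsd(ref, moved, flex), 1e-6)
  expect_lt(ligand_rmsd(ref, moved), 1e-6)
  # constructed case: 4-atom side chain, one atom displaced by 1 A,
  # backbone identical -> RMSD sqrt(1^2/4) = 0.5
  bb <- mk_atoms(rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0),
                       c(3.4, 1.4, 0.1)),
                 elety = c("N", "CA", "C", "O"), resid = "ASP",
                 resno = 1L)
  bb$backbone <- TRUE
  sc <- mk_atoms(rbind(c(1.9, -1.4, 0.4), c(3.2, -2.1, 0.2),
                       c(3.3, -3.3, 0.6), c(4.2, -1.5, -0.4)),
                 elety = c("CB", "CG", "OD1", "OD2"), resid = "ASP",
                 resno = 1L)
  ref4 <- rbind(bb, sc)
  des4 <- ref4
  des4$x[des4$elety == "OD1"] <- des4$x[des4$elety == "OD1"] + 1
  expect_equal(pocket_rmsd(ref4, des4, "A:1"), 0.5, tolerance = 1e-9)
})

test_that("reports render deterministically and HTML is well-formed", {
  ts <- toy_solution()
  rep <- design_report(ts$d$tables, list(ts$sol),
                       provenance = list(config = "abc"))
  f1 <- tempfile(fileext = ".txt")
  f2 <- tempfile(fileext = ".txt")
  render_report(rep, f1, "text")
  render_report(rep, f2, "text")
  expect_identical(readLines(f1), readLines(f2))
  txt <- readLines(f1)
  expect_true(any(grepl(sprintf("total energy: %.4f",
                                ts$sol$total_energy), txt, fixed = TRUE)))
  # breakdown lines sum to the reported totals
  grab <- function(pat) {
    as.numeric(sub(".*: ", "", grep(pat, txt, value = TRUE)))
  }
  expect_equal(grab("packing energy") + grab("binding energy \\(scaled\\)"),
               grab("total energy"), tolerance = 1e-3)
  h <- tempfile(fileext = ".html")
  render_report(rep, h, "html")
  expect_silent(xml2::read_html(h))
})
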