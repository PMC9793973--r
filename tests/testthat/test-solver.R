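# GMEC solving: ILP formulation counts, oracle equivalence, tie-breaks,
# N-best enumeration, planted-optimum recovery.

test_that("ILP variable and constraint counts follow the formulation", {
  tb <- random_energy_tables(1, c(2, 2), 2)
  ilp <- build_ilp(tb)
  # 2+2 rotamer nodes + 2 pose nodes
  expect_equal(ilp$n_node, 6)
  # edges: pos1-pos2 (4) + pos1-lig (4) + pos2-lig (4)
  expect_equal(ilp$n_var - ilp$n_node, 12)
  # rows: 3 assignment + per pair 2+2 consistency
  expect_equal(nrow(ilp$A), 3 + 3 * 4)
  # forced degenerate instance: all variables 1
  tb1 <- random_energy_tables(2, c(1), 1)
  res <- pocketdesign:::ilp_solve_once(build_ilp(tb1))
  expect_true(res$feasible)
  expect_equal(res$x, rep(1, 3))  # 2 nodes + 1 edge
})

test_that("a single position reduces to the argmin of self energies", {
  tb <- random_energy_tables(3, c(3), 1)
  tb$self_packing[[1]] <- c(3, 1, 2)
  tb$lig_self <- 0
  tb$lig_pair <- list(matrix(0, 1, 3))
  sol <- solve_gmec(tb)
  expect_equal(sol$rotamer_choice, 2L)
  expect_equal(sol$total_energy, 1.0)
  # objective at a forced assignment equals the table sum
  bf <- brute_force_gmec(tb)
  expect_equal(bf$rotamer_choice, 2L)
})

test_that("solver matches the exhaustive oracle on random instances", {
  for (s in 1:40) {
    shape <- list(c(3, 4), c(2, 3, 4), c(5, 5))[[1 + s %% 3]]
    tb <- random_energy_tables(s, shape, 4 + s %% 4)
    sol <- solve_gmec(tb)
    bf <- brute_force_gmec(tb)
    expect_equal(sol$total_energy, bf$total_energy, tolerance = 1e-9)
    expect_identical(c(sol$rotamer_choice, sol$pose_choice),
                     c(bf$rotamer_choice, bf$pose_choice))
    # rescoring identity
    e <- assignment_energy(tb, sol$rotamer_choice, sol$pose_choice)
    expect_equal(sol$total_energy, e$total, tolerance = 1e-12)
    expect_equal(sol$total_energy,
                 sol$packing_energy + sol$binding_energy_scaled,
                 tolerance = 1e-9)
  }
})

test_that("degenerate optima break ties to the lexicographically smallest
           assignment", {
  tb <- random_energy_tables(5, c(2, 2), 2)
  tb$self_packing <- list(c(0, 0), c(0, 0))
  tb$pair_packing[["1|2"]] <- matrix(0, 2, 2)
  tb$lig_self <- c(0, 0)
  tb$lig_pair <- list(matrix(0, 2, 2), matrix(0, 2, 2))
  sol <- solve_gmec(tb)
  expect_identical(c(sol$rotamer_choice, sol$pose_choice), c(1L, 1L, 1L))
  bf <- brute_force_gmec(tb)
  expect_identical(c(bf$rotamer_choice, bf$pose_choice), c(1L, 1L, 1L))
  # partial tie: two equal optima differing at position 2
  tb$self_packing[[1]] <- c(0, -5)
  sol2 <- solve_gmec(tb)
  expect_identical(c(sol2$rotamer_choice, sol2$pose_choice),
                   c(2L, 1L, 1L))
})

test_that("brute force refuses oversized instances and separable ones
           reduce to independent argmins", {
  big <- random_energy_tables(6, c(110, 110), 110)
  expect_error(brute_force_gmec(big), "too large")
  tb <- random_energy_tables(7, c(4, 3), 5)
  tb$pair_packing[["1|2"]] <- matrix(0, 4, 3)
  tb$lig_pair <- list(matrix(0, 5, 4), matrix(0, 5, 3))
  bf <- brute_force_gmec(tb)
  expect_equal(bf$rotamer_choice,
               c(which.min(tb$self_packing[[1]]),
                 which.min(tb$self_packing[[2]])))
  expect_equal(bf$pose_choice, which.min(tb$lig_self))
})

test_that("enumerate_best returns the exhaustive n-smallest list", {
  tb <- random_energy_tables(8, c(3, 3), 4)
  n <- 5
  best <- enumerate_best(tb, n)
  totals <- vapply(best, `[[`, numeric(1), "total_energy")
  expect_true(all(diff(totals) >= -1e-9))
  # exhaustive sorted list
  arr <- pocketdesign:::assignment_energy_array(tb)
  expect_equal(totals, sort(as.vector(arr))[seq_len(n)], tolerance = 1e-9)
  # assignments distinct
  keys <- vapply(best, function(s)
    paste(c(s$rotamer_choice, s$pose_choice), collapse = ","),
    character(1))
  expect_false(anyDuplicated(keys) > 0)
  # n = 1 equals solve_gmec
  expect_equal(enumerate_best(tb, 1)[[1]], solve_gmec(tb))
  # n beyond the assignment count returns everything with a warning
  tiny <- random_energy_tables(9, c(2), 2)
  expect_warning(all4 <- enumerate_best(tiny, 10), "exist")
  expect_length(all4, 4)
})

test_that("planted optima are recovered exactly; zero margin plants a
           tie", {
  for (s in 1:25) {
    inst <- make_known_optimum_instance(s)
    sol <- solve_gmec(inst$tables)
    expect_identical(sol$rotamer_choice, inst$planted$rot_idx)
    expect_identical(sol$pose_choice, inst$planted$pose_idx)
    bf <- brute_force_gmec(inst$tables)
    expect_identical(bf$rotamer_choice, inst$planted$rot_idx)
  }
  # margin 0: the planted assignment is among the optima
  inst0 <- make_known_optimum_instance(99, margin = 0)
  sol0 <- solve_gmec(inst0$tables)
  e_planted <- assignment_energy(inst0$tables, inst0$planted$rot_idx,
                                 inst0$planted$pose_idx)
  expect_lte(sol0$total_energy, e_planted$total + 1e-9)
})

test_that("LP export round-trips the objective structure", {
  tb <- random_energy_tables(10, c(2, 2), 2)
  ilp <- build_ilp(tb)
  f <- tempfile(fileext = ".lp")
  write_lp(ilp, f)
  lines <- readLines(f)
  expect_equal(lines[1], "Minimize")
  expect_true(any(grepl("Binary", lines)))
  expect_equal(sum(grepl("^ c", lines)), nrow(ilp$A))
})
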