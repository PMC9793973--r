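# Closed-form checks of the scoring primitives and brute-force oracles
# for the pairwise force-field evaluation.

test_that("Lennard-Jones minimum, root and tail follow the 12-6 form", {
  a <- list(epsilon = 0.25, rmin_half = 1.7)
  b <- list(epsilon = 0.16, rmin_half = 2.1)
  eps <- sqrt(0.25 * 0.16)
  rmin <- 1.7 + 2.1
  expect_equal(lj_energy(a, b, rmin), -eps, tolerance = 1e-12)
  expect_equal(lj_energy(a, b, rmin / 2^(1 / 6)), 0, tolerance = 1e-12)
  expect_lt(lj_energy(a, b, 50), 0)          # approaches zero from below
  expect_gt(lj_energy(a, b, 50), -1e-6)
  expect_gt(lj_energy(a, b, rmin / 2), 500)  # steep repulsion
  expect_error(lj_energy(a, b, 0), "r must be")
})

test_that("Coulomb term matches the configured constant", {
  qi <- list(charge = 1)
  qj <- list(charge = 1)
  expect_equal(coulomb_energy(qi, qj, 1), 332.0636)
  expect_equal(coulomb_energy(qi, list(charge = -1), 2), -166.0318)
  expect_equal(coulomb_energy(list(charge = 0), qj, 1.3), 0)
  expect_error(coulomb_energy(qi, qj, 0), "r must be")
})

test_that("ff_interaction equals a hand-rolled pair loop", {
  set.seed(21)
  a <- mk_atoms(matrix(rnorm(9, sd = 2), 3, 3),
                charge = c(0.3, -0.2, 0.1),
                rmin_half = c(1.9, 1.7, 1.66), epsilon = c(0.1, 0.2, 0.15))
  b <- mk_atoms(matrix(rnorm(6, sd = 2) + 5, 2, 3),
                charge = c(-0.4, 0.25), rmin_half = c(1.8, 2.0),
                epsilon = c(0.12, 0.21), resno = 2L)
  expect_equal(ff_interaction(a, b), brute_ff(a, b), tolerance = 1e-12)
  # with exclusions and 1-4 scaling
  excl <- list(excl = cbind(1L, 1L), pair14 = cbind(c(2L, 3L), c(1L, 2L)))
  expect_equal(ff_interaction(a, b, exclusions = excl),
               brute_ff(a, b, exclusions = excl), tolerance = 1e-12)
  # groups far apart decay to ~0
  far <- mk_atoms(matrix(rnorm(6) + 100, 2, 3), charge = 0)
  expect_lt(abs(ff_interaction(a, far)), 1e-6)
})

test_that("Vina terms reproduce their closed forms at anchor points", {
  w1 <- vina_weights(gauss1 = 1, gauss2 = 0, repulsion = 0,
                     hydrophobic = 0, hbond = 0)
  # two heavy atoms at surface distance 0 (r = sum of radii)
  at <- function(x, class = "none", vdw = 1.9)
    mk_atoms(c(x, 0, 0), class = class, vdw_radius = vdw)
  expect_equal(vina_score(at(0), at(3.8), w1), 1.0, tolerance = 1e-12)
  w2 <- vina_weights(gauss1 = 0, gauss2 = 1, repulsion = 0,
                     hydrophobic = 0, hbond = 0)
  expect_equal(vina_score(at(0), at(3.8), w2), exp(-2.25),
               tolerance = 1e-12)
  # d = -1: repulsion d^2 with weight 1
  wr <- vina_weights(gauss1 = 0, gauss2 = 0, repulsion = 1,
                     hydrophobic = 0, hbond = 0)
  expect_equal(vina_score(at(0), at(2.8), wr), 1.0, tolerance = 1e-12)
  # hydrophobic ramp midpoint: d = 1.0 -> 0.5 before weighting
  wh <- vina_weights(gauss1 = 0, gauss2 = 0, repulsion = 0,
                     hydrophobic = 2, hbond = 0)
  expect_equal(vina_score(at(0, "hydrophobic"), at(4.8, "hydrophobic"), wh),
               1.0, tolerance = 1e-12)
  # hbond ramp: donor-acceptor at d = -0.35 -> 0.5
  wb <- vina_weights(gauss1 = 0, gauss2 = 0, repulsion = 0,
                     hydrophobic = 0, hbond = 2)
  expect_equal(vina_score(at(0, "donor"), at(3.45, "acceptor"), wb), 1.0,
               tolerance = 1e-12)
  # like classes do not form hbonds
  expect_equal(vina_score(at(0, "donor"), at(3.45, "donor"), wb), 0)
  # beyond the cutoff nothing is scored
  expect_equal(vina_score(at(0), at(8.1), vina_weights()), 0)
})

test_that("vina_score is invariant under joint rigid motion", {
  d <- toy_design()
  lig <- d$poses$poses[[1]]$atoms
  rec <- d$pocket$fixed
  base <- vina_score(lig, rec)
  expect_true(is.finite(base))
  for (k in 1:5) {
    set.seed(30 + k)
    ang <- runif(3, -180, 180)
    sh <- rnorm(3, sd = 10)
    lig2 <- set_atom_xyz(lig, rigid_transform(atom_xyz(lig), ang, sh))
    rec2 <- set_atom_xyz(rec, rigid_transform(atom_xyz(rec), ang, sh))
    expect_equal(vina_score(lig2, rec2), base, tolerance = 1e-9)
  }
})

test_that("bonded exclusions across the CA/CB cut are classified by bond
           count", {
  d <- toy_design()
  pos1 <- d$rotamers$by_position[[1]]
  rot <- pos1$rotamers[[1]]
  fixed <- d$pocket$fixed
  excl <- group_exclusions(rot$atoms, fixed)
  lab <- function(m) {
    apply(m, 1, function(ij)
      paste(rot$atoms$elety[ij[1]], fixed$elety[ij[2]],
            fixed$resno[ij[2]], sep = "-"))
  }
  resno <- pos1$position$resno
  e <- lab(excl$excl)
  # CB-CA: 1 bond; CB-N and CB-C: 2 bonds -> excluded
  expect_true(all(c(paste0("CB-CA-", resno), paste0("CB-N-", resno),
                    paste0("CB-C-", resno)) %in% e))
  p14 <- lab(excl$pair14)
  # 3-bond pairs: CB to O and to the peptide neighbors
  expect_true(paste0("CB-O-", resno) %in% p14)
  expect_true(paste0("CB-C-", resno - 1) %in% p14)
  expect_true(paste0("CB-N-", resno + 1) %in% p14)
  # nothing beyond the bonded neighborhood is touched
  expect_true(all(fixed$resno[excl$excl[, 2]] %in%
                    (resno - 1):(resno + 1)))
})
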