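# Rotamer construction: backbone dihedral measurement, exact chi
# application, rigid-group behavior and scaffold-clash pruning.

test_that("ideal helix fixture measures (phi, psi) near (-57, -47)", {
  b <- toy_bundle()
  for (resno in 2:5) {
    pp <- backbone_dihedrals(b$scaffold, "A", resno)
    expect_equal(pp[["phi"]], -57, tolerance = 2 / 57)
    expect_equal(pp[["psi"]], -47, tolerance = 2 / 47)
  }
  expect_error(backbone_dihedrals(b$scaffold, "A", 1), "terminus")
})

test_that("requested chi angles are reproduced within 0.5 degrees", {
  b <- toy_bundle()
  pos <- list(chain = "A", resno = 3, native = "SER",
              allowed_aas = "SER", is_mutable = FALSE)
  for (aa in c("SER", "LEU", "ASP", "PHE")) {
    rots <- build_rotamers(b$scaffold, pos, aa, b$library, b$params)
    lib_entries <- library_lookup(b$library, aa, -57, -47)
    expect_length(rots, length(lib_entries))
    for (k in seq_along(rots)) {
      r <- rots[[k]]
      expect_equal(r$prob, lib_entries[[k]]$prob)
      coords <- c(r$frame, stats::setNames(
        lapply(seq_len(nrow(r$atoms)), function(i)
          as.numeric(r$atoms[i, c("x", "y", "z")])), r$atoms$elety))
      for (ci in seq_along(r$chis)) {
        measured <- pocketdesign:::measure_chi(aa, ci, coords)
        delta <- (measured - r$chis[ci] + 180) %% 360 - 180
        expect_lt(abs(delta), 0.5)
      }
    }
  }
})

test_that("bond lengths in built side chains match the template", {
  b <- toy_bundle()
  pos <- list(chain = "A", resno = 4, native = "ASP",
              allowed_aas = "LEU", is_mutable = TRUE)
  r <- build_rotamers(b$scaffold, pos, "LEU", b$library, b$params)[[1]]
  tmpl <- pocketdesign:::SIDE_CHAIN_TEMPLATES$LEU
  coords <- c(r$frame, stats::setNames(
    lapply(seq_len(nrow(r$atoms)), function(i)
      as.numeric(r$atoms[i, c("x", "y", "z")])), r$atoms$elety))
  for (i in seq_len(nrow(tmpl))) {
    d <- sqrt(sum((coords[[tmpl$atom[i]]] - coords[[tmpl$parent[i]]])^2))
    expect_equal(d, tmpl$bond[i], tolerance = 1e-3 / tmpl$bond[i])
  }
})

test_that("distances across atoms not separated by a chi axis are
           invariant under chi changes", {
  b <- toy_bundle()
  f <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0),
            C = as.numeric(place_atom(c(0, 0, 1), c(0, 0, 0),
                                      c(1.458, 0, 0), 1.525, 111.2, -35)))
  sc1 <- build_side_chain("LEU", f$N, f$CA, f$C, c(-60, 180))
  sc2 <- build_side_chain("LEU", f$N, f$CA, f$C, c(65, -40))
  # CB-CG bonded across chi2 axis only via CG: CB/CG inter-distance and
  # the CD1-CD2 geminal distance are chi-invariant
  dist_of <- function(sc, a1, a2) {
    p <- function(n) as.numeric(sc[sc$atom == n, c("x", "y", "z")])
    sqrt(sum((p(a1) - p(a2))^2))
  }
  expect_equal(dist_of(sc1, "CB", "CG"), dist_of(sc2, "CB", "CG"),
               tolerance = 1e-9)
  expect_equal(dist_of(sc1, "CD1", "CD2"), dist_of(sc2, "CD1", "CD2"),
               tolerance = 1e-9)
  expect_equal(dist_of(sc1, "CG", "CD1"), dist_of(sc2, "CG", "CD1"),
               tolerance = 1e-9)
})

test_that("ALA yields a single chi-free rotamer; empty bins warn", {
  b <- toy_bundle()
  pos <- list(chain = "A", resno = 3, native = "SER",
              allowed_aas = "ALA", is_mutable = TRUE)
  rots <- build_rotamers(b$scaffold, pos, "ALA", b$library, b$params)
  expect_length(rots, 1)
  expect_length(rots[[1]]$chis, 0)
  expect_identical(rots[[1]]$atoms$elety, "CB")
  expect_warning(
    out <- build_rotamers(b$scaffold, pos, "LYS", b$library, b$params),
    "no LYS entries")
  expect_length(out, 0)
})

test_that("pruning is a pure threshold filter on scaffold LJ energy", {
  d <- toy_design()
  b <- d$bundle
  pocket <- d$pocket
  # recompute candidate set without pruning and verify the filter
  for (k in seq_along(pocket$positions)) {
    p <- pocket$positions[[k]]
    all_rots <- list()
    for (aa in p$allowed_aas)
      all_rots <- c(all_rots,
                    build_rotamers(b$scaffold, p, aa, b$library, b$params))
    vdw <- vapply(all_rots, function(r) {
      excl <- group_exclusions(r$atoms, pocket$fixed)
      brute_ff_lj <- 0
      for (i in seq_len(nrow(r$atoms))) for (j in seq_len(nrow(pocket$fixed))) {
        if (nrow(excl$excl) > 0 &&
            any(excl$excl[, 1] == i & excl$excl[, 2] == j)) next
        rij <- sqrt(sum((as.numeric(r$atoms[i, c("x", "y", "z")]) -
                           as.numeric(pocket$fixed[j, c("x", "y", "z")]))^2))
        scale <- if (nrow(excl$pair14) > 0 &&
                       any(excl$pair14[, 1] == i & excl$pair14[, 2] == j))
          ff_params()$lj_14_scale else 1
        brute_ff_lj <- brute_ff_lj +
          scale * lj_energy(r$atoms[i, ], pocket$fixed[j, ], rij)
      }
      brute_ff_lj
    }, numeric(1))
    kept_expected <- which(vdw < 100)
    kept_set <- d$rotamers$by_position[[k]]
    expect_length(kept_set$rotamers, length(kept_expected))
    expect_equal(kept_set$scaffold_vdw, vdw[kept_expected],
                 tolerance = 1e-9)
    expect_equal(kept_set$n_pruned, sum(vdw >= 100))
  }
  # the toy system plants at least one clashing and one viable rotamer
  expect_gt(sum(vapply(d$rotamers$by_position, `[[`, integer(1),
                       "n_pruned")), 0)
})

test_that("a position with every rotamer pruned is a hard error", {
  d <- toy_design()
  expect_error(
    build_rotamer_set(d$pocket, d$bundle$library, d$bundle$params,
                      vdw_prune_threshold = -1e9),
    "no viable rotamers")
})
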