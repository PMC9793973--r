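# Nonbonded energy core. Two tracks:
#  - packing: Lennard-Jones (12-6, Rmin/epsilon combination) + Coulomb,
#    with 1-2/1-3 exclusions and 1-4 scaling across the CA/CB cut;
#  - binding: Vina-style empirical pairwise score over heavy atoms
#    (two gaussians, quadratic repulsion, hydrophobic and H-bond ramps on
#    the surface distance), interaction rescoring only - no rotatable-bond
#    entropy term.

#' Lennard-Jones pair energy
#'
#' 12-6 potential in Rmin/epsilon form:
#' E = eps * ((rmin/r)^12 - 2 (rmin/r)^6) with rmin = rmin_half_i +
#' rmin_half_j and eps = sqrt(eps_i * eps_j). Minimum -eps at r = rmin;
#' zero crossing at r = rmin / 2^(1/6).
#'
#' @param atom_i,atom_j Single-row atom tables (or lists) with fields
#'   `rmin_half` and `epsilon`.
#' @param r Interatomic distance, Angstrom (> 0).
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(atom_i, atom_j, r) {
  if (any(r <= 0)) stop("lj_energy: r must be > 0")
  eps <- sqrt(atom_i$epsilon * atom_j$epsilon)
  q <- ((atom_i$rmin_half + atom_j$rmin_half) / r)^6
  eps * (q^2 - 2 * q)
}

#' Coulomb pair energy
#'
#' E = k q_i q_j / r with k the configured Coulomb constant
#' (332.0636 kcal A / (mol e^2) by default).
#'
#' @param atom_i,atom_j Single-row atom tables (or lists) with field
#'   `charge` (elementary charge units).
#' @param r Interatomic distance, Angstrom (> 0).
#' @param coulomb_constant kcal A / (mol e^2).
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(atom_i, atom_j, r, coulomb_constant = 332.0636) {
  if (any(r <= 0)) stop("coulomb_energy: r must be > 0")
  coulomb_constant * atom_i$charge * atom_j$charge / r
}

#' Force-field interaction energy between two atom groups
#'
#' Sum of Lennard-Jones and Coulomb terms over all cross pairs (strictly
#' inter-group). Pairs separated by one or two bonds are excluded; pairs
#' separated by exactly three bonds are scaled by the force field's 1-4
#' factors. Bond separations are supplied via `exclusions`.
#'
#' @param atoms_a,atoms_b Atom tables with parameters attached.
#' @param ff [ff_params()].
#' @param exclusions `NULL`, or a list with integer pair matrices `excl`
#'   (columns: row in a, row in b; fully excluded) and `pair14` (1-4
#'   scaled); see [group_exclusions()].
#' @param terms `"both"`, `"lj"` or `"coulomb"`.
#' @return Energy in kcal/mol.
#' @export
ff_interaction <- function(atoms_a, atoms_b, ff = ff_params(),
                           exclusions = NULL,
                           terms = c("both", "lj", "coulomb")) {
  terms <- match.arg(terms)
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) return(0)
  r <- cross_dist(atom_xyz(atoms_a), atom_xyz(atoms_b))
  f_lj <- matrix(1, nrow(atoms_a), nrow(atoms_b))
  f_c <- f_lj
  if (!is.null(exclusions)) {
    if (nrow(exclusions$excl) > 0) {
      f_lj[exclusions$excl] <- 0
      f_c[exclusions$excl] <- 0
    }
    if (nrow(exclusions$pair14) > 0) {
      f_lj[exclusions$pair14] <- ff$lj_14_scale
      f_c[exclusions$pair14] <- ff$coulomb_14_scale
    }
  }
  live <- f_lj != 0 | f_c != 0
  if (any(r[live] == 0))
    stop("coincident atoms (r = 0) in nonbonded evaluation")
  e <- 0
  if (terms %in% c("both", "lj")) {
    eps <- sqrt(outer(atoms_a$epsilon, atoms_b$epsilon))
    q <- (outer(atoms_a$rmin_half, atoms_b$rmin_half, "+") / pmax(r, 1e-12))^6
    e <- e + sum(f_lj * eps * (q^2 - 2 * q))
  }
  if (terms %in% c("both", "coulomb")) {
    e <- e + sum(f_c * ff$coulomb_constant *
                   outer(atoms_a$charge, atoms_b$charge) / pmax(r, 1e-12))
  }
  e
}

#' Empirical binding-score weights
#'
#' Defaults are the published AutoDock Vina weights; all five weights and
#' the pair cutoff are configurable.
#'
#' @param gauss1,gauss2,repulsion,hydrophobic,hbond Term weights
#'   (dimensionless).
#' @param cutoff Pair distance cutoff in Angstrom (center-center).
#' @return Object of class `scoring_weights`.
#' @export
vina_weights <- function(gauss1 = -0.035579, gauss2 = -0.005156,
                         repulsion = 0.840245, hydrophobic = -0.035069,
                         hbond = -0.587439, cutoff = 8.0) {
  stopifnot(cutoff > 0)
  structure(list(gauss1 = gauss1, gauss2 = gauss2, repulsion = repulsion,
                 hydrophobic = hydrophobic, hbond = hbond, cutoff = cutoff),
            class = "scoring_weights")
}

# Piecewise-linear ramp: 1 for d <= a, 0 for d >= b, linear between.
vina_ramp <- function(d, a, b) {
  pmin(1, pmax(0, (b - d) / (b - a)))
}

#' Vina-style protein-ligand interaction score
#'
#' Heavy atoms only. For each pair within the cutoff, the surface
#' distance d = r - (vdw_radius_i + vdw_radius_j) enters:
#' gauss1 exp(-(d/0.5)^2) + gauss2 exp(-((d-3)/2)^2) +
#' repulsion d^2 [d<0] + hydrophobic ramp(d; 0.5, 1.5) (both atoms
#' hydrophobic) + hbond ramp(d; -0.7, 0) (donor-acceptor pair).
#'
#' @param ligand_atoms,receptor_atoms Atom tables with `vdw_radius` and
#'   `class` attached.
#' @param weights [vina_weights()].
#' @return Score (score units; more negative = more favorable).
#' @export
vina_score <- function(ligand_atoms, receptor_atoms,
                       weights = vina_weights()) {
  la <- ligand_atoms[!ligand_atoms$is_h, , drop = FALSE]
  ra <- receptor_atoms[!receptor_atoms$is_h, , drop = FALSE]
  if (nrow(la) == 0 || nrow(ra) == 0) return(0)
  r <- cross_dist(atom_xyz(la), atom_xyz(ra))
  sel <- r <= weights$cutoff
  if (!any(sel)) return(0)
  d <- (r - outer(la$vdw_radius, ra$vdw_radius, "+"))[sel]
  phobic <- outer(la$class == "hydrophobic", ra$class == "hydrophobic",
                  "&")[sel]
  hb <- (outer(la$class == "donor", ra$class == "acceptor", "&") |
           outer(la$class == "acceptor", ra$class == "donor", "&"))[sel]
  sum(weights$gauss1 * exp(-(d / 0.5)^2) +
        weights$gauss2 * exp(-((d - 3) / 2)^2) +
        weights$repulsion * d^2 * (d < 0) +
        weights$hydrophobic * phobic * vina_ramp(d, 0.5, 1.5) +
        weights$hbond * hb * vina_ramp(d, -0.7, 0))
}

# Backbone bonds (by atom name) within one residue, used when assembling
# the small bond graph around a variable group.
BACKBONE_BONDS <- list(c("N", "CA"), c("CA", "C"), c("C", "O"),
                       c("C", "OXT"), c("N", "H"), c("N", "H1"),
                       c("N", "H2"), c("N", "H3"), c("CA", "HA"),
                       c("CA", "HA2"), c("CA", "HA3"))

#' Bonded exclusions between a variable group and the fixed scaffold
#'
#' Computes the atom pairs across the group/scaffold interface separated
#' by one or two bonds (excluded) or exactly three bonds (1-4 scaled).
#' Bonds are taken from the side-chain template of the group's residue
#' (falling back to a covalent-distance rule for native side chains),
#' plus the backbone bonds of the residue and its peptide neighbors.
#' Groups not rooted in a scaffold residue (ligand poses) have no bonded
#' pairs.
#'
#' @param group_atoms Atom table of the variable group (one residue).
#' @param fixed_atoms Fixed-scaffold atom table.
#' @return `NULL`, or `list(excl = , pair14 = )` of integer pair matrices
#'   (group row, fixed row).
#' @export
group_exclusions <- function(group_atoms, fixed_atoms) {
  if (nrow(group_atoms) == 0) return(NULL)
  ch <- group_atoms$chain[1]
  rn <- group_atoms$resno[1]
  nb <- which(fixed_atoms$chain == ch & abs(fixed_atoms$resno - rn) <= 1)
  if (length(nb) == 0) return(NULL)
  gn <- paste0("g", seq_len(nrow(group_atoms)))
  fn <- paste0("f", nb)
  name_of <- c(stats::setNames(gn, NULL), fn)
  vert <- data.frame(id = c(gn, fn),
                     elety = c(group_atoms$elety, fixed_atoms$elety[nb]),
                     resno = c(group_atoms$resno, fixed_atoms$resno[nb]),
                     stringsAsFactors = FALSE)
  edges <- character(0)
  add_edge <- function(id1, id2) edges <<- c(edges, id1, id2)
  vid <- function(elety, resno) {
    k <- which(vert$elety == elety & vert$resno == resno)
    if (length(k) == 0) NA_character_ else vert$id[k[1]]
  }
  # side-chain bonds of the group
  aa <- group_atoms$resid[1]
  tmpl <- SIDE_CHAIN_TEMPLATES[[aa]]
  is_template_group <- !is.null(tmpl) &&
    all(group_atoms$elety %in% c(tmpl$atom))
  if (is_template_group) {
    for (i in seq_len(nrow(tmpl))) {
      v1 <- vid(tmpl$atom[i], rn)
      v2 <- vid(tmpl$parent[i], rn)
      if (!is.na(v1) && !is.na(v2)) add_edge(v1, v2)
    }
  } else {
    # covalent-distance rule within the residue (native side chains)
    own <- which(vert$resno == rn)
    xyz <- rbind(atom_xyz(group_atoms),
                 atom_xyz(fixed_atoms[nb, , drop = FALSE]))
    h <- c(group_atoms$is_h, fixed_atoms$is_h[nb])
    d <- cross_dist(xyz[own, , drop = FALSE], xyz[own, , drop = FALSE])
    lim <- ifelse(outer(h[own], h[own], "|"), 1.3, 1.9)
    for (i in seq_along(own)) for (j in seq_along(own)) {
      if (i < j && d[i, j] < lim[i, j])
        add_edge(vert$id[own[i]], vert$id[own[j]])
    }
  }
  # backbone bonds of the residue and its neighbors, plus peptide links
  for (r in (rn - 1):(rn + 1)) {
    for (b in BACKBONE_BONDS) {
      v1 <- vid(b[1], r)
      v2 <- vid(b[2], r)
      if (!is.na(v1) && !is.na(v2)) add_edge(v1, v2)
    }
    v1 <- vid("C", r)
    v2 <- vid("N", r + 1)
    if (!is.na(v1) && !is.na(v2)) add_edge(v1, v2)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(vert), name = vert$id)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, match(edges, vert$id))
  dg <- igraph::distances(g, v = seq_len(nrow(group_atoms)),
                          to = nrow(group_atoms) + seq_along(nb))
  excl <- which(dg <= 2, arr.ind = TRUE)
  p14 <- which(dg == 3, arr.ind = TRUE)
  to_pairs <- function(m) {
    if (nrow(m) == 0) return(matrix(integer(0), 0, 2))
    cbind(m[, 1], nb[m[, 2]])
  }
  list(excl = to_pairs(excl), pair14 = to_pairs(p14))
}
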