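# GMEC search. The design problem - one rotamer per position plus one
# ligand pose minimizing the decomposed energy - is written as the
# classic side-chain-positioning integer linear program: binary node
# variables select a candidate per position, binary edge variables
# linearize the pairwise terms. The ligand enters as one extra position
# whose candidates are the poses (binding entries pre-scaled). Solved to
# proven optimality with the HiGHS MILP solver (scipy.optimize.milp);
# ties are broken to the lexicographically smallest index vector by an
# epsilon-free sequence of fixing re-solves. A brute-force enumerator
# over the full assignment space serves as an independent oracle.

.po_env <- new.env(parent = emptyenv())

scipy_optimize <- function() {
  if (!is.null(.po_env$scipy_opt)) return(.po_env$scipy_opt)
  if (!reticulate::py_available(initialize = FALSE)) {
    py <- Sys.which("python3")
    if (py == "") py <- Sys.which("python")
    if (py != "")
      try(reticulate::use_python(py, required = FALSE), silent = TRUE)
  }
  sp <- tryCatch(reticulate::import("scipy.optimize"),
                 error = function(e)
                   stop("ILP backend unavailable: python with scipy is ",
                        "required (", conditionMessage(e), ")"))
  .po_env$scipy_opt <- sp
  sp
}

# Candidate counts and per-position self/pair tables with the ligand as
# the last position; binding entries are pre-scaled here.
tables_to_instance <- function(tables) {
  n_pos <- length(tables$n_rot)
  counts <- c(tables$n_rot, tables$n_pose)
  P <- n_pos + 1L
  self <- c(tables$self_packing,
            list(tables$binding_scale * tables$lig_self))
  pair <- list()
  if (n_pos >= 2) {
    for (p in seq_len(n_pos - 1)) for (q in (p + 1):n_pos)
      pair[[paste(p, q, sep = "|")]] <-
        tables$pair_packing[[paste(p, q, sep = "|")]]
  }
  for (p in seq_len(n_pos))
    pair[[paste(p, P, sep = "|")]] <-
      tables$binding_scale * t(tables$lig_pair[[p]])
  list(counts = counts, self = self, pair = pair, P = P)
}

#' Build the GMEC integer linear program
#'
#' Binary node variables x[p,r] (one candidate r per position p, the
#' ligand being the last position) and binary edge variables y[p,r,q,s]
#' for every position pair, with consistency constraints
#' sum_r x[p,r] = 1 and sum_s y[p,r,q,s] = x[p,r]; the objective is the
#' sum of self terms over nodes and pair terms over edges.
#'
#' @param tables An `energy_tables` object.
#' @return Object of class `ilp_model` (objective, dense equality
#'   constraint matrix, variable index maps).
#' @export
build_ilp <- function(tables) {
  inst <- tables_to_instance(tables)
  counts <- inst$counts
  P <- inst$P
  if (any(counts < 1)) stop("every position needs at least one candidate")
  node_off <- c(0L, cumsum(counts))
  n_node <- node_off[P + 1]
  node_var <- function(p, r) node_off[p] + r
  edge_off <- integer(0)
  pair_keys <- names(inst$pair)
  n_edge <- 0L
  for (k in pair_keys) {
    edge_off[k] <- n_node + n_edge
    pq <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    n_edge <- n_edge + counts[pq[1]] * counts[pq[2]]
  }
  n_var <- n_node + n_edge
  # edge variable index: r-major within its block
  edge_var <- function(k, r, s) {
    pq <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    edge_off[k] + (r - 1L) * counts[pq[2]] + s
  }
  obj <- numeric(n_var)
  for (p in seq_len(P)) obj[node_var(p, seq_len(counts[p]))] <- inst$self[[p]]
  for (k in pair_keys) {
    pq <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    m <- inst$pair[[k]]
    for (r in seq_len(counts[pq[1]]))
      obj[edge_var(k, r, seq_len(counts[pq[2]]))] <- m[r, ]
  }
  n_row <- P + sum(vapply(pair_keys, function(k) {
    pq <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    counts[pq[1]] + counts[pq[2]]
  }, numeric(1)))
  A <- matrix(0, n_row, n_var)
  b <- numeric(n_row)
  row <- 0L
  for (p in seq_len(P)) {
    row <- row + 1L
    A[row, node_var(p, seq_len(counts[p]))] <- 1
    b[row] <- 1
  }
  for (k in pair_keys) {
    pq <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    for (r in seq_len(counts[pq[1]])) {
      row <- row + 1L
      A[row, edge_var(k, r, seq_len(counts[pq[2]]))] <- 1
      A[row, node_var(pq[1], r)] <- -1
    }
    for (s in seq_len(counts[pq[2]])) {
      row <- row + 1L
      A[row, edge_var(k, seq_len(counts[pq[1]]), s)] <- 1
      A[row, node_var(pq[2], s)] <- -1
    }
  }
  structure(list(counts = counts, P = P, n_node = n_node, n_var = n_var,
                 obj = obj, A = A, b = b, node_off = node_off,
                 pair_keys = pair_keys, edge_off = edge_off),
            class = "ilp_model")
}

# One HiGHS solve; fixed = integer vector of node variables forced to 1;
# cuts = list of node-variable index vectors with sum <= length - 1.
ilp_solve_once <- function(ilp, fixed = integer(0), cuts = list()) {
  sp <- scipy_optimize()
  lb <- numeric(ilp$n_var)
  ub <- rep(1, ilp$n_var)
  lb[fixed] <- 1
  cons <- list(sp$LinearConstraint(ilp$A, ilp$b, ilp$b))
  if (length(cuts) > 0) {
    Ac <- matrix(0, length(cuts), ilp$n_var)
    for (i in seq_along(cuts)) Ac[i, cuts[[i]]] <- 1
    cons <- c(cons, list(sp$LinearConstraint(
      Ac, rep(0, length(cuts)),
      vapply(cuts, length, numeric(1)) - 1)))
  }
  res <- sp$milp(c = ilp$obj, constraints = cons,
                 integrality = rep(1L, ilp$n_var),
                 bounds = sp$Bounds(lb, ub))
  if (isTRUE(res$success)) {
    list(feasible = TRUE, value = res$fun,
         x = as.numeric(res$x))
  } else if (res$status == 2L) {
    list(feasible = FALSE)
  } else {
    stop("MILP backend failure (status ", res$status, "): ", res$message)
  }
}

ilp_decode <- function(ilp, x) {
  vapply(seq_len(ilp$P), function(p)
    which.max(x[ilp$node_off[p] + seq_len(ilp$counts[p])]), integer(1))
}

make_solution <- function(tables, assign) {
  n_pos <- length(tables$n_rot)
  e <- assignment_energy(tables, assign[seq_len(n_pos)], assign[n_pos + 1])
  structure(list(rotamer_choice = assign[seq_len(n_pos)],
                 pose_choice = assign[n_pos + 1],
                 total_energy = e$total, packing_energy = e$packing,
                 binding_energy_raw = e$binding_raw,
                 binding_energy_scaled = e$binding_scaled),
            class = "design_solution")
}

#' @export
print.design_solution <- function(x, ...) {
  cat(sprintf(paste0("design_solution: rotamers [%s], pose %d | total ",
                     "%.4f = packing %.4f + scaled binding %.4f (raw %.4f)\n"),
              paste(x$rotamer_choice, collapse = ","), x$pose_choice,
              x$total_energy, x$packing_energy, x$binding_energy_scaled,
              x$binding_energy_raw))
  invisible(x)
}

#' Solve for the global minimum energy conformation
#'
#' Proven-optimal ILP solve, followed by an epsilon-free lexicographic
#' pass: position by position, the smallest candidate index that still
#' attains the optimal value is fixed, so among equally optimal
#' assignments the lexicographically smallest index vector is returned.
#'
#' @param tables An `energy_tables` object.
#' @param cuts Internal: exclusion cuts from [enumerate_best()].
#' @return A `design_solution`.
#' @export
solve_gmec <- function(tables, cuts = list()) {
  ilp <- build_ilp(tables)
  first <- ilp_solve_once(ilp, cuts = cuts)
  if (!first$feasible) stop("GMEC ILP infeasible")
  v_star <- first$value
  tol <- 1e-7 * max(1, abs(v_star))
  assign <- ilp_decode(ilp, first$x)
  # uniqueness probe: if no other assignment attains v_star, the
  # incumbent needs no lexicographic tie-break
  probe_cut <- list(vapply(seq_len(ilp$P), function(p)
    ilp$node_off[p] + assign[p], integer(1)))
  probe <- ilp_solve_once(ilp, cuts = c(cuts, probe_cut))
  if (!probe$feasible || probe$value > v_star + tol) {
    sol <- make_solution(tables, assign)
    if (abs(sol$total_energy - v_star) > 1e-6 * max(1, abs(v_star)))
      stop("solver objective and table recomputation disagree")
    return(sol)
  }
  fixed <- integer(0)
  for (p in seq_len(ilp$P)) {
    for (r in seq_len(ilp$counts[p])) {
      if (r == assign[p]) {  # incumbent is optimal; no solve needed
        fixed <- c(fixed, ilp$node_off[p] + r)
        break
      }
      trial <- ilp_solve_once(ilp, fixed = c(fixed, ilp$node_off[p] + r),
                              cuts = cuts)
      if (trial$feasible && trial$value <= v_star + tol) {
        assign <- ilp_decode(ilp, trial$x)
        fixed <- c(fixed, ilp$node_off[p] + r)
        break
      }
    }
  }
  sol <- make_solution(tables, assign)
  if (abs(sol$total_energy - v_star) > 1e-6 * max(1, abs(v_star)))
    stop("solver objective and table recomputation disagree")
  sol
}

#' Exhaustive GMEC oracle
#'
#' Enumerates every full assignment (product of candidate counts, capped
#' at 1e6), with the same lexicographic tie-break as [solve_gmec()].
#'
#' @param tables An `energy_tables` object.
#' @return A `design_solution`.
#' @export
brute_force_gmec <- function(tables) {
  arr <- assignment_energy_array(tables)
  sol <- pick_min_assignment(arr)
  make_solution(tables, sol)
}

# Dense array of total energies over all assignments, dims =
# (rotamers per position ..., poses).
assignment_energy_array <- function(tables) {
  counts <- c(tables$n_rot, tables$n_pose)
  if (prod(counts) > 1e6)
    stop("instance too large for brute force (", prod(counts),
         " assignments)")
  n_pos <- length(tables$n_rot)
  L <- n_pos + 1L
  arr <- array(0, dim = counts)
  for (p in seq_len(n_pos))
    arr <- arr + tables$self_packing[[p]][slice.index(arr, p)]
  arr <- arr + tables$binding_scale * tables$lig_self[slice.index(arr, L)]
  if (n_pos >= 2) {
    for (p in seq_len(n_pos - 1)) for (q in (p + 1):n_pos) {
      m <- tables$pair_packing[[paste(p, q, sep = "|")]]
      arr <- arr + m[cbind(as.vector(slice.index(arr, p)),
                           as.vector(slice.index(arr, q)))]
    }
  }
  for (p in seq_len(n_pos)) {
    m <- tables$lig_pair[[p]]
    arr <- arr + tables$binding_scale *
      m[cbind(as.vector(slice.index(arr, L)),
              as.vector(slice.index(arr, p)))]
  }
  arr
}

# Lexicographically smallest argmin subscript of an energy array.
pick_min_assignment <- function(arr, exclude = NULL) {
  v <- as.vector(arr)
  if (!is.null(exclude)) v[exclude] <- Inf
  m <- min(v)
  cand <- which(v <= m + 1e-9 * max(1, abs(m)))
  subs <- arrayInd(cand, dim(arr))
  as.integer(subs[do.call(order, as.data.frame(subs))[1], ])
}

#' Enumerate the N best design solutions
#'
#' Repeatedly re-solves the ILP, each time adding an exclusion cut
#' forbidding every previously returned assignment, yielding distinct
#' assignments with non-decreasing totals.
#'
#' @param tables An `energy_tables` object.
#' @param n Number of solutions requested (>= 1).
#' @return List of `design_solution`, best first. If `n` exceeds the
#'   number of assignments, all are returned with a warning.
#' @export
enumerate_best <- function(tables, n) {
  stopifnot(n >= 1)
  ilp <- build_ilp(tables)
  sols <- list()
  cuts <- list()
  for (i in seq_len(n)) {
    feas <- ilp_solve_once(ilp, cuts = cuts)
    if (!feas$feasible) {
      warning("only ", length(sols), " assignment(s) exist; n = ", n,
              " requested")
      break
    }
    sol <- solve_gmec(tables, cuts = cuts)
    sols[[i]] <- sol
    assign <- c(sol$rotamer_choice, sol$pose_choice)
    cuts[[i]] <- vapply(seq_len(ilp$P), function(p)
      ilp$node_off[p] + assign[p], integer(1))
  }
  sols
}

#' Export the GMEC ILP in LP file format
#'
#' Writes the model in CPLEX LP text format for inspection or for
#' solving with an external solver.
#'
#' @param ilp A [build_ilp()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(ilp, path) {
  vn <- paste0("v", seq_len(ilp$n_var))
  term <- function(coef, idx) {
    keep <- coef != 0
    paste(sprintf("%+.10g %s", coef[keep], vn[idx[keep]]), collapse = " ")
  }
  lines <- c("Minimize", paste(" obj:", term(ilp$obj, seq_len(ilp$n_var))),
             "Subject To")
  for (i in seq_len(nrow(ilp$A)))
    lines <- c(lines, sprintf(" c%d: %s = %.10g", i,
                              term(ilp$A[i, ], seq_len(ilp$n_var)),
                              ilp$b[i]))
  lines <- c(lines, "Binary", paste("", vn), "End")
  writeLines(lines, path)
  invisible(path)
}
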