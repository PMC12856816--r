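#' Build a minimum-set reserve-selection problem
#'
#' Assembles costs, the feature matrix, representation targets, and lock
#' constraints for one conservation objective. Objective 1 locks in the
#' existing protected estate (PA and IPA units) and leaves every other unit
#' available; Objective 2 additionally locks out all units whose tenure is
#' not Native Title (including pastoral-use), or Indigenous freehold —
#' expansion by voluntary declaration of Indigenous land only.
#'
#' Locked-in units count toward targets. Feasibility is checked up front:
#' if the available units cannot meet some target, an error reports the
#' per-species shortfall.
#'
#' @param pu a [build_pu_table()] result.
#' @param targets a [build_targets()] table (or named vector of absolute
#'   targets in km2).
#' @param objective 1 or 2.
#' @return an object of class `prior_problem`.
#' @export
build_problem <- function(pu, targets, objective = 1) {
  stopifnot(inherits(pu, "pu_table"), objective %in% 1:2)
  a <- pu$features
  cost <- pu$pus$cost
  T_abs <- if (inherits(targets, "target_table"))
    stats::setNames(targets$T_km2, targets$species) else targets
  T_abs <- T_abs[colnames(a)]
  T_abs[is.na(T_abs)] <- 0
  locked_in <- which(pu$pus$locked_in)
  locked_out <- integer(0)
  if (objective == 2) {
    eligible <- pu$pus$tenure %in%
      c("native_title", "native_title_pastoral", "indigenous_freehold")
    locked_out <- setdiff(which(!eligible), locked_in)
  }
  avail <- setdiff(seq_len(nrow(a)), locked_out)
  supply <- colSums(a[avail, , drop = FALSE])
  short <- T_abs - supply
  if (any(short > 1e-9)) {
    bad <- which(short > 1e-9)
    stopf("infeasible problem (objective %d); target shortfalls: %s",
          objective,
          paste(sprintf("%s=%.2f km2", colnames(a)[bad], short[bad]),
                collapse = ", "))
  }
  structure(list(cost = cost, features = a, targets = T_abs,
                 locked_in = locked_in, locked_out = locked_out,
                 objective = objective, n_pu = nrow(a)),
            class = "prior_problem")
}

#' @export
print.prior_problem <- function(x, ...) {
  cat(sprintf("<prior_problem> objective %d: %d PUs (%d locked in, %d locked out), %d targeted species\n",
              x$objective, x$n_pu, length(x$locked_in),
              length(x$locked_out), sum(x$targets > 0)))
  invisible(x)
}

#' Solve the minimum-set problem
#'
#' `method = "exact"` minimizes total cost subject to all representation
#' targets and lock constraints by depth-first branch and bound with a
#' Lagrangian dual lower bound (multipliers tuned by subgradient ascent at
#' the root) and a greedy incumbent. With `gap = 0` the returned solution is
#' proven optimal; among equal-cost optima the lexicographically smallest
#' selection (by PU id) is returned. If the node limit is hit, the best
#' incumbent is returned with status `"incumbent"`.
#'
#' `method = "greedy"` iteratively adds the unit with the largest capped
#' shortfall reduction per unit cost, then prunes redundant units.
#'
#' @param problem a [build_problem()] object.
#' @param method `"exact"` or `"greedy"`.
#' @param gap relative optimality gap accepted by the exact solver.
#' @param node_limit maximum branch-and-bound nodes.
#' @return an object of class `prior_solution`: `selected` (ids, including
#'   locked-in), `new` (newly selected ids), `cost_new`, `cost_total`,
#'   `status`, `nodes`, `objective`.
#' @export
solve_prioritization <- function(problem, method = c("exact", "greedy"),
                                 gap = 0, node_limit = 500000L) {
  method <- match.arg(method)
  p <- problem
  a <- p$features
  tol <- 1e-9
  contrib0 <- if (length(p$locked_in))
    colSums(a[p$locked_in, , drop = FALSE]) else rep(0, ncol(a))
  t_res <- pmax(0, p$targets - contrib0)
  active <- which(t_res > tol)
  cand <- setdiff(seq_len(p$n_pu), union(p$locked_in, p$locked_out))
  useful <- cand[colSums(t(a[cand, active, drop = FALSE]) > 0) > 0]
  res <- if (length(active) == 0L) {
    list(sel = integer(0), cost = 0, status = "optimal", nodes = 0L)
  } else if (method == "greedy") {
    g <- greedy_cover(p$cost, a, t_res, active, useful, tol)
    list(sel = g, cost = sum(p$cost[g]), status = "heuristic", nodes = 0L)
  } else {
    bb_cover(p$cost, a, t_res, active, useful, gap, node_limit, tol)
  }
  selected <- sort(union(p$locked_in, res$sel))
  structure(list(selected = selected, new = sort(res$sel),
                 cost_new = sum(p$cost[res$sel]),
                 cost_total = sum(p$cost[selected]),
                 status = res$status, nodes = res$nodes,
                 objective = p$objective, method = method),
            class = "prior_solution")
}

#' @export
print.prior_solution <- function(x, ...) {
  cat(sprintf("<prior_solution> objective %d (%s, %s): %d selected (%d new), new cost %.4f\n",
              x$objective, x$method, x$status, length(x$selected),
              length(x$new), x$cost_new))
  invisible(x)
}

# Greedy capped-coverage heuristic with redundancy pruning.
greedy_cover <- function(cost, a, t_res, active, cand, tol) {
  sel <- integer(0)
  s <- t_res[active]
  A <- a[, active, drop = FALSE]
  free <- cand
  while (any(s > tol)) {
    if (!length(free)) stopf("greedy could not meet all targets")
    gain <- as.numeric(pmin(A[free, , drop = FALSE],
                            rep(s, each = length(free))) %*% rep(1, length(s)))
    score <- gain / pmax(cost[free], 1e-12)
    best <- free[which(score == max(score))][1]
    sel <- c(sel, best)
    s <- pmax(0, s - A[best, ])
    free <- free[free != best]
  }
  # prune redundant picks, most expensive first (ties: higher id first)
  ord <- order(-cost[sel], -sel)
  for (i in sel[ord]) {
    rest <- setdiff(sel, i)
    if (all(colSums(A[rest, , drop = FALSE]) >= t_res[active] - tol))
      sel <- rest
  }
  sort(sel)
}

# Depth-first branch and bound for the covering problem
#   min c'x  s.t.  A x >= t,  x binary over `cand`.
# Lower bounds come from a Lagrangian dual (multipliers tuned by
# subgradient ascent at the root and reused down the tree); root
# reduced-cost fixing shrinks the variable set before search.
bb_cover <- function(cost, a, t_res, active, cand, gap, node_limit, tol) {
  A <- a[, active, drop = FALSE]
  t0 <- t_res[active]
  m <- length(active)
  # incumbent from greedy
  inc_sel <- tryCatch(greedy_cover(cost, a, t_res, active, cand, tol),
                      error = function(e) NULL)
  best_cost <- if (is.null(inc_sel)) Inf else sum(cost[inc_sel])
  best_sel <- inc_sel
  # Lagrangian multipliers by subgradient ascent at the root
  y <- vapply(seq_len(m), function(j) {
    prov <- cand[A[cand, j] > 0]
    if (!length(prov)) return(0)
    min(cost[prov] / A[prov, j])
  }, numeric(1))
  lag_bound <- function(y, t, free) {
    rc <- cost[free] - as.numeric(A[free, , drop = FALSE] %*% y)
    sum(t * y) + sum(pmin(0, rc))
  }
  best_lb <- lag_bound(y, t0, cand)
  best_y <- y
  yy <- y
  ub0 <- if (is.finite(best_cost)) best_cost else sum(cost[cand])
  lambda <- 1
  since_improve <- 0L
  for (it in 1:250) {
    rc <- cost[cand] - as.numeric(A[cand, , drop = FALSE] %*% yy)
    inx <- cand[rc < 0]
    g <- t0 - if (length(inx)) colSums(A[inx, , drop = FALSE]) else 0
    lb <- sum(t0 * yy) + sum(pmin(0, rc))
    if (lb > best_lb + 1e-12) {
      best_lb <- lb; best_y <- yy; since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= 20L) { lambda <- lambda / 2; since_improve <- 0L }
    }
    gn <- sum(g^2)
    if (gn < 1e-14 || best_lb >= ub0 - 1e-9) break
    step <- lambda * max(ub0 - lb, 1e-9) / gn
    yy <- pmax(0, yy + step * g)
  }
  y <- best_y
  # root reduced-cost fixing: force-including i costs at least
  # best_lb + max(0, rc_i); prune variables that cannot be in an improving
  # solution
  if (is.finite(best_cost)) {
    rc_root <- cost[cand] - as.numeric(A[cand, , drop = FALSE] %*% y)
    keep <- best_lb + pmax(0, rc_root) < best_cost - 1e-9
    cand_fix <- cand[keep]
    # keep feasibility: never fix away the last provider of a target
    if (all(colSums(A[cand_fix, , drop = FALSE]) >= t0 - tol))
      cand <- cand_fix
  }
  nodes <- 0L
  hit_limit <- FALSE
  lex_less <- function(a1, b1) {
    n <- min(length(a1), length(b1))
    if (n > 0) for (i in seq_len(n)) {
      if (a1[i] != b1[i]) return(a1[i] < b1[i])
    }
    length(a1) < length(b1)
  }
  recurse <- function(sel, ccur, t, free) {
    if (nodes >= node_limit) { hit_limit <<- TRUE; return() }
    nodes <<- nodes + 1L
    if (all(t <= tol)) {
      s <- sort(sel)
      if (ccur < best_cost - 1e-9 ||
          (abs(ccur - best_cost) <= 1e-9 && lex_less(s, sort(best_sel)))) {
        best_cost <<- ccur
        best_sel <<- s
      }
      return()
    }
    unmet <- t > tol
    gain <- A[free, unmet, drop = FALSE]
    useful <- rowSums(gain) > 0
    free <- free[useful]
    if (!length(free)) return()
    gain <- gain[useful, , drop = FALSE]
    sup <- colSums(gain)
    if (any(t[unmet] - sup > tol)) return()
    lb <- ccur + max(0, lag_bound(y, t, free))
    prune_at <- best_cost - gap * max(best_cost, 0)
    if (lb >= prune_at - 1e-9) return()
    # dynamic branching: best capped-gain per cost (ties: lower id)
    score <- as.numeric(pmin(gain, rep(t[unmet], each = nrow(gain))) %*%
                          rep(1, sum(unmet))) / pmax(cost[free], 1e-12)
    i <- free[order(-score, free)][1]
    rest <- free[free != i]
    recurse(c(sel, i), ccur + cost[i], pmax(0, t - A[i, ]), rest)
    recurse(sel, ccur, t, rest)
  }
  recurse(integer(0), 0, t0, cand)
  if (is.null(best_sel)) stopf("no feasible solution found")
  list(sel = sort(best_sel), cost = best_cost,
       status = if (hit_limit) "incumbent" else "optimal",
       nodes = nodes)
}

#' Audit a solution against its problem
#'
#' Independent constraint check: every target met with nonnegative slack,
#' locked-in units selected, locked-out units absent.
#'
#' @param problem a [build_problem()] object.
#' @param solution a [solve_prioritization()] result.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
audit_solution <- function(problem, solution) {
  sel <- solution$selected
  if (!all(problem$locked_in %in% sel))
    stopf("audit: locked-in units missing from solution")
  if (length(intersect(problem$locked_out, sel)))
    stopf("audit: locked-out units selected")
  got <- colSums(problem$features[sel, , drop = FALSE])
  slack <- got - problem$targets
  if (any(slack < -1e-6))
    stopf("audit: unmet targets: %s",
          paste(names(problem$targets)[slack < -1e-6], collapse = ", "))
  invisible(TRUE)
}

#' Metrics of a reserve-selection solution
#'
#' Area, boundary length, proxy cost, and species coverage of a solution.
#' Boundary length is computed on the hexagon lattice: each selected unit
#' contributes its full hexagon perimeter minus twice the shared edge for
#' every selected neighbor (edges on the region border count fully; cropped
#' units are treated as full hexagons). Coverage is reported for all
#' species, not only targets: `100 * sum(a_ij over selected) / A_j`.
#' Cost and tenure proportions are over newly selected (non-locked-in)
#' units; locked-in units' cost is sunk.
#'
#' @param solution a [solve_prioritization()] result.
#' @param pu the [build_pu_table()] result the problem was built from.
#' @return list of class `solution_metrics`: `n_selected`, `n_new`,
#'   `cost_new`, `cost_total`, `area_new_km2`, `area_total_km2`,
#'   `boundary_km`, `coverage_pct` (named vector), `mean_coverage_pct`,
#'   `tenure_new` (proportions).
#' @export
solution_metrics <- function(solution, pu) {
  pus <- pu$pus
  a <- pu$features
  sel <- solution$selected
  new <- solution$new
  side <- attr(pus, "side_km")
  adj <- attr(pus, "adjacency")
  in_sel <- pus$id %in% sel
  shared <- sum(in_sel[adj[, 1]] & in_sel[adj[, 2]])
  boundary <- length(sel) * 6 * side - 2 * side * shared
  totals <- attr(a, "totals")
  got <- colSums(a[match(sel, pus$id), , drop = FALSE])
  coverage <- ifelse(totals > 0, 100 * got / totals, NA_real_)
  tenure_new <- if (length(new)) {
    tt <- table(factor(pus$tenure[match(new, pus$id)],
                       levels = tenure_classes()))
    as.numeric(tt) / length(new)
  } else rep(0, length(tenure_classes()))
  names(tenure_new) <- tenure_classes()
  structure(list(
    n_selected = length(sel), n_new = length(new),
    cost_new = solution$cost_new, cost_total = solution$cost_total,
    area_new_km2 = sum(pus$area_km2[match(new, pus$id)]),
    area_total_km2 = sum(pus$area_km2[match(sel, pus$id)]),
    boundary_km = boundary,
    coverage_pct = coverage,
    mean_coverage_pct = mean(coverage, na.rm = TRUE),
    tenure_new = tenure_new), class = "solution_metrics")
}

#' @export
print.solution_metrics <- function(x, ...) {
  cat(sprintf("%d PUs selected (%d new); cost %.4f; area %.0f km2; boundary %.0f km; mean coverage %.2f%%\n",
              x$n_selected, x$n_new, x$cost_new, x$area_total_km2,
              x$boundary_km, x$mean_coverage_pct))
  invisible(x)
}
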