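random_instance <- function(n_pu, n_sp, seed, lock_in = 0) {
  set.seed(seed)
  feats <- matrix(round(runif(n_pu * n_sp) * (runif(n_pu * n_sp) > 0.35), 3),
                  n_pu, n_sp)
  cost <- round(runif(n_pu, 0.2, 3), 3)
  tenure <- sample(tenure_classes()[-(1:2)], n_pu, TRUE)
  locked <- if (lock_in > 0) sample(n_pu, lock_in) else NULL
  pu <- fake_pu_table(cost, feats, tenure, locked_in = locked)
  supply <- colSums(feats)
  targets <- setNames(runif(n_sp, 0.1, 0.6) * supply, colnames(pu$features))
  list(pu = pu, targets = targets)
}

test_that("zero targets select exactly the locked-in set", {
  inst <- random_instance(8, 3, seed = 41, lock_in = 2)
  zero <- setNames(rep(0, 3), colnames(inst$pu$features))
  prob <- build_problem(inst$pu, zero, objective = 1)
  sol <- solve_prioritization(prob)
  expect_setequal(sol$selected, which(inst$pu$pus$locked_in))
  expect_equal(sol$cost_new, 0)
  expect_equal(sol$status, "optimal")
})

test_that("the exact solver matches exhaustive enumeration on small instances", {
  for (seed in 1:25) {
    n_pu <- sample(6:12, 1)
    n_sp <- sample(2:5, 1)
    inst <- random_instance(n_pu, n_sp, seed = 100 + seed)
    prob <- build_problem(inst$pu, inst$targets, objective = 1)
    sol <- solve_prioritization(prob, "exact", gap = 0)
    bf <- brute_force_cover(inst$pu$pus$cost, inst$pu$features, inst$targets)
    expect_equal(sol$cost_new, bf$cost, tolerance = 1e-9)
    expect_equal(sol$status, "optimal")
    audit_solution(prob, sol)
  }
})

test_that("greedy is feasible, never beats exact, and terminates", {
  for (seed in 1:25) {
    inst <- random_instance(sample(8:14, 1), sample(2:6, 1), seed = 200 + seed)
    prob <- build_problem(inst$pu, inst$targets, objective = 1)
    ex <- solve_prioritization(prob, "exact", gap = 0)
    gr <- solve_prioritization(prob, "greedy")
    audit_solution(prob, gr)
    expect_gte(gr$cost_new, ex$cost_new - 1e-9)
    expect_lte(length(gr$new), nrow(inst$pu$pus))
  }
  # unit costs, one species everywhere with amount 1, target 3: cost 3
  pu <- fake_pu_table(rep(1, 10), matrix(1, 10, 1),
                      rep("pastoral", 10))
  prob <- build_problem(pu, c(sp001 = 3), objective = 1)
  expect_equal(solve_prioritization(prob, "exact")$cost_new, 3)
  expect_equal(solve_prioritization(prob, "greedy")$cost_new, 3)
})

test_that("objective 2 locks out non-Indigenous tenure and reports infeasibility", {
  feats <- matrix(c(1, 1, 1, 1), 4, 1)
  pu <- fake_pu_table(rep(1, 4), feats,
                      c("pastoral", "other", "ILUA", "pastoral"))
  expect_error(build_problem(pu, c(sp001 = 2), objective = 2),
               "infeasible.*shortfalls")
  # same targets feasible under objective 1
  prob1 <- build_problem(pu, c(sp001 = 2), objective = 1)
  expect_equal(solve_prioritization(prob1)$cost_new, 2)
  # with Indigenous tenure present, objective 2 uses only eligible units
  pu2 <- fake_pu_table(c(1, 1, 5, 5), feats,
                       c("pastoral", "other", "indigenous_freehold",
                         "native_title"))
  prob2 <- build_problem(pu2, c(sp001 = 2), objective = 2)
  sol2 <- solve_prioritization(prob2)
  expect_setequal(sol2$selected, c(3, 4))
  expect_true(length(intersect(sol2$selected, prob2$locked_out)) == 0)
})

test_that("restricting tenure never lowers the optimal cost", {
  # objective 2's feasible set nests inside objective 1's
  n_ok <- 0
  for (seed in 1:20) {
    set.seed(300 + seed)
    n_pu <- 12
    feats <- matrix(runif(n_pu * 3) * (runif(n_pu * 3) > 0.3), n_pu, 3)
    tenure <- sample(c("indigenous_freehold", "native_title", "pastoral",
                       "other"), n_pu, TRUE)
    pu <- fake_pu_table(runif(n_pu, 0.5, 2), feats, tenure)
    elig <- tenure %in% c("indigenous_freehold", "native_title")
    supply2 <- colSums(pu$features[elig, , drop = FALSE])
    targets <- setNames(0.5 * supply2, colnames(pu$features))
    p1 <- build_problem(pu, targets, objective = 1)
    p2 <- build_problem(pu, targets, objective = 2)
    c1 <- solve_prioritization(p1, gap = 0)$cost_new
    c2 <- solve_prioritization(p2, gap = 0)$cost_new
    expect_gte(c2, c1 - 1e-9)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 20)
})

test_that("solution metrics compute boundary length on the hexagon lattice", {
  boundary <- cbind(x = c(0, 40, 40, 0), y = c(0, 0, 35, 35))
  lattice <- tessellate_hexagons(boundary, side_km = 7.5)
  interior <- lattice$id[abs(lattice$w - 1) < 1e-9]
  adj <- attr(lattice, "adjacency")
  lattice$tenure <- rep("pastoral", nrow(lattice))
  lattice$cost <- rep(1, nrow(lattice))
  lattice$locked_in <- rep(FALSE, nrow(lattice))
  feats <- matrix(1, nrow(lattice), 1,
                  dimnames = list(lattice$id, "sp001"))
  attr(feats, "totals") <- colSums(feats)
  pu <- structure(list(pus = lattice, features = feats, cellmap = NULL),
                  class = "pu_table")
  mk_sol <- function(sel) structure(list(selected = sel, new = sel,
                                         cost_new = length(sel),
                                         cost_total = length(sel),
                                         status = "optimal", objective = 1),
                                    class = "prior_solution")
  # single full hexagon: its perimeter, 45 km
  one <- mk_sol(interior[1])
  expect_equal(solution_metrics(one, pu)$boundary_km, 45)
  # two adjacent hexagons share one 7.5-km edge: 2 * 45 - 2 * 7.5 = 75
  pair_row <- which(adj[, 1] == interior[1] | adj[, 2] == interior[1])[1]
  pair <- as.integer(adj[pair_row, ])
  expect_equal(solution_metrics(mk_sol(pair), pu)$boundary_km, 75)
  # selecting everything gives every species 100% coverage
  all_sol <- mk_sol(lattice$id)
  m <- solution_metrics(all_sol, pu)
  expect_equal(unname(m$coverage_pct), 100)
  expect_equal(m$mean_coverage_pct, 100)
})
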