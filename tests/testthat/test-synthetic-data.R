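test_that("simulated phylogenies are ultrametric, label-stable, and reproducible", {
  trees <- simulate_phylogenies(10, 4, seed = 7)
  expect_length(trees, 4)
  for (tr in trees) {
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_setequal(tr$tip.label, sprintf("sp%03d", 1:10))
  }
  # unit height
  expect_equal(max(ape::node.depth.edgelength(trees[[1]])), 1)
  # same seed twice: byte-identical Newick
  nwk1 <- ape::write.tree(simulate_phylogenies(10, 4, seed = 7))
  nwk2 <- ape::write.tree(simulate_phylogenies(10, 4, seed = 7))
  expect_identical(nwk1, nwk2)
  expect_error(simulate_phylogenies(2, 1), "n_species")
})

test_that("trait evolution respects the tree and its zero-variance limit", {
  tree <- simulate_phylogenies(12, 1, seed = 3)[[1]]
  p0 <- list(root = c(body_mass_g = 100, age_first_repro = 1,
                      litters_per_year = 1, litter_size = 2),
             sigma2_bm = 0, sigma2_noise = 0)
  tr0 <- simulate_traits(tree, p0, seed = 1)
  expect_true(all(abs(tr0$body_mass_g - 100) < 1e-9))
  expect_error(simulate_traits(tree, modifyList(p0, list(sigma2_bm = -1))),
               "non-negative")
  # determinism
  expect_identical(simulate_traits(tree, seed = 5),
                   simulate_traits(tree, seed = 5))
  # sister tips covary more than distant tips (Monte-Carlo over replicates)
  bal <- ape::compute.brlen(ape::stree(4, "balanced"), 1)  # ((t1,t2),(t3,t4))
  d_sis <- d_far <- numeric(200)
  for (r in 1:200) {
    tt <- simulate_traits(bal, trait_params = list(
      root = c(body_mass_g = 100), sigma2_bm = 1, sigma2_noise = 0.01),
      seed = r)
    lx <- log(tt$body_mass_g)
    d_sis[r] <- abs(lx[1] - lx[2])
    d_far[r] <- abs(lx[1] - lx[3])
  }
  expect_lt(mean(d_sis), mean(d_far))
})

test_that("landscape layers are autocorrelated, aligned, and reproducible", {
  cfg <- small_config()
  land <- simulate_landscape(cfg, seed = 2)
  expect_named(land, c("temp_wet_q", "fire_total", "fire_lds", "hii",
                       "mei", "fox", "toad"))
  for (g in land) expect_identical(dim(g), c(24L, 24L))
  expect_true(all(land$fox$values %in% c(0, 1)))
  expect_true(all(land$toad$values %in% c(0, 1)))
  # spatial structure: Moran's I beats a shuffled copy of the same values
  set.seed(99)
  for (nm in c("temp_wet_q", "hii", "mei")) {
    shuffled <- land[[nm]]
    shuffled$values[] <- sample(shuffled$values)
    expect_gt(moran_i(land[[nm]]), moran_i(shuffled))
  }
  expect_identical(simulate_landscape(cfg, seed = 2),
                   simulate_landscape(cfg, seed = 2))
})

test_that("range growth hits target sizes with 4-connected patches", {
  cfg <- small_config()
  sizes <- c(1L, 24L, 120L, 24L * 24L)
  rg <- simulate_ranges(cfg, target_sizes = sizes, seed = 5)
  for (j in seq_along(sizes)) {
    m <- rg[[j]]$values
    expect_equal(sum(m), sizes[j])
    # flood fill from one occupied cell reaches the whole patch
    expect_setequal(flood_fill4(m), which(m > 0))
  }
  expect_equal(unname(attr(rg, "A")), rep(1, 4))  # margin_cells = 0
  expect_error(simulate_ranges(cfg, target_sizes = 0L), ">= 1")
  # with a margin, ranges may spill and A drops below 1 but sizes still exact
  cfg2 <- small_config()
  cfg2$margin_cells <- 10L
  rg2 <- simulate_ranges(cfg2, target_sizes = rep(200L, 6), seed = 11)
  A <- attr(rg2, "A")
  expect_true(all(A <= 1 & A > 0))
  expect_equal(unname(vapply(rg2, function(g) sum(g$values), 1) / 200),
               unname(A))
})

test_that("tenure generation matches requested proportions and the PA mask", {
  cfg <- sim_config(grid_nrows = 60L, grid_ncols = 60L, n_species = 5L,
                    seed = 4L)
  ten <- simulate_tenure(cfg, seed = 4)
  lev <- attr(ten$tenure, "levels")
  realized <- tabulate(ten$tenure$values, nbins = length(lev)) / 3600
  names(realized) <- lev
  expect_true(all(abs(realized - cfg$tenure_mix[lev]) <= 0.05))
  # PA mask exactly the PA/IPA-labelled cells
  pa_cells <- lev[ten$tenure$values] %in% c("PA", "IPA")
  expect_equal(as.numeric(pa_cells), as.numeric(ten$pa_mask$values))
  # degenerate mix: uniform raster
  cfg1 <- small_config(tenure_mix = c(pastoral = 1))
  t1 <- simulate_tenure(cfg1, seed = 1)
  expect_true(all(t1$tenure$values == 1))
  expect_error(sim_config(tenure_mix = c(pastoral = 0.7, other = 0.2)),
               "sum to 1")
})

test_that("threat-status generation covers the scale and encodes suppression exactly", {
  set.seed(10)
  n <- 120
  tree <- simulate_phylogenies(n, 1, seed = 2)[[1]]
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(tree$tip.label, c("a", "b", "c")))
  X <- scale(X)
  cent <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  rownames(cent) <- tree$tip.label
  tm <- true_risk_model(beta_true = c(a = 1, b = -0.5, c = 0),
                        suppression_shift = 3)
  st <- assign_threat_status(tm, X, tree, cent, suppressed_fraction = 0.2,
                             seed = 3)
  expect_gte(length(unique(st$ordinal)), 3)
  expect_true(all(st$ordinal >= 1 & st$ordinal <= 10))
  sup <- st$suppressed
  expect_equal(sum(sup), 24)
  expect_equal(st$ordinal[sup], pmax(1L, st$ordinal_true[sup] - 3L))
  expect_identical(st$ordinal[!sup], st$ordinal_true[!sup])
  # deciles populate every level on a smooth latent
  expect_equal(sort(unique(st$ordinal_true)), 1:10)
  # sign recovery of beta by plain OLS at large n
  n2 <- 500
  tree2 <- simulate_phylogenies(n2, 1, seed = 5)[[1]]
  X2 <- scale(matrix(rnorm(n2 * 2), n2, 2,
                     dimnames = list(tree2$tip.label, c("a", "b"))))
  cent2 <- cbind(runif(n2, 0, 100), runif(n2, 0, 100))
  tm2 <- true_risk_model(beta_true = c(a = 1.2, b = -1.2), w_phylo = 0.2,
                         w_space = 0, w_iid = 0.8)
  st2 <- assign_threat_status(tm2, X2, tree2, cent2,
                              suppressed_fraction = 0, seed = 6)
  co <- coef(lm(st2$ordinal ~ X2))
  expect_gt(co[[2]], 0)  # slope on a
  expect_lt(co[[3]], 0)  # slope on b
  # zero-signal, zero-noise limit: a single shared status
  tm0 <- true_risk_model(beta_true = c(a = 0, b = 0), sigma2 = 0,
                         w_phylo = 0, w_space = 0, w_iid = 1)
  st0 <- assign_threat_status(tm0, X2, tree2, cent2,
                              suppressed_fraction = 0, seed = 7)
  expect_length(unique(st0$ordinal), 1)
})
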