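test_that("ordinal threat coding is monotone and reaches every level", {
  cats <- c("LC", "NT", "VU", "EN", "CR")
  trends <- c("increasing", "stable", "decreasing", "unknown")
  grid <- expand.grid(category = cats, trend = trends,
                      stringsAsFactors = FALSE)
  ord <- encode_threat_ordinal(grid$category, grid$trend)
  expect_setequal(ord, 1:10)
  expect_equal(encode_threat_ordinal("LC", "increasing"), 1L)
  expect_equal(encode_threat_ordinal("CR", "decreasing"), 10L)
  # severity monotone at fixed trend
  for (tr in trends) {
    expect_true(all(diff(encode_threat_ordinal(cats, rep(tr, 5))) > 0))
  }
  expect_error(encode_threat_ordinal("XX", "stable"), "category")
  expect_error(encode_threat_ordinal("LC", "rising"), "trend")
  expect_equal(endangered_ordinal_base(), 7L)
})

test_that("species-pool filtering applies each exclusion once", {
  pool <- data.frame(species = sprintf("s%03d", 1:178))
  pool$data_deficient <- seq_len(178) <= 2
  pool$criterion_b <- seq_len(178) %in% 3:16
  pool$unresolved_phylogeny <- seq_len(178) %in% 17:32
  pool$insufficient_overlap <- seq_len(178) %in% 33:50
  out <- filter_species_pool(pool)
  expect_equal(nrow(out), 128)
  expect_equal(unname(attr(out, "removed")), c(2L, 14L, 16L, 18L))
})

test_that("occurrence cleaning drops imprecise, incomplete, and duplicate records", {
  occ <- data.frame(lon = c(1, 1, 2, NA, 3, 4),
                    lat = c(1, 1, 2, 5, 3, 4),
                    uncertainty_km = c(0.5, 0.5, 3, 1, NA, 2))
  out <- clean_occurrences(occ)
  # row 2 duplicates row 1; row 3 too uncertain; row 4 lacks coords;
  # row 5 has unknown uncertainty (kept); row 6 exactly at the threshold
  expect_equal(out$lon, c(1, 3, 4))
})

test_that("predictor summaries match hand arithmetic on tiny fixtures", {
  r <- tiny_ranges(4, 4, patches = list(c(1, 2), c(5, 6, 7)))
  env <- list(temp = rgrid(matrix(2, 4, 4)),
              layerA = rgrid(matrix(seq(0, 15), 4, 4)),
              fox = rgrid(matrix(0, 4, 4)))
  sp <- summarize_predictors(r, env, overlap_layers = "fox")
  expect_equal(sp$predictors$temp, c(2, 2))
  expect_equal(sp$predictors$fox_overlap, c(0, 0))
  # cells 1,2 of layerA hold 0 and 1 -> mean 0.5
  expect_equal(sp$predictors$layerA[1], 0.5)
  expect_equal(sp$predictors$range_size, c(2, 3))
  # centroid of cells (r1,c1),(r2,c1) at cellsize 1: x=0.5, y=1
  expect_equal(unname(sp$centroids[1, ]), c(0.5, 1))
  r_empty <- tiny_ranges(4, 4, patches = list(integer(0)))
  expect_error(summarize_predictors(r_empty, env), "empty range")
})

test_that("transform/standardize yields unit-scale columns and reduces skew", {
  set.seed(3)
  df <- data.frame(sym = rnorm(200),
                   lognorm = exp(rnorm(200, 0, 1.2)),
                   with_zero = c(0, rexp(199, 0.2)))
  out <- transform_standardize(df)
  for (nm in names(out)) {
    expect_lt(abs(mean(out[[nm]])), 1e-8)
    expect_lt(abs(sd(out[[nm]]) - 1), 1e-8)
  }
  lg <- attr(out, "transform_log")
  expect_equal(lg$transform[lg$column == "lognorm"], "log+z")
  expect_equal(lg$transform[lg$column == "sym"], "z")
  expect_lt(abs(lg$skew_after[lg$column == "lognorm"]),
            abs(lg$skew_before[lg$column == "lognorm"]))
  # already standardized input is unchanged by a second pass
  out2 <- transform_standardize(out)
  expect_equal(as.matrix(out2), as.matrix(out), tolerance = 1e-8)
  expect_error(transform_standardize(data.frame(k = rep(1, 10))), "constant")
})

test_that("VIF screen matches the per-predictor regression oracle", {
  set.seed(4)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  vs <- vif_screen(X, threshold = 5)
  expect_setequal(vs$retained, paste0("v", 1:4))
  # oracle: VIF_j = 1 / (1 - R2_j)
  for (j in 1:4) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(vs$rounds[[1]][j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # collinear pair: one is removed, with a warning for the exact duplicate
  X2 <- cbind(X, v5 = X[, 1])
  expect_warning(vs2 <- vif_screen(X2, threshold = 5), "collinear")
  expect_length(vs2$removed, 1)
  expect_false(all(c("v1", "v5") %in% vs2$retained))
})

test_that("combined covariance matches its closed-form limits", {
  tree <- simulate_phylogenies(6, 1, seed = 1)[[1]]
  cent <- cbind(x = runif(6, 0, 50), y = runif(6, 0, 50))
  rownames(cent) <- tree$tip.label
  # both weights zero: identity
  expect_equal(build_covariance(species = letters[1:4])$V, diag(4),
               ignore_attr = TRUE)
  # star phylogeny shares no branches: V_phylo = I
  star <- ape::compute.brlen(ape::stree(5, "star"), 1)
  Vs <- build_covariance(star, w_phylo = 0.7)$V
  expect_equal(Vs, 0.7 * diag(5) + 0.3 * diag(5), ignore_attr = TRUE)
  # rho -> infinity: spatial kernel tends to the all-ones matrix
  Vinf <- build_covariance(centroids = cent, w_space = 1, rho = 1e9)$V
  expect_true(max(abs(Vinf - 1)) < 1e-6)
  # unit diagonal in a mixed model
  Vmix <- build_covariance(tree, cent, 0.4, 0.3, rho = 20)$V
  expect_equal(unname(diag(Vmix)), rep(1, 6), tolerance = 1e-9)
  expect_error(build_covariance(tree, cent, 0.5, 0.2, rho = 20,
                                species = c("nope", tree$tip.label[1:3])),
               "missing from tree")
})

test_that("GLS with identity covariance reproduces OLS exactly", {
  set.seed(5)
  for (r in 1:5) {
    n <- 40
    d <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n))
    rownames(d) <- paste0("s", 1:n)
    fit <- risk_gls(y ~ x1 + x2, d)
    ols <- lm(y ~ x1 + x2, d)
    expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
    expect_equal(unname(fit$se), unname(summary(ols)$coefficients[, 2]),
                 tolerance = 1e-8)
    expect_equal(unname(fit$pvals), unname(summary(ols)$coefficients[, 4]),
                 tolerance = 1e-8)
  }
})

test_that("GLS solves a 3-observation fixture by explicit matrix algebra", {
  X <- cbind(1, c(0, 1, 2))
  y <- c(1, 2, 4)
  V <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.5,
                0.2, 0.5, 1), 3, 3)
  d <- data.frame(y = y, x = X[, 2])
  rownames(d) <- paste0("s", 1:3)
  cov <- structure(list(V = V, weights = c(phylo = 0, space = 0, iid = 1),
                        rho = NULL, species = rownames(d), jitter = 0),
                   class = "risk_cov")
  fit <- risk_gls(y ~ x, d, cov = cov)
  Vi <- solve(V)
  beta_hand <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(unname(coef(fit)), drop(beta_hand), tolerance = 1e-12)
  # ML sigma2 and the multivariate-normal log-likelihood, by hand
  resid <- y - X %*% beta_hand
  s2 <- drop(t(resid) %*% Vi %*% resid) / 3
  expect_equal(fit$sigma2, s2, tolerance = 1e-12)
  ll_hand <- -0.5 * (3 * log(2 * pi * s2) + log(det(V)) + 3)
  expect_equal(fit$logLik, ll_hand, tolerance = 1e-10)
})

test_that("profile likelihood is maximal at the fitted coefficients", {
  set.seed(6)
  tree <- simulate_phylogenies(20, 1, seed = 2)[[1]]
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  rownames(d) <- tree$tip.label
  fit <- risk_gls(y ~ x, d, tree = tree, weights = c(0.5, 0))
  U <- chol(fit$cov$V)
  ll_of_beta <- function(b) {
    r <- d$y - cbind(1, d$x) %*% b
    w <- backsolve(U, r, transpose = TRUE)
    s2 <- sum(w^2) / 20
    -0.5 * (20 * log(2 * pi * s2) + 2 * sum(log(diag(U))) + 20)
  }
  for (k in 1:10) {
    pert <- coef(fit) + rnorm(2, 0, 0.05)
    expect_lte(ll_of_beta(pert), fit$logLik + 1e-10)
  }
})

test_that("GLS agrees with nlme under a Brownian phylogenetic correlation", {
  skip_if_not_installed("nlme")
  set.seed(7)
  tree <- simulate_phylogenies(30, 1, seed = 9)[[1]]
  V <- ape::vcv(tree, corr = TRUE)
  y <- MASS::mvrnorm(1, rep(2, 30), 1.5 * V)
  d <- data.frame(y = y, x = rnorm(30), species = tree$tip.label)
  rownames(d) <- tree$tip.label
  fit <- risk_gls(y ~ x, d, tree = tree, weights = c(1, 0))
  gfit <- nlme::gls(y ~ x, d,
                    correlation = ape::corBrownian(phy = tree,
                                                   form = ~species),
                    method = "ML")
  expect_equal(unname(coef(fit)), unname(coef(gfit)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(stats::logLik(gfit)), tolerance = 1e-6)
})

test_that("AICc matches hand arithmetic and its large-n limit", {
  expect_equal(aicc(-10, 3, 20), 20 + 6 + 24 / 16)
  expect_equal(aicc(-10, 0, 50), 20)
  expect_lt(abs(aicc(-10, 3, 1e9) - (20 + 6)), 1e-6)
  expect_error(aicc(-10, 5, 6), "n > k")
  # the generic agrees with the stored value and with logLik-based default
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  rownames(d) <- paste0("s", 1:30)
  fit <- risk_gls(y ~ x, d)
  expect_equal(AICc(fit), aicc(fit$logLik, fit$k, fit$n))
})

test_that("model methods are coherent (predict, residuals, simulate, summary)", {
  set.seed(8)
  d <- data.frame(y = rnorm(25), x1 = rnorm(25), x2 = rnorm(25))
  rownames(d) <- paste0("s", 1:25)
  fit <- risk_gls(y ~ x1 + x2, d)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(unname(predict(fit, newdata = d[1:3, ])),
               unname(fitted(fit)[1:3]))
  expect_equal(fitted(fit) + residuals(fit), d$y, ignore_attr = TRUE)
  sm <- summary(fit)
  expect_equal(unname(sm$coefficients[, "Estimate"]), unname(coef(fit)))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(25L, 3L))
  expect_output(print(fit), "Generalized least squares")
})
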