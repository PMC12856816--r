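#' Generate ordinal threat statuses with known ground truth
#'
#' Draws a latent continuous risk `X beta_true + e`, where `e` is multivariate
#' normal with covariance `sigma2 * (w_phylo V_phylo + w_space V_space +
#' w_iid I)`, discretizes it to the 10-point ordinal scale by
#' equal-probability bins (empirical deciles, so every level is populated in
#' expectation), then lowers a designated fraction of species by
#' `suppression_shift` points (floored at 1). Suppressed species are the
#' ground truth that latent-risk analyses should flag.
#'
#' @param true_model a [true_risk_model].
#' @param X numeric matrix of standardized predictors (rows = species, with
#'   rownames), with columns matching `names(true_model$beta_true)`.
#' @param tree [ape::phylo] with tips covering the rows of `X`.
#' @param centroids two-column matrix of species range centroids (km), rows
#'   aligned with `X`.
#' @param suppressed_fraction fraction of species to suppress.
#' @param seed integer seed.
#' @return data.frame: `species`, `latent_true` (continuous), `ordinal_true`,
#'   `ordinal` (observed, after suppression), `suppressed` (logical).
#' @export
assign_threat_status <- function(true_model, X, tree, centroids,
                                 suppressed_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(true_model, "true_risk_model"))
  beta <- true_model$beta_true
  if (!all(names(beta) %in% colnames(X)))
    stopf("X lacks predictor columns: %s",
          paste(setdiff(names(beta), colnames(X)), collapse = ", "))
  X <- as.matrix(X[, names(beta), drop = FALSE])
  n <- nrow(X)
  set.seed(seed)
  cov <- build_covariance(tree, centroids,
                          w_phylo = true_model$w_phylo,
                          w_space = true_model$w_space,
                          rho = true_model$spatial_range,
                          species = rownames(X))
  e <- if (true_model$sigma2 > 0)
    MASS::mvrnorm(1, rep(0, n), true_model$sigma2 * cov$V) else 0
  latent <- drop(X %*% beta) + e
  ordinal_true <- discretize_deciles(latent)
  suppressed <- rep(FALSE, n)
  n_sup <- round(suppressed_fraction * n)
  if (n_sup > 0) suppressed[sample.int(n, n_sup)] <- TRUE
  ordinal <- ordinal_true
  ordinal[suppressed] <- pmax(1L, ordinal_true[suppressed] -
                                true_model$suppression_shift)
  data.frame(species = rownames(X), latent_true = latent,
             ordinal_true = ordinal_true, ordinal = ordinal,
             suppressed = suppressed, stringsAsFactors = FALSE)
}

# Equal-probability 10-level discretization by empirical deciles.
# Degenerate (all-equal) input maps everything to level 1.
discretize_deciles <- function(x) {
  qs <- unique(stats::quantile(x, probs = seq(0.1, 0.9, by = 0.1),
                               names = FALSE, type = 7))
  as.integer(findInterval(x, qs, left.open = TRUE) + 1L)
}
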