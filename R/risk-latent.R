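#' Latent extinction risk averaged over a phylogeny sample
#'
#' Refits a model's coefficients under the covariance implied by each tree
#' in a sample (the spatial component and mixture weights are held at the
#' model's values; only the phylogenetic correlation changes with the tree),
#' computes each species' fitted threat status per tree, and reports latent
#' risk `L = mean fitted - observed` with its positive part. Positive latent
#' risk flags species currently listed as less threatened than the model
#' predicts.
#'
#' @param object a [risk_gls] fit or a [step_mam()] result.
#' @param trees a `multiPhylo` list (or single `phylo`).
#' @param data data for refits (defaults to the data stored in the fit).
#' @return a data.frame of class `latent_risk`: `species`, `observed`,
#'   `fitted_mean`, `fitted_sd`, `latent`, `latent_pos`; the per-tree fitted
#'   matrix is in attribute `"per_tree"`.
#' @export
latent_risk <- function(object, trees, data = NULL) {
  fit <- if (inherits(object, "risk_mam")) object$fit else object
  stopifnot(inherits(fit, "risk_gls"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) < 1L) stopf("need at least one tree")
  if (is.null(data)) data <- fit$data
  cov0 <- fit$cov
  fits <- matrix(NA_real_, nrow = fit$n, ncol = length(trees))
  for (t in seq_along(trees)) {
    cov_t <- if (cov0$weights[["phylo"]] > 0)
      rebuild_covariance(cov0, trees[[t]]) else cov0
    f <- risk_gls(fit$formula, data, cov = cov_t)
    fits[, t] <- f$fitted
  }
  y <- fit$y
  lat <- rowMeans(fits) - y
  out <- data.frame(species = fit$species, observed = y,
                    fitted_mean = rowMeans(fits),
                    fitted_sd = apply(fits, 1, stats::sd),
                    latent = lat, latent_pos = pmax(lat, 0),
                    stringsAsFactors = FALSE)
  attr(out, "per_tree") <- fits
  class(out) <- c("latent_risk", "data.frame")
  out
}

# Recombine a risk_cov with the phylogenetic correlation of a new tree,
# keeping weights, rho, and the spatial kernel unchanged.
rebuild_covariance <- function(cov, tree) {
  sp <- cov$species
  miss <- setdiff(sp, tree$tip.label)
  if (length(miss))
    stopf("species missing from tree: %s", paste(miss, collapse = ", "))
  Vp <- ape::vcv(tree, corr = TRUE)[sp, sp]
  w <- cov$weights
  V <- diag(w[["iid"]], length(sp)) + w[["phylo"]] * Vp
  if (w[["space"]] > 0) V <- V + w[["space"]] * cov$V_space
  dimnames(V) <- list(sp, sp)
  out <- cov
  out$V_phylo <- Vp
  out$V <- V
  out
}
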