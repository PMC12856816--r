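#' Combined phylogenetic-spatial covariance model
#'
#' Builds the species-by-species correlation structure used by [risk_gls()]:
#' a convex combination `V = w_phylo * V_phylo + w_space * V_space +
#' w_iid * I`, where `V_phylo` comes from shared branch lengths scaled to a
#' unit diagonal, `V_space = exp(-d / rho)` on Euclidean distances between
#' range centroids, and `w_iid = 1 - w_phylo - w_space`. Positive
#' definiteness is enforced by adding a small diagonal jitter if needed
#' (recorded in the `jitter` field).
#'
#' @param tree [ape::phylo]; its tips must include every species.
#' @param centroids two-column matrix of range centroids (km) with species
#'   rownames (or aligned with `species`).
#' @param w_phylo,w_space mixture weights (>= 0, sum <= 1).
#' @param rho spatial decay range (km, > 0).
#' @param species character vector giving the species order; defaults to
#'   `rownames(centroids)`, else the tree's tip labels.
#' @return an object of class `risk_cov` with elements `V`, `V_phylo`,
#'   `V_space`, `weights`, `rho`, `species`, `jitter`.
#' @export
build_covariance <- function(tree = NULL, centroids = NULL,
                             w_phylo = 0, w_space = 0, rho = NULL,
                             species = NULL) {
  if (w_phylo < 0 || w_space < 0 || w_phylo + w_space > 1 + 1e-9)
    stopf("weights must be >= 0 with w_phylo + w_space <= 1")
  if (is.null(species)) {
    species <- if (!is.null(centroids) && !is.null(rownames(centroids)))
      rownames(centroids) else tree$tip.label
  }
  n <- length(species)
  Vp <- Vs <- NULL
  if (w_phylo > 0) {
    if (is.null(tree)) stopf("w_phylo > 0 requires a tree")
    miss <- setdiff(species, tree$tip.label)
    if (length(miss))
      stopf("species missing from tree: %s", paste(miss, collapse = ", "))
    Vp <- ape::vcv(tree, corr = TRUE)[species, species]
  }
  if (w_space > 0) {
    if (is.null(centroids)) stopf("w_space > 0 requires centroids")
    if (is.null(rho) || rho <= 0) stopf("w_space > 0 requires rho > 0")
    xy <- centroids
    if (!is.null(rownames(xy))) xy <- xy[species, , drop = FALSE]
    d <- as.matrix(stats::dist(xy))
    Vs <- exp(-d / rho)
  }
  V <- diag(1 - w_phylo - w_space, n)
  if (!is.null(Vp)) V <- V + w_phylo * Vp
  if (!is.null(Vs)) V <- V + w_space * Vs
  dimnames(V) <- list(species, species)
  jitter <- 0
  repeat {
    ok <- tryCatch({ chol(V + diag(jitter, n)); TRUE },
                   error = function(e) FALSE)
    if (ok) break
    jitter <- if (jitter == 0) 1e-10 else jitter * 10
    if (jitter > 1e-2) stopf("covariance matrix is not positive definite")
  }
  if (jitter > 0) V <- V + diag(jitter, n)
  structure(list(V = V, V_phylo = Vp, V_space = Vs,
                 weights = c(phylo = unname(w_phylo),
                             space = unname(w_space),
                             iid = 1 - unname(w_phylo) - unname(w_space)),
                 rho = rho, species = species, jitter = jitter),
            class = "risk_cov")
}

#' @export
print.risk_cov <- function(x, ...) {
  cat(sprintf("<risk_cov> %d species; weights phylo=%.3f space=%.3f iid=%.3f",
              length(x$species), x$weights[1], x$weights[2], x$weights[3]))
  if (!is.null(x$rho)) cat(sprintf("; rho=%.3g km", x$rho))
  cat("\n")
  invisible(x)
}

# Core GLS solve given the upper Cholesky factor of V.
# Returns beta, residuals (raw scale), RSS in the whitened metric, etc.
gls_core <- function(X, y, U) {
  ytil <- backsolve(U, y, transpose = TRUE)
  Xtil <- backsolve(U, X, transpose = TRUE)
  colnames(Xtil) <- colnames(X)
  qr_x <- qr(Xtil)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, ytil)
  rss <- sum(qr.resid(qr_x, ytil)^2)
  piv <- qr_x$pivot
  B <- chol2inv(qr.R(qr_x))
  xtvx_inv <- matrix(0, ncol(X), ncol(X),
                     dimnames = list(colnames(X), colnames(X)))
  xtvx_inv[piv, piv] <- B
  list(beta = beta, rss = rss, xtvx_inv = xtvx_inv)
}

profile_loglik <- function(X, y, V) {
  n <- length(y)
  U <- chol(V)
  f <- gls_core(X, y, U)
  sigma2 <- f$rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(U))) + n)
  list(loglik = ll, sigma2 = sigma2, fit = f, U = U)
}

#' Fit a generalized least squares risk model
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V)` by maximum likelihood,
#' where `V` combines phylogenetic and spatial correlation (see
#' [build_covariance()]). With `V = I` the fit reduces exactly to ordinary
#' least squares. The mixture weights and spatial range can either be fixed
#' or estimated by profile maximum likelihood (coarse grid search refined by
#' Nelder-Mead).
#'
#' Standard errors use the small-sample residual variance (`rss / (n - p)`)
#' and t statistics with `n - p` degrees of freedom. The AICc parameter
#' count is `p + 1` (coefficients plus `sigma2`), plus 3 when the covariance
#' parameters are estimated.
#'
#' @param formula model formula; the response is the ordinal threat status
#'   treated as numeric.
#' @param data data.frame of response and standardized predictors; row names
#'   (or a `species` column) identify species.
#' @param cov optional pre-built [build_covariance()] object (overrides
#'   `tree`/`centroids`/`weights`/`rho`).
#' @param tree,centroids inputs for [build_covariance()].
#' @param weights numeric `c(phylo, space)` mixture weights when not
#'   estimating.
#' @param rho spatial decay range (km); defaults to the median centroid
#'   distance when needed.
#' @param estimate_cov if `TRUE`, estimate `(w_phylo, w_space, rho)` by
#'   profile ML.
#' @return an object of class `risk_gls`.
#' @export
risk_gls <- function(formula, data, cov = NULL, tree = NULL,
                     centroids = NULL, weights = c(0, 0), rho = NULL,
                     estimate_cov = FALSE) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stopf("need n > number of coefficients (%d <= %d)", n, p)
  species <- if ("species" %in% names(data)) data$species else rownames(data)

  cov_est <- FALSE
  if (is.null(cov)) {
    if (estimate_cov) {
      if (is.null(tree) && is.null(centroids))
        stopf("estimate_cov = TRUE requires a tree and/or centroids")
      cov <- estimate_covariance(X, y, tree, centroids, species)
      cov_est <- TRUE
    } else if (weights[1] > 0 || weights[2] > 0) {
      if (weights[2] > 0 && is.null(rho) && !is.null(centroids))
        rho <- stats::median(stats::dist(centroids))
      cov <- build_covariance(tree, centroids, weights[1], weights[2], rho,
                              species = species)
    } else {
      cov <- build_covariance(species = species)  # V = I
    }
  }
  pl <- profile_loglik(X, y, cov$V)
  f <- pl$fit
  k <- p + 1L + if (cov_est) 3L else 0L
  sigma2_df <- f$rss / (n - p)
  se <- sqrt(sigma2_df * diag(f$xtvx_inv))
  tval <- f$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  fitted <- drop(X %*% f$beta)
  structure(list(
    coefficients = f$beta, se = se, tvals = tval, pvals = pval,
    sigma2 = pl$sigma2, sigma2_df = sigma2_df,
    logLik = pl$loglik, k = k, n = n, p = p,
    AICc = if (n > k + 1) aicc(pl$loglik, k, n) else NA_real_,
    fitted = fitted, residuals = y - fitted, y = y,
    vcov = sigma2_df * f$xtvx_inv,
    cov = cov, cov_estimated = cov_est,
    formula = formula, terms = attr(mf, "terms"),
    species = species, data = data, call = cl),
    class = "risk_gls")
}

# Profile-ML estimation of (w_phylo, w_space, rho): coarse grid then
# Nelder-Mead on logit/log-transformed parameters.
estimate_covariance <- function(X, y, tree, centroids, species) {
  have_p <- !is.null(tree)
  have_s <- !is.null(centroids)
  d_med <- if (have_s) stats::median(stats::dist(centroids)) else 1
  Vp <- if (have_p) {
    miss <- setdiff(species, tree$tip.label)
    if (length(miss))
      stopf("species missing from tree: %s", paste(miss, collapse = ", "))
    ape::vcv(tree, corr = TRUE)[species, species]
  } else NULL
  D <- if (have_s) as.matrix(stats::dist(centroids)) else NULL
  n <- length(y)
  ll_of <- function(wp, ws, rho) {
    V <- diag(1 - wp - ws, n)
    if (wp > 0) V <- V + wp * Vp
    if (ws > 0) V <- V + ws * exp(-D / rho)
    out <- tryCatch(profile_loglik(X, y, V)$loglik, error = function(e) -Inf)
    out
  }
  # coarse grid
  wgrid <- c(0, 0.2, 0.4, 0.6, 0.8)
  rgrid_v <- if (have_s) d_med * c(0.25, 0.5, 1, 2) else 1
  best <- list(ll = -Inf, wp = 0, ws = 0, rho = rgrid_v[1])
  for (wp in (if (have_p) wgrid else 0))
    for (ws in (if (have_s) wgrid else 0)) {
      if (wp + ws > 0.95) next
      for (r in (if (ws > 0) rgrid_v else rgrid_v[1])) {
        ll <- ll_of(wp, ws, r)
        if (ll > best$ll) best <- list(ll = ll, wp = wp, ws = ws, rho = r)
      }
    }
  # local refinement on transformed scale
  to_w <- function(a, b) {
    ea <- exp(pmin(pmax(a, -10), 10)); eb <- exp(pmin(pmax(b, -10), 10))
    s <- 1 + (if (have_p) ea else 0) + (if (have_s) eb else 0)
    c(if (have_p) ea / s else 0, if (have_s) eb / s else 0)
  }
  par0 <- c(a = log(max(best$wp, 0.02) / max(1 - best$wp - best$ws, 0.02)),
            b = log(max(best$ws, 0.02) / max(1 - best$wp - best$ws, 0.02)),
            lr = log(best$rho))
  obj <- function(par) {
    w <- to_w(par[1], par[2])
    -ll_of(w[1], w[2], exp(pmin(pmax(par[3], log(d_med) - 4),
                                log(d_med) + 4)))
  }
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-8))
  w <- unname(to_w(opt$par[[1]], opt$par[[2]]))
  rho <- exp(pmin(pmax(opt$par[[3]], log(d_med) - 4), log(d_med) + 4))
  if (-opt$value < best$ll) {  # keep grid optimum if refinement regressed
    w <- c(best$wp, best$ws); rho <- best$rho
  }
  build_covariance(tree, centroids, w[1], w[2],
                   rho = if (have_s) rho else NULL, species = species)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik log-likelihood at the maximum.
#' @param k number of estimated parameters.
#' @param n number of observations (must exceed `k + 1`).
#' @return numeric scalar.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stopf("AICc requires n > k + 1 (n = %d, k = %d)", n, k)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
AICc <- function(object, ...) UseMethod("AICc")

#' @export
AICc.risk_gls <- function(object, ...) object$AICc

#' @export
AICc.default <- function(object, ...) {
  ll <- stats::logLik(object)
  aicc(as.numeric(ll), attr(ll, "df"), attr(ll, "nobs"))
}

#' @export
print.risk_gls <- function(x, ...) {
  cat("Generalized least squares risk model\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d, logLik = %.3f, AICc = %.3f\n", x$n, x$logLik, x$AICc))
  w <- x$cov$weights
  cat(sprintf("Covariance weights%s: phylo=%.3f space=%.3f iid=%.3f",
              if (x$cov_estimated) " (profile ML)" else "",
              w[1], w[2], w[3]))
  if (!is.null(x$cov$rho) && w[2] > 0) cat(sprintf(", rho=%.3g km", x$cov$rho))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.risk_gls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, SE = object$se,
               t = object$tvals, p = object$pvals)
  structure(list(coefficients = tab, sigma2 = object$sigma2,
                 logLik = object$logLik, AICc = object$AICc,
                 n = object$n, weights = object$cov$weights,
                 rho = object$cov$rho, call = object$call),
            class = "summary.risk_gls")
}

#' @export
print.summary.risk_gls <- function(x, ...) {
  cat("Call: "); print(x$call)
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("sigma2 (ML) = %.4f, logLik = %.3f, AICc = %.3f, n = %d\n",
              x$sigma2, x$logLik, x$AICc, x$n))
  invisible(x)
}

#' @export
coef.risk_gls <- function(object, ...) object$coefficients

#' @export
fitted.risk_gls <- function(object, ...) object$fitted

#' @export
residuals.risk_gls <- function(object, ...) object$residuals

#' @export
logLik.risk_gls <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.risk_gls <- function(object, ...) object$vcov

#' @export
predict.risk_gls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}

#' @export
simulate.risk_gls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  draws <- MASS::mvrnorm(nsim, mu = object$fitted,
                         Sigma = object$sigma2 * object$cov$V)
  out <- as.data.frame(t(matrix(draws, nrow = nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.risk_gls <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  U <- chol(x$cov$V)
  white <- backsolve(U, x$residuals, transpose = TRUE) / sqrt(x$sigma2)
  plot(x$fitted, x$residuals, xlab = "Fitted", ylab = "Residual",
       main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(white, main = "Whitened residual QQ")
  stats::qqline(white)
  invisible(x)
}
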