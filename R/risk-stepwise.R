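#' Stepwise search for the minimum adequate model
#'
#' Backward-then-forward heuristic on AICc. Backward phase: at each round,
#' candidate predictors are ranked by decreasing p value (ties broken by
#' smaller absolute t, then column order) and the first whose deletion
#' improves AICc by at least `delta` is removed; the search stops when no
#' deletion qualifies. Forward phase: each deleted predictor is tried again
#' in deletion order and kept only if re-adding it improves AICc by at least
#' `delta`.
#'
#' The covariance structure of the starting fit is held fixed across all
#' refits so that AICc differences reflect the fixed-effects structure only.
#' A quadratic term listed in `hierarchy` is never retained without its
#' linear parent, and the parent is never deleted while the quadratic is in
#' the model.
#'
#' @param fit a [risk_gls] fit of the full model.
#' @param delta AICc improvement required to accept a step.
#' @param hierarchy named character vector mapping a term to the term it
#'   requires, e.g. `c(body_mass2 = "body_mass")`.
#' @param data data used for refits (defaults to the data stored in `fit`).
#' @return an object of class `risk_mam`: list with `fit` (final
#'   [risk_gls]), `trace` (decision log data.frame), `full_AICc`,
#'   `dropped` (terms absent from the final model).
#' @export
step_mam <- function(fit, delta = 2, hierarchy = NULL, data = fit$data) {
  stopifnot(inherits(fit, "risk_gls"))
  response <- all.vars(fit$formula)[1]
  terms_all <- attr(fit$terms, "term.labels")
  refit <- function(labels) {
    f <- stats::reformulate(if (length(labels)) labels else "1",
                            response = response)
    risk_gls(f, data, cov = fit$cov)
  }
  cur <- refit(terms_all)   # refit so AICc is comparable across all models
  trace <- list()
  note <- function(phase, term, cand, accepted) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, term = term, AICc_current = cur$AICc,
      AICc_candidate = cand, accepted = accepted)
  }
  required <- function(labels) {
    if (is.null(hierarchy)) return(character(0))
    unname(hierarchy[names(hierarchy) %in% labels])
  }
  term_p <- function(f) {
    asg <- attr(stats::model.matrix(f$terms, stats::model.frame(f$terms,
                                                                data)),
                "assign")
    labs <- attr(f$terms, "term.labels")
    p <- vapply(seq_along(labs),
                function(i) max(f$pvals[asg == i]), numeric(1))
    tv <- vapply(seq_along(labs),
                 function(i) min(abs(f$tvals[asg == i])), numeric(1))
    data.frame(term = labs, p = p, abs_t = tv, ord = seq_along(labs))
  }
  labels <- terms_all
  deleted <- character(0)
  # backward
  repeat {
    if (length(labels) == 0L) break
    tp <- term_p(cur)
    tp <- tp[!(tp$term %in% required(labels)), , drop = FALSE]
    if (nrow(tp) == 0L) break
    tp <- tp[order(-tp$p, tp$abs_t, tp$ord), , drop = FALSE]
    accepted <- FALSE
    for (tm in tp$term) {
      cand <- refit(setdiff(labels, tm))
      ok <- cand$AICc <= cur$AICc - delta
      note("backward", tm, cand$AICc, ok)
      if (ok) {
        labels <- setdiff(labels, tm)
        deleted <- c(deleted, tm)
        cur <- cand
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  # forward: try re-adding deleted terms in deletion order
  for (tm in deleted) {
    if (tm %in% labels) next
    parent <- if (!is.null(hierarchy) && tm %in% names(hierarchy))
      hierarchy[[tm]] else NULL
    if (!is.null(parent) && !(parent %in% labels)) {
      note("forward", tm, NA_real_, FALSE)
      next
    }
    cand <- refit(c(labels, tm))
    ok <- cand$AICc <= cur$AICc - delta
    note("forward", tm, cand$AICc, ok)
    if (ok) {
      labels <- c(labels, tm)
      cur <- cand
    }
  }
  structure(list(fit = cur, trace = do.call(rbind, trace),
                 full_AICc = refit(terms_all)$AICc,
                 retained = labels, dropped = setdiff(terms_all, labels)),
            class = "risk_mam")
}

#' @export
print.risk_mam <- function(x, ...) {
  cat("Minimum adequate model (stepwise AICc search)\n")
  cat(sprintf("Full model AICc: %.3f; MAM AICc: %.3f\n",
              x$full_AICc, x$fit$AICc))
  cat("Retained:", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "(intercept only)", "\n")
  if (length(x$dropped))
    cat("Dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
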