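#' Select target species under a protection criterion
#'
#' Under the `current` criterion, targets are the species whose encoded
#' ordinal status reaches the endangered range (EN or CR, i.e. ordinal >=
#' [endangered_ordinal_base()]). Under the `latent` criterion, targets are
#' species whose mean latent risk exceeds a threshold (default 1.50).
#' A literal top-decile cut is available as `mode = "decile"`.
#'
#' @param risk numeric vector of per-species risk (ordinal status for
#'   `current`, mean latent risk for `latent`), named by species.
#' @param criterion `"current"` or `"latent"`.
#' @param latent_threshold latent-risk cutoff for the latent criterion.
#' @param en_ordinal ordinal cutoff for the current criterion.
#' @param mode `"rule"` (the category/threshold rules) or `"decile"` (top
#'   10% of risk values).
#' @return logical vector (named) flagging target species.
#' @export
select_targets <- function(risk, criterion = c("current", "latent"),
                           latent_threshold = 1.5,
                           en_ordinal = endangered_ordinal_base(),
                           mode = c("rule", "decile")) {
  criterion <- match.arg(criterion)
  mode <- match.arg(mode)
  if (any(!is.finite(risk))) stopf("risk values must be finite")
  sel <- if (mode == "decile") {
    risk >= stats::quantile(risk, 0.9, names = FALSE)
  } else if (criterion == "current") {
    risk >= en_ordinal
  } else {
    risk > latent_threshold
  }
  if (!any(sel))
    stopf("no target species selected under the %s criterion; lower the threshold",
          criterion)
  sel
}

#' Scale target-species risk to [0.25, 0.75]
#'
#' Min-max map of the target species' raw risk values onto `[0.25, 0.75]`,
#' avoiding extremely high or low representation targets. If all raw values
#' are equal, every species gets 0.5.
#'
#' @param raw numeric vector of raw risk values of the target species.
#' @param lower,upper endpoints of the scaled range.
#' @return numeric vector of scaled risk `R`.
#' @export
scale_risk <- function(raw, lower = 0.25, upper = 0.75) {
  if (!length(raw)) stopf("need at least one target species")
  rng <- range(raw)
  if (diff(rng) <= 0) return(rep((lower + upper) / 2, length(raw)))
  lower + (raw - rng[1]) / diff(rng) * (upper - lower)
}

#' Representation-target proportion and amount
#'
#' `P = min(0.4 R + 0.6 A, cap)` where `R` is scaled risk and `A` the
#' proportion of the species' distribution inside the region; the cap
#' (default 75%) keeps every target feasible. The absolute target is
#' `T = P * area`.
#'
#' @param R scaled risk in `[0.25, 0.75]`.
#' @param A in-region distribution proportion in `[0, 1]`.
#' @param area species' represented range area in the region (km2).
#' @param cap maximum target proportion.
#' @return list with `P` (proportion) and `T` (km2).
#' @export
compute_target <- function(R, A, area = 0, cap = 0.75) {
  stopifnot(all(R >= 0.25 - 1e-9 & R <= 0.75 + 1e-9),
            all(A >= 0 & A <= 1))
  P <- pmin(0.4 * R + 0.6 * A, cap)
  list(P = P, T = P * area)
}

#' Build the representation-target table
#'
#' Applies [select_targets()], [scale_risk()], and [compute_target()] to a
#' per-species risk vector; non-target species get zero targets.
#'
#' @param risk named numeric vector (ordinal status or mean latent risk).
#' @param areas named numeric vector of represented range areas `A_j`
#'   (feature-matrix column totals, km2).
#' @param criterion,latent_threshold,mode passed to [select_targets()].
#' @param A named in-region distribution proportions (default 1: the
#'   synthetic region holds each species' full range).
#' @param cap target-proportion cap.
#' @return data.frame of class `target_table`: `species`, `target`
#'   (logical), `R_raw`, `R`, `A`, `P`, `T_km2`.
#' @export
build_targets <- function(risk, areas, criterion = c("current", "latent"),
                          latent_threshold = 1.5, A = 1, cap = 0.75,
                          mode = "rule") {
  criterion <- match.arg(criterion)
  sp <- names(risk)
  stopifnot(!is.null(sp), all(sp %in% names(areas)))
  areas <- areas[sp]
  if (length(A) == 1L) A <- stats::setNames(rep(A, length(sp)), sp)
  sel <- select_targets(risk, criterion, latent_threshold, mode = mode)
  R <- rep(0, length(sp)); P <- rep(0, length(sp)); T_km2 <- rep(0, length(sp))
  R[sel] <- scale_risk(risk[sel])
  tg <- compute_target(R[sel], A[sel], areas[sel], cap)
  P[sel] <- tg$P
  T_km2[sel] <- tg$T
  structure(data.frame(species = sp, target = unname(sel),
                       R_raw = unname(risk), R = R, A = unname(A),
                       P = P, T_km2 = T_km2, stringsAsFactors = FALSE),
            class = c("target_table", "data.frame"))
}
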