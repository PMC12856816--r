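#' Encode IUCN category and population trend as a 10-point ordinal
#'
#' Combines the five Red List categories with recent population trend into a
#' single pseudo-numeric response: base score LC = 1, NT = 3, VU = 5, EN = 7,
#' CR = 9, plus 1 if the trend is decreasing. The mapping is monotone in
#' category severity at fixed trend, reaches every level in 1..10, and is the
#' same coding the synthetic generator discretizes to.
#'
#' @param category character vector in `{LC, NT, VU, EN, CR}`.
#' @param trend character vector in
#'   `{increasing, stable, decreasing, unknown}`.
#' @return integer vector of ordinal scores in 1..10.
#' @export
encode_threat_ordinal <- function(category, trend) {
  base <- c(LC = 1L, NT = 3L, VU = 5L, EN = 7L, CR = 9L)
  trends <- c("increasing", "stable", "decreasing", "unknown")
  if (!all(category %in% names(base)))
    stopf("unknown category: %s",
          paste(unique(setdiff(category, names(base))), collapse = ", "))
  if (!all(trend %in% trends))
    stopf("unknown trend: %s",
          paste(unique(setdiff(trend, trends)), collapse = ", "))
  unname(base[category] + as.integer(trend == "decreasing"))
}

#' Ordinal score at which the endangered categories begin
#'
#' Species at or above this encoded score are EN or CR; used by the
#' current-risk target criterion.
#' @return integer scalar (7 under the package's coding).
#' @export
endangered_ordinal_base <- function() 7L

#' Filter the candidate species pool for comparative modelling
#'
#' Removes species unsuitable for the extinction-risk models: data-deficient
#' species, species listed for small geographic range (which would make the
#' range-size predictor circular), species with unresolved phylogenetic
#' placement, and species with insufficient geographic overlap with the
#' study region.
#'
#' @param pool data.frame with a `species` column and logical columns
#'   `data_deficient`, `criterion_b`, `unresolved_phylogeny`,
#'   `insufficient_overlap` (missing columns are treated as all-`FALSE`).
#' @return the retained subset, with the per-reason removal counts in
#'   attribute `"removed"`.
#' @export
filter_species_pool <- function(pool) {
  stopifnot("species" %in% names(pool))
  reasons <- c("data_deficient", "criterion_b", "unresolved_phylogeny",
               "insufficient_overlap")
  removed <- integer(0)
  drop <- rep(FALSE, nrow(pool))
  for (r in reasons) {
    flag <- if (r %in% names(pool)) pool[[r]] & !drop else FALSE
    removed[r] <- sum(flag)
    drop <- drop | (if (r %in% names(pool)) pool[[r]] else FALSE)
  }
  out <- pool[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Clean point-occurrence records
#'
#' Drops records without coordinates, records with coordinate uncertainty
#' above a threshold, and duplicated coordinates.
#'
#' @param occ data.frame with columns `lon`, `lat`, `uncertainty_km`.
#' @param max_uncertainty_km retain records with uncertainty at or below
#'   this value (km).
#' @return the filtered data.frame.
#' @export
clean_occurrences <- function(occ, max_uncertainty_km = 2) {
  stopifnot(all(c("lon", "lat", "uncertainty_km") %in% names(occ)))
  unc <- occ$uncertainty_km
  keep <- is.finite(occ$lon) & is.finite(occ$lat) &
    (is.na(unc) | unc <= max_uncertainty_km)
  out <- occ[keep, , drop = FALSE]
  out[!duplicated(out[, c("lon", "lat")]), , drop = FALSE]
}

#' Summarize spatial predictors over species ranges
#'
#' For each species: the mean of every environmental layer over its range
#' cells, its range size (cells x cell area), the proportion of its range
#' overlapped by each binary invader layer, and its range centroid.
#'
#' @param ranges named list of binary [rgrid] layers (1 = present).
#' @param env named list of [rgrid] environmental layers; names become
#'   predictor columns. Binary layers named in `overlap_layers` are
#'   summarized as overlap proportions.
#' @param traits data.frame with a `species` column matching `names(ranges)`;
#'   its remaining numeric columns are carried through.
#' @param overlap_layers names of `env` entries to treat as invader presence.
#' @return list with `predictors` (data.frame, one row per species) and
#'   `centroids` (matrix of range centroids, km).
#' @export
summarize_predictors <- function(ranges, env, traits = NULL,
                                 overlap_layers = c("fox", "toad")) {
  stopifnot(length(ranges) > 0)
  sp <- names(ranges)
  cell_area <- ranges[[1]]$cellsize^2
  cc <- cell_centers(ranges[[1]])
  rows <- vector("list", length(ranges))
  centroids <- matrix(NA_real_, length(ranges), 2,
                      dimnames = list(sp, c("x", "y")))
  for (j in seq_along(ranges)) {
    r <- ranges[[j]]
    if (!grid_compatible(r, ranges[[1]])) stopf("range grids are not aligned")
    cells <- which(r$values > 0)
    if (length(cells) == 0L) stopf("species %s has an empty range", sp[j])
    row <- list(species = sp[j],
                range_size = length(cells) * cell_area)
    for (nm in names(env)) {
      if (!grid_compatible(env[[nm]], r)) stopf("layer %s is not aligned", nm)
      v <- env[[nm]]$values[cells]
      row[[if (nm %in% overlap_layers) paste0(nm, "_overlap") else nm]] <-
        mean(v, na.rm = TRUE)
    }
    centroids[j, ] <- c(mean(cc$x[cells]), mean(cc$y[cells]))
    rows[[j]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  pred <- do.call(rbind, rows)
  if (!is.null(traits)) {
    stopifnot("species" %in% names(traits))
    pred <- merge(traits, pred, by = "species", sort = FALSE)
    pred <- pred[match(sp, pred$species), , drop = FALSE]
    rownames(pred) <- NULL
  }
  list(predictors = pred, centroids = centroids)
}

#' Transform and standardize predictor columns
#'
#' Log-transforms columns whose absolute skewness exceeds a threshold
#' (using `log(x + eps)` when a column contains zeros; columns with negative
#' values are never logged), then z-scores every column to mean 0, SD 1.
#' The transformation applied to each column is recorded in the
#' `"transform_log"` attribute.
#'
#' @param df data.frame of numeric predictor columns (non-numeric columns
#'   are passed through untouched).
#' @param skew_threshold absolute skewness above which a log transform is
#'   applied.
#' @param eps offset used for zero-containing columns.
#' @return data.frame of standardized predictors with attribute
#'   `transform_log` (data.frame: column, transform, skew_before,
#'   skew_after).
#' @export
transform_standardize <- function(df, skew_threshold = 1, eps = 1e-6) {
  num <- vapply(df, is.numeric, TRUE)
  log_rows <- list()
  for (nm in names(df)[num]) {
    x <- df[[nm]]
    if (max(x) - min(x) <= 0)
      stopf("predictor column '%s' is constant", nm)
    sk0 <- skewness(x)
    trans <- "z"
    if (abs(sk0) > skew_threshold && min(x) >= 0) {
      x <- log(x + if (min(x) == 0) eps else 0)
      trans <- "log+z"
    }
    sk1 <- skewness(x)
    df[[nm]] <- (x - mean(x)) / stats::sd(x)
    log_rows[[nm]] <- data.frame(column = nm, transform = trans,
                                 skew_before = sk0, skew_after = sk1)
  }
  attr(df, "transform_log") <- do.call(rbind, c(log_rows,
                                                make.row.names = FALSE))
  df
}

#' Variance-inflation-factor screen
#'
#' Iteratively removes the predictor with the highest VIF (`1 / (1 - R2)`
#' from regressing it on the remaining predictors) while any VIF exceeds the
#' threshold. Exactly collinear predictors (infinite VIF) are removed with a
#' warning rather than crashing.
#'
#' @param X numeric matrix or data.frame of predictors.
#' @param threshold VIF above which the worst predictor is dropped.
#' @return list with `retained` (column names kept), `removed` (dropped, in
#'   order), and `rounds` (list of named VIF vectors per iteration).
#' @export
vif_screen <- function(X, threshold = 5) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X))
    stopf("need more observations (%d) than predictors (%d)", nrow(X), ncol(X))
  keep <- colnames(X)
  removed <- character(0)
  rounds <- list()
  repeat {
    if (length(keep) < 2L) break
    vif <- vapply(keep, function(nm) {
      others <- setdiff(keep, nm)
      fit <- stats::lm.fit(cbind(1, X[, others, drop = FALSE]), X[, nm])
      r2 <- 1 - sum(fit$residuals^2) /
        sum((X[, nm] - mean(X[, nm]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    rounds[[length(rounds) + 1L]] <- vif
    worst <- names(which.max(vif))
    if (vif[[worst]] <= threshold) break
    if (!is.finite(vif[[worst]]))
      warnf("predictor '%s' is exactly collinear; removing it", worst)
    keep <- setdiff(keep, worst)
    removed <- c(removed, worst)
  }
  list(retained = keep, removed = removed, rounds = rounds)
}
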