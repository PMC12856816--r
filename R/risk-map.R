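#' Project per-species risk values onto the analysis grid
#'
#' `map_total()` sums a per-species value over all species present in each
#' cell (cells where no species occurs hold 0). `map_mean_positive_latent()`
#' averages latent risk over the species present whose latent risk is
#' strictly positive; cells with no such species are no-data (`NA`), because
#' a mean over an empty set is undefined.
#'
#' @param ranges named list of binary [rgrid] layers.
#' @param values named numeric vector of per-species values; every name must
#'   have a range.
#' @return an [rgrid].
#' @export
map_total <- function(ranges, values) {
  if (length(values) && is.null(names(values)))
    stopf("`values` must be named by species")
  miss <- setdiff(names(values), names(ranges))
  if (length(miss))
    stopf("species without a range: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(values))) stopf("risk values must be finite")
  acc <- ranges[[1]]$values * 0
  for (sp in names(values)) acc <- acc + ranges[[sp]]$values * values[[sp]]
  rgrid(acc, ranges[[1]]$xmin, ranges[[1]]$ymin, ranges[[1]]$cellsize)
}

#' @rdname map_total
#' @param latent named numeric vector of latent risk values.
#' @export
map_mean_positive_latent <- function(ranges, latent) {
  pos <- latent[latent > 0]
  num <- map_total(ranges, pos)
  cnt <- map_total(ranges, (pos > 0) * 1 + 0 * pos)
  m <- num$values / cnt$values
  m[cnt$values == 0] <- NA_real_
  rgrid(m, num$xmin, num$ymin, num$cellsize)
}

#' Current- and latent-risk map stack
#'
#' Builds the grid summaries of extinction risk: total and mean current risk
#' (on the 10-point ordinal scale), total and mean positive latent risk, and
#' species richness. Mean maps are no-data where the relevant species count
#' is zero.
#'
#' @param ranges named list of binary [rgrid] layers.
#' @param status named numeric vector of observed ordinal statuses.
#' @param latent named numeric vector of mean latent risk.
#' @return named list of [rgrid]: `richness`, `total_current`,
#'   `mean_current`, `total_latent_pos`, `mean_latent_pos`.
#' @export
risk_maps <- function(ranges, status, latent) {
  ones <- stats::setNames(rep(1, length(ranges)), names(ranges))
  richness <- map_total(ranges, ones)
  total_cur <- map_total(ranges, status)
  mean_cur <- total_cur$values / richness$values
  mean_cur[richness$values == 0] <- NA_real_
  lat_pos <- pmax(latent, 0)
  total_lat <- map_total(ranges, lat_pos)
  list(richness = richness,
       total_current = total_cur,
       mean_current = rgrid(mean_cur, richness$xmin, richness$ymin,
                            richness$cellsize),
       total_latent_pos = total_lat,
       mean_latent_pos = map_mean_positive_latent(ranges, latent))
}
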