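#' Assign grid cells to planning units
#'
#' Each cell belongs to the planning unit whose center is nearest to its
#' center (for this lattice the nearest-center rule reproduces the hexagons
#' exactly); cells falling in dropped or out-of-lattice positions get 0.
#' Ties (cell centers on a hexagon edge) go to the lower planning-unit id.
#'
#' @param pus a [tessellate_hexagons()] lattice.
#' @param grid an [rgrid] defining the cells.
#' @return integer matrix shaped like `grid$values` of PU ids (0 = none).
#' @export
map_cells_to_pus <- function(pus, grid) {
  cc <- cell_centers(grid)
  s <- attr(pus, "side_km")
  px <- pus$x; py <- pus$y
  ncell <- length(cc$x)
  assign <- integer(ncell)
  # distance from every cell to every PU center; modest sizes make this fine
  best <- rep(Inf, ncell)
  for (i in seq_along(px)) {
    d2 <- (cc$x - px[i])^2 + (cc$y - py[i])^2
    upd <- d2 < best - 1e-9
    assign[upd] <- pus$id[i]
    best[upd] <- d2[upd]
  }
  # a cell whose nearest retained center is farther than the circumradius
  # lies in a dropped hexagon
  assign[best > s^2 + 1e-9] <- 0L
  matrix(assign, nrow(grid$values), ncol(grid$values))
}

modal_value <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  tab <- table(v)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)  # ties at the mode resolve to the smaller value
}

#' Classify planning-unit land tenure
#'
#' Assigns each planning unit the tenure class covering the largest share of
#' its cells (the majority class when one exceeds 50%), with ties broken by
#' the fixed priority order of [tenure_classes()]. If the winning class is
#' `native_title` or `ILUA` and a pastoral overlay covers the majority of
#' the unit, the combined pastoral-use class is assigned. Units with no
#' covered cells are classified `other`.
#'
#' @param pus a [tessellate_hexagons()] lattice.
#' @param tenure categorical [rgrid] of tenure codes with a `levels`
#'   attribute.
#' @param cellmap cell-to-PU assignment from [map_cells_to_pus()] (built on
#'   demand if `NULL`).
#' @param pastoral optional binary [rgrid] marking pastoral-lease overlay.
#' @return character vector of tenure classes, one per planning unit.
#' @export
classify_tenure <- function(pus, tenure, cellmap = NULL, pastoral = NULL) {
  if (is.null(cellmap)) cellmap <- map_cells_to_pus(pus, tenure)
  lev <- attr(tenure, "levels")
  if (is.null(lev)) stopf("tenure grid lacks a `levels` attribute")
  prio <- tenure_classes()
  out <- character(nrow(pus))
  for (i in seq_len(nrow(pus))) {
    cells <- which(cellmap == pus$id[i])
    codes <- tenure$values[cells]
    codes <- codes[is.finite(codes) & codes > 0]
    if (!length(codes)) { out[i] <- "other"; next }
    cnt <- tabulate(codes, nbins = length(lev))
    winners <- lev[cnt == max(cnt)]
    cls <- winners[order(match(winners, prio))][1]
    if (!is.null(pastoral) && cls %in% c("native_title", "ILUA")) {
      pv <- pastoral$values[cells]
      if (mean(pv > 0, na.rm = TRUE) > 0.5)
        cls <- paste0(cls, "_pastoral")
    }
    out[i] <- cls
  }
  out
}

#' Proxy cost of planning units
#'
#' Extracts modal MEI and HII per planning unit, min-max normalizes each
#' variable to `[0, 1]` across units, rescales to `[0.01, 100]`, combines as
#' `cost = 0.4 * MEI' + 0.6 * HII'`, and finally multiplies by each unit's
#' area fraction `w` so that cropped units cost proportionally less. A
#' full-sized unit minimal in both variables costs exactly 0.01; one maximal
#' in both costs 100.
#'
#' @param pus a [tessellate_hexagons()] lattice.
#' @param mei,hii [rgrid] layers of median employee income and human
#'   influence index.
#' @param cellmap cell-to-PU assignment (built on demand if `NULL`).
#' @param weights numeric `c(mei, hii)` mixture weights.
#' @return list with `cost` (numeric per PU), `mei_modal`, `hii_modal`,
#'   `mei_scaled`, `hii_scaled`.
#' @export
compute_cost <- function(pus, mei, hii, cellmap = NULL,
                         weights = c(0.4, 0.6)) {
  if (is.null(cellmap)) cellmap <- map_cells_to_pus(pus, mei)
  modal <- function(g) vapply(pus$id, function(id)
    modal_value(g$values[cellmap == id]), numeric(1))
  m_mei <- modal(mei); m_hii <- modal(hii)
  rescale <- function(v) {
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) <= 0)
      stopf("cost layer is constant across planning units")
    0.01 + (v - rng[1]) / diff(rng) * (100 - 0.01)
  }
  s_mei <- rescale(m_mei); s_hii <- rescale(m_hii)
  cost <- (weights[1] * s_mei + weights[2] * s_hii) * pus$w
  list(cost = cost, mei_modal = m_mei, hii_modal = m_hii,
       mei_scaled = s_mei, hii_scaled = s_hii)
}

#' Species-by-planning-unit feature matrix
#'
#' `a_ij` is the area (km2) of species `j`'s range falling in planning unit
#' `i`, weighted by the unit's area fraction `w_i`. Column sums are the
#' species' represented totals `A_j` used as coverage denominators.
#'
#' @param pus a [tessellate_hexagons()] lattice.
#' @param ranges named list of binary [rgrid] layers.
#' @param cellmap cell-to-PU assignment (built on demand if `NULL`).
#' @return numeric matrix (`n_pu` x `n_species`, named) with attribute
#'   `totals` = `colSums`.
#' @export
build_features <- function(pus, ranges, cellmap = NULL) {
  if (is.null(cellmap)) cellmap <- map_cells_to_pus(pus, ranges[[1]])
  cell_area <- ranges[[1]]$cellsize^2
  n_pu <- nrow(pus)
  A <- matrix(0, n_pu, length(ranges),
              dimnames = list(pus$id, names(ranges)))
  for (j in seq_along(ranges)) {
    cells <- which(ranges[[j]]$values > 0)
    if (!length(cells)) {
      warnf("species %s has an empty range; zero feature row", names(ranges)[j])
      next
    }
    ids <- cellmap[cells]
    ids <- ids[ids > 0]
    if (length(ids)) {
      cnt <- tabulate(ids, nbins = max(pus$id))
      A[, j] <- cnt[pus$id] * cell_area * pus$w
    }
  }
  attr(A, "totals") <- colSums(A)
  A
}

#' Build the full planning-unit table
#'
#' Tessellates the boundary, assigns cells, classifies tenure, computes
#' proxy costs, flags locked-in units (existing PA and IPA tenure), and
#' assembles the species feature matrix.
#'
#' @param boundary two-column matrix of boundary polygon vertices (km).
#' @param side_km hexagon side (km).
#' @param tenure categorical tenure [rgrid] (with `levels`).
#' @param mei,hii cost-layer [rgrid]s.
#' @param ranges named list of binary species range [rgrid]s.
#' @param pastoral optional pastoral overlay [rgrid] for combined classes.
#' @param w_floor minimum retained PU area fraction.
#' @return list of class `pu_table`: `pus` (lattice data.frame with added
#'   `tenure`, `cost`, `locked_in`), `features`, `cellmap`, `cost_detail`.
#' @export
build_pu_table <- function(boundary, side_km, tenure, mei, hii, ranges,
                           pastoral = NULL, w_floor = 0.01) {
  lattice <- tessellate_hexagons(boundary, side_km, w_floor)
  cellmap <- map_cells_to_pus(lattice, tenure)
  lattice$tenure <- classify_tenure(lattice, tenure, cellmap, pastoral)
  cd <- compute_cost(lattice, mei, hii, cellmap)
  lattice$cost <- cd$cost
  lattice$locked_in <- lattice$tenure %in% c("PA", "IPA")
  feats <- build_features(lattice, ranges, cellmap)
  structure(list(pus = lattice, features = feats, cellmap = cellmap,
                 cost_detail = cd),
            class = "pu_table")
}

#' @export
print.pu_table <- function(x, ...) {
  cat(sprintf("<pu_table> %d PUs, %d species; %d locked in (PA/IPA)\n",
              nrow(x$pus), ncol(x$features), sum(x$pus$locked_in)))
  print(table(x$pus$tenure))
  invisible(x)
}
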