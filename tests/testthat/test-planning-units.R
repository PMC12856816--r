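test_that("hexagon geometry matches the closed form", {
  hg <- hexagon_geometry(7.5)
  expect_equal(hg$perimeter_km, 45)
  expect_equal(round(hg$area_km2), 146)
  expect_equal(hexagon_geometry(1)$perimeter_km, 6)
  expect_equal(hexagon_geometry(2)$area_km2, 1.5 * sqrt(3) * 4)
  expect_error(hexagon_geometry(0), "positive")
})

test_that("tessellation conserves area and weights interior units fully", {
  boundary <- cbind(x = c(0, 60, 60, 0), y = c(0, 0, 50, 50))
  pus <- tessellate_hexagons(boundary, side_km = 4)
  full <- hexagon_geometry(4)$area_km2
  # union of clipped areas reproduces the boundary area to 0.1%
  expect_lt(abs(sum(pus$area_km2) - 60 * 50) / (60 * 50), 0.001)
  # interior units (centers well inside) have w = 1
  interior <- pus$x > 8 & pus$x < 52 & pus$y > 8 & pus$y < 42
  expect_true(all(abs(pus$w[interior] - 1) < 1e-9))
  expect_true(all(pus$w > 0 & pus$w <= 1 + 1e-12))
  # lattice adjacency: all neighbor center distances are sqrt(3) * side
  adj <- attr(pus, "adjacency")
  d <- sqrt((pus$x[adj[, 1]] - pus$x[adj[, 2]])^2 +
              (pus$y[adj[, 1]] - pus$y[adj[, 2]])^2)
  expect_true(all(abs(d - sqrt(3) * 4) < 1e-6))
  expect_error(tessellate_hexagons(cbind(c(0, 1), c(0, 1)), 4), "polygon")
})

test_that("cells map to the hexagon that contains them", {
  boundary <- cbind(x = c(0, 30, 30, 0), y = c(0, 0, 30, 30))
  pus <- tessellate_hexagons(boundary, side_km = 3)
  g <- rgrid(matrix(0, 30, 30))
  cm <- map_cells_to_pus(pus, g)
  expect_true(all(cm >= 0))
  expect_gt(mean(cm > 0), 0.99)
  # every assigned cell center lies inside (or on) its hexagon
  cc <- cell_centers(g)
  hexes <- attr(pus, "hex_vertices")
  idx <- which(cm > 0)
  sampled <- idx[seq(1, length(idx), by = 17)]
  for (i in sampled) {
    hx <- hexes[[cm[i]]]
    expect_true(tenureplan:::points_in_polygon(cc$x[i], cc$y[i], hx))
  }
})

test_that("tenure classification follows majority, priority, and pastoral-use rules", {
  # a single planning unit covering the whole 10 x 10 grid, via an explicit
  # cell assignment
  pus <- data.frame(id = 1L, x = 5, y = 5, w = 1,
                    area_km2 = hexagon_geometry(1)$area_km2)
  attr(pus, "side_km") <- 1
  class(pus) <- c("pu_lattice", "data.frame")
  cellmap <- matrix(1L, 10, 10)
  classify1 <- function(tenure, pastoral = NULL)
    classify_tenure(pus, tenure, cellmap, pastoral)
  mk_tenure <- function(v) {
    g <- rgrid(matrix(v, 10, 10))
    attr(g, "levels") <- c("pastoral", "indigenous_freehold", "native_title",
                           "ILUA", "PA")
    g
  }
  # 60/40 pastoral vs freehold: pastoral wins the majority
  t1 <- mk_tenure(c(rep(1, 60), rep(2, 40)))
  expect_equal(classify1(t1), "pastoral")
  # exact 50/50: the documented priority order favors indigenous_freehold
  t2 <- mk_tenure(c(rep(1, 50), rep(2, 50)))
  expect_equal(classify1(t2), "indigenous_freehold")
  # Native Title majority with a pastoral overlay on most of the unit
  t3 <- mk_tenure(c(rep(3, 70), rep(5, 30)))
  pastoral_overlay <- rgrid(matrix(c(rep(1, 60), rep(0, 40)), 10, 10))
  expect_equal(classify1(t3, pastoral_overlay), "native_title_pastoral")
  # same overlay under an ILUA majority
  t4 <- mk_tenure(c(rep(4, 70), rep(5, 30)))
  expect_equal(classify1(t4, pastoral_overlay), "ILUA_pastoral")
})

test_that("proxy costs reach the printed bounds and scale with area fraction", {
  boundary <- cbind(x = c(0, 40, 40, 0), y = c(0, 0, 40, 40))
  pus <- tessellate_hexagons(boundary, side_km = 5)
  g0 <- rgrid(matrix(0, 40, 40))
  cm <- map_cells_to_pus(pus, g0)
  full <- which(abs(pus$w - 1) < 1e-9)
  # layers constant per PU: value = PU id, so one unit holds both minima
  mei <- hii <- g0
  mei$values[cm > 0] <- cm[cm > 0]
  hii$values[cm > 0] <- 2 * cm[cm > 0]
  cd <- compute_cost(pus, mei, hii, cm)
  lo <- which.min(pus$id)  # id 1 is minimal in both
  expect_equal(cd$cost[lo] / pus$w[lo], 0.01, tolerance = 1e-9)
  hi <- which.max(pus$id)
  expect_equal(cd$cost[hi] / pus$w[hi], 100, tolerance = 1e-9)
  # weighted-sum arithmetic: scaled components combine as 0.4/0.6
  expect_equal(cd$cost, (0.4 * cd$mei_scaled + 0.6 * cd$hii_scaled) * pus$w)
  expect_error(compute_cost(pus, g0, hii, cm), "constant")
})

test_that("modal extraction takes the most frequent value, smaller on ties", {
  expect_equal(tenureplan:::modal_value(c(1, 1, 2, 3)), 1)
  expect_equal(tenureplan:::modal_value(c(5, 5, 2, 2, 9)), 2)
  expect_equal(tenureplan:::modal_value(c(NA, 4, 4, 7)), 4)
})

test_that("feature amounts accumulate ranges cell by cell", {
  boundary <- cbind(x = c(0, 24, 24, 0), y = c(0, 0, 24, 24))
  pus <- tessellate_hexagons(boundary, side_km = 3)
  cfg <- small_config()
  rg <- simulate_ranges(cfg, target_sizes = c(40L, 160L, 1L), seed = 9)
  cm <- map_cells_to_pus(pus, rg[[1]])
  feats <- build_features(pus, rg, cm)
  # double-loop oracle
  oracle <- matrix(0, nrow(pus), 3)
  for (j in 1:3) {
    cells <- which(rg[[j]]$values > 0)
    for (cell in cells) {
      i <- cm[cell]
      if (i > 0) {
        row <- match(i, pus$id)
        oracle[row, j] <- oracle[row, j] + pus$w[row]
      }
    }
  }
  expect_equal(unname(feats), oracle, ignore_attr = TRUE)
  # single-cell species occupies exactly one planning unit
  expect_equal(sum(feats[, 3] > 0), 1)
  # with all weights forced to 1 the totals reconstruct range areas exactly
  pus1 <- pus
  pus1$w <- rep(1, nrow(pus))
  feats1 <- build_features(pus1, rg, cm)
  covered <- vapply(rg, function(g) sum(g$values[cm > 0]), 1)
  expect_equal(unname(attr(feats1, "totals")), unname(covered))
})
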