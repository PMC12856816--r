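# Small shared fixtures, built in code at test time.

small_config <- function(seed = 1L, ...) {
  sim_config(grid_nrows = 24L, grid_ncols = 24L, n_species = 8L,
             n_trees = 3L, margin_cells = 0L, smooth_sigma = 3,
             range_frac = c(0.05, 0.3), seed = seed, ...)
}

# a handful of aligned binary ranges on a tiny grid
tiny_ranges <- function(nr = 6, nc = 6, patches = list(1:4, 10:18, 20)) {
  out <- lapply(patches, function(cells) {
    m <- matrix(0, nr, nc)
    m[cells] <- 1
    rgrid(m)
  })
  names(out) <- sprintf("sp%03d", seq_along(out))
  out
}

# deterministic flat pu_table-like object for prioritizer tests
fake_pu_table <- function(cost, features, tenure, locked_in = NULL,
                          side = 1) {
  n <- nrow(features)
  pus <- data.frame(id = seq_len(n), x = seq_len(n) * 2 * side, y = 0,
                    w = 1, area_km2 = hexagon_geometry(side)$area_km2)
  pus$tenure <- tenure
  pus$cost <- cost
  pus$locked_in <- seq_len(n) %in% locked_in
  attr(pus, "side_km") <- side
  attr(pus, "adjacency") <- matrix(integer(0), ncol = 2)
  class(pus) <- c("pu_lattice", "data.frame")
  colnames(features) <- sprintf("sp%03d", seq_len(ncol(features)))
  rownames(features) <- pus$id
  attr(features, "totals") <- colSums(features)
  structure(list(pus = pus, features = features, cellmap = NULL),
            class = "pu_table")
}

# exhaustive minimum-cost covering oracle over all 2^n subsets
brute_force_cover <- function(cost, features, targets) {
  n <- length(cost)
  best <- Inf
  best_set <- NULL
  for (s in 0:(2^n - 1)) {
    sel <- which(bitwAnd(s, 2^(seq_len(n) - 1)) > 0)
    got <- if (length(sel)) colSums(features[sel, , drop = FALSE]) else
      rep(0, ncol(features))
    if (all(got >= targets - 1e-9)) {
      cs <- sum(cost[sel])
      if (cs < best - 1e-12) { best <- cs; best_set <- sel }
    }
  }
  list(cost = best, sel = best_set)
}

# 4-connected flood fill from the first occupied cell; returns reached cells
flood_fill4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  occ <- which(m > 0)
  if (!length(occ)) return(integer(0))
  seen <- logical(length(m))
  stack <- occ[1]
  seen[occ[1]] <- TRUE
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    r <- ((i - 1) %% nr) + 1
    c <- ((i - 1) %/% nr) + 1
    for (nbr in c(if (r > 1) i - 1, if (r < nr) i + 1,
                  if (c > 1) i - nr, if (c < nc) i + nr)) {
      if (!seen[nbr] && m[nbr] > 0) {
        seen[nbr] <- TRUE
        stack <- c(stack, nbr)
      }
    }
  }
  which(seen)
}
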