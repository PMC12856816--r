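#' Simulate environmental raster layers
#'
#' Spatially autocorrelated continuous layers (Gaussian-filtered white noise,
#' rescaled to plausible units) for wet-quarter temperature, total and late
#' dry season fire frequency, human influence index (HII) and median employee
#' income (MEI), plus binary presence layers for two invasive species (fox
#' and cane toad) obtained by thresholding smoothed fields.
#'
#' @param config a [sim_config].
#' @param seed integer seed (defaults to `config$seed`).
#' @return named list of [rgrid] layers: `temp_wet_q`, `fire_total`,
#'   `fire_lds`, `hii`, `mei`, `fox`, `toad`.
#' @export
simulate_landscape <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  nr <- config$grid_nrows; nc <- config$grid_ncols
  field <- function(sigma = config$smooth_sigma) {
    f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
    (f - min(f)) / (max(f) - min(f))  # [0, 1]
  }
  g <- function(m) rgrid(m, 0, 0, config$cell_size)
  list(
    temp_wet_q = g(24 + 6 * field()),              # degrees C
    fire_total = g(round(12 * field())),           # years burnt of 12
    fire_lds   = g(round(8 * field())),            # late dry season years
    hii        = g(round(61 * field()^2)),         # 0-61 index, right-skewed
    mei        = g(round(300 + 900 * field()^2)),  # weekly income, skewed
    fox        = g((field() > 0.65) * 1),
    toad       = g((field() > 0.55) * 1))
}

grid_neighbors4 <- function(nr, nc) {
  # returns function(idx) -> integer vector of rook neighbors of cell idx
  function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    nb <- c(if (r > 1L) idx - 1L, if (r < nr) idx + 1L,
            if (c > 1L) idx - nr, if (c < nc) idx + nr)
    nb
  }
}

# Grow one connected patch of `size` cells from `start` by spreading dye:
# repeatedly pick a uniformly random frontier cell (seeded RNG) and add it.
# `blocked` is a logical vector of cells that may not be used.
spread_dye <- function(nr, nc, size, start, blocked = NULL) {
  ncell <- nr * nc
  nb <- grid_neighbors4(nr, nc)
  in_patch <- logical(ncell)
  if (is.null(blocked)) blocked <- logical(ncell)
  stopifnot(!blocked[start])
  in_patch[start] <- TRUE
  frontier <- setdiff(nb(start), which(blocked))
  on_front <- logical(ncell)
  on_front[frontier] <- TRUE
  grown <- 1L
  while (grown < size && length(frontier) > 0L) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    on_front[pick] <- FALSE
    in_patch[pick] <- TRUE
    grown <- grown + 1L
    for (v in nb(pick)) {
      if (!in_patch[v] && !on_front[v] && !blocked[v]) {
        frontier <- c(frontier, v)
        on_front[v] <- TRUE
      }
    }
  }
  if (grown < size) stopf("spreading dye stalled at %d of %d cells", grown, size)
  which(in_patch)
}

#' Simulate species ranges as connected patches
#'
#' Each species' range is a single 4-connected patch grown by spreading dye
#' from a random seed cell until it reaches exactly its target size. Ranges
#' grow on the region grid extended by `config$margin_cells` on every side
#' (the seed cell always lies inside the region), so a range may extend
#' beyond the study region; the returned grids are clipped to the region
#' and each species' in-region proportion is reported.
#'
#' @param config a [sim_config].
#' @param target_sizes integer vector of global range sizes in cells, one
#'   per species (each in `[1, n extended cells]`). If `NULL`, sizes are
#'   drawn log-uniformly between `config$range_frac` fractions of the
#'   region grid.
#' @param seed integer seed.
#' @return named list of binary [rgrid] layers (1 = present) clipped to the
#'   region, with attributes `A` (named in-region proportions) and
#'   `global_cells` (named global range sizes in cells).
#' @export
simulate_ranges <- function(config, target_sizes = NULL, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  nr <- config$grid_nrows; nc <- config$grid_ncols
  m <- config$margin_cells
  nre <- nr + 2L * m; nce <- nc + 2L * m
  ncell_region <- nr * nc
  if (is.null(target_sizes)) {
    lf <- stats::runif(config$n_species, log(config$range_frac[1]),
                       log(config$range_frac[2]))
    target_sizes <- pmax(1L, round(exp(lf) * ncell_region))
  }
  if (any(target_sizes < 1L)) stopf("range target sizes must be >= 1")
  if (any(target_sizes > nre * nce)) stopf("range target size exceeds grid size")
  n_sp <- length(target_sizes)
  out <- vector("list", n_sp)
  A <- numeric(n_sp)
  for (j in seq_len(n_sp)) {
    # seed cell inside the region window of the extended grid
    r0 <- sample.int(nr, 1L) + m
    c0 <- sample.int(nc, 1L) + m
    start <- (c0 - 1L) * nre + r0
    cells <- spread_dye(nre, nce, target_sizes[j], start)
    ext <- matrix(0, nre, nce)
    ext[cells] <- 1
    reg <- ext[(m + 1L):(m + nr), (m + 1L):(m + nc), drop = FALSE]
    A[j] <- sum(reg) / target_sizes[j]
    out[[j]] <- rgrid(reg, 0, 0, config$cell_size)
  }
  names(out) <- species_labels(n_sp)
  attr(out, "A") <- stats::setNames(A, names(out))
  attr(out, "global_cells") <- stats::setNames(as.integer(target_sizes),
                                               names(out))
  out
}

#' Simulate a land-tenure raster and protected-area mask
#'
#' Grows contiguous tenure patches by multi-source spreading dye so that the
#' realized class proportions match `config$tenure_mix` up to integer
#' rounding. Classes listed in `dispersed_classes` (by default the
#' non-Indigenous, non-protected tenures) are grown first as many smaller
#' patches from seeds kept at least `min_seed_dist` cells apart, emulating
#' scattered leasehold and freehold blocks within a larger Indigenous
#' estate; the remaining classes fill the landscape as large clumps. The
#' protected-area mask marks cells whose class is PA or IPA.
#'
#' @param config a [sim_config].
#' @param seed integer seed.
#' @param n_patches seed patches per clumped tenure class.
#' @param dispersed_classes classes grown as dispersed patches.
#' @param patch_cells approximate dispersed patch size (cells).
#' @param min_seed_dist minimum distance (cells) between dispersed seeds.
#' @return list with `tenure` (an [rgrid] of integer class codes with a
#'   `levels` attribute), and `pa_mask` (binary [rgrid]).
#' @export
simulate_tenure <- function(config, seed = config$seed, n_patches = 4L,
                            dispersed_classes = c("ILUA", "ILUA_pastoral",
                                                  "pastoral", "other"),
                            patch_cells = 110L, min_seed_dist = 45) {
  validate_sim_config(config)
  set.seed(seed)
  nr <- config$grid_nrows; nc <- config$grid_ncols
  ncell <- nr * nc
  mix <- config$tenure_mix[config$tenure_mix > 0]
  k <- length(mix)
  quota <- floor(mix * ncell)
  rem <- ncell - sum(quota)
  if (rem > 0) {  # distribute remainder by largest fractional part
    fr <- order(mix * ncell - quota, decreasing = TRUE)
    quota[fr[seq_len(rem)]] <- quota[fr[seq_len(rem)]] + 1L
  }
  assigned <- integer(ncell)  # 0 = unassigned, else class index
  nb <- grid_neighbors4(nr, nc)
  need <- as.integer(quota)
  grow_class <- function(ci, cells_to_add, seeds) {
    frontier <- integer(0)
    for (s in seeds) {
      if (assigned[s] != 0L || cells_to_add == 0L) next
      assigned[s] <<- ci
      cells_to_add <- cells_to_add - 1L
      frontier <- c(frontier, nb(s))
    }
    while (cells_to_add > 0L) {
      frontier <- frontier[assigned[frontier] == 0L]
      if (!length(frontier)) {
        free <- which(assigned == 0L)
        if (!length(free)) break
        s <- free[sample.int(length(free), 1L)]
        assigned[s] <<- ci
        cells_to_add <- cells_to_add - 1L
        frontier <- nb(s)
        next
      }
      pick <- frontier[sample.int(length(frontier), 1L)]
      assigned[pick] <<- ci
      cells_to_add <- cells_to_add - 1L
      frontier <- c(frontier[frontier != pick], nb(pick))
    }
    cells_to_add
  }
  cell_rc <- function(idx) cbind(((idx - 1L) %% nr) + 1L,
                                 ((idx - 1L) %/% nr) + 1L)
  # phase 1: dispersed classes as spaced, PU-scale patches
  disp_seeds <- matrix(numeric(0), ncol = 2)
  disp <- which(names(mix) %in% dispersed_classes)
  for (ci in disp) {
    n_seeds <- max(1L, round(quota[ci] / patch_cells))
    seeds <- integer(0)
    tries <- 0L
    while (length(seeds) < n_seeds && tries < 2000L) {
      tries <- tries + 1L
      cand <- sample.int(ncell, 1L)
      rc <- cell_rc(cand)
      if (nrow(disp_seeds) &&
          min(sqrt((disp_seeds[, 1] - rc[1])^2 +
                   (disp_seeds[, 2] - rc[2])^2)) < min_seed_dist) next
      if (assigned[cand] != 0L) next
      seeds <- c(seeds, cand)
      disp_seeds <- rbind(disp_seeds, rc)
    }
    if (!length(seeds)) {  # spacing impossible on a small grid: any free cell
      free <- which(assigned == 0L)
      seeds <- free[sample.int(length(free), 1L)]
    }
    # grow each seed's patch to an equal share of the class quota
    per <- diff(round(seq(0, quota[ci], length.out = length(seeds) + 1L)))
    left <- 0L
    for (si in seq_along(seeds))
      left <- left + grow_class(ci, per[si], seeds[si])
    if (left > 0L) left <- grow_class(ci, left, seeds[1])
    need[ci] <- left
  }
  # phase 2: clumped classes fill the remainder
  clump <- setdiff(seq_len(k), disp)
  for (ci in clump[order(-need[clump])]) {
    free <- which(assigned == 0L)
    ns <- min(n_patches, max(1L, need[ci] %/% 200L + 1L), length(free))
    seeds <- free[sample.int(length(free), ns)]
    need[ci] <- grow_class(ci, need[ci], seeds)
  }
  # mop up any shortfall (e.g. failed seed placement) before giving up
  for (ci in seq_len(k)) {
    if (need[ci] > 0L && any(assigned == 0L))
      need[ci] <- grow_class(ci, need[ci], integer(0))
  }
  assigned[assigned == 0L] <- which.max(quota)
  m <- matrix(assigned, nr, nc)
  tenure <- rgrid(m, 0, 0, config$cell_size)
  attr(tenure, "levels") <- names(mix)
  pa <- matrix(as.numeric(names(mix)[assigned] %in% c("PA", "IPA")), nr, nc)
  list(tenure = tenure, pa_mask = rgrid(pa, 0, 0, config$cell_size))
}
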