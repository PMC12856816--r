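#' Simulate a sample of ultrametric phylogenies
#'
#' Draws `n_trees` birth-death trees with a shared set of tip labels,
#' rescaled to unit root-to-tip height, emulating a random sample from a
#' posterior set of species trees.
#'
#' @param n_species number of tips (>= 3).
#' @param n_trees number of trees (>= 1).
#' @param seed integer seed.
#' @param birth,death birth-death rates of the simulation.
#' @return a `multiPhylo` list of ultrametric [ape::phylo] trees whose tip
#'   labels are `sp001, sp002, ...` in every tree.
#' @export
simulate_phylogenies <- function(n_species, n_trees, seed = 1L,
                                 birth = 1, death = 0.4) {
  if (n_species < 3L) stopf("n_species must be >= 3")
  if (n_trees < 1L) stopf("n_trees must be >= 1")
  set.seed(seed)
  labels <- species_labels(n_species)
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- ape::rphylo(n_species, birth = birth, death = death)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr$tip.label <- labels
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"
  trees
}

species_labels <- function(n) sprintf("sp%03d", seq_len(n))

#' Simulate life-history traits on a phylogeny
#'
#' Brownian motion on the log scale along the tree plus independent
#' log-normal noise, for four mammalian life-history traits: adult body mass
#' (g), age at first reproduction (y), litters per year, and litter size.
#' Trait values are always positive.
#'
#' @param tree an ultrametric [ape::phylo] tree.
#' @param trait_params list with elements `root` (named vector of trait means
#'   on the natural scale), `sigma2_bm` (Brownian rate on the log scale,
#'   >= 0) and `sigma2_noise` (independent log-scale noise variance, >= 0).
#' @param seed integer seed.
#' @return data.frame with one row per tip: `species`, `body_mass_g`,
#'   `age_first_repro`, `litters_per_year`, `litter_size`.
#' @export
simulate_traits <- function(tree,
                            trait_params = list(
                              root = c(body_mass_g = 150,
                                       age_first_repro = 1,
                                       litters_per_year = 1.5,
                                       litter_size = 3),
                              sigma2_bm = 1, sigma2_noise = 0.05),
                            seed = 1L) {
  if (!inherits(tree, "phylo")) stopf("`tree` must be a phylo object")
  if (trait_params$sigma2_bm < 0 || trait_params$sigma2_noise < 0)
    stopf("variance parameters must be non-negative")
  set.seed(seed)
  n <- length(tree$tip.label)
  C <- ape::vcv(tree)
  out <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  for (tr in names(trait_params$root)) {
    mu <- rep(log(trait_params$root[[tr]]), n)
    g <- if (trait_params$sigma2_bm > 0)
      MASS::mvrnorm(1, mu, trait_params$sigma2_bm * C) else mu
    eps <- if (trait_params$sigma2_noise > 0)
      stats::rnorm(n, 0, sqrt(trait_params$sigma2_noise)) else 0
    out[[tr]] <- exp(g + eps)
  }
  rownames(out) <- NULL
  out
}
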