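# Demonstration configuration: the package's reference study conditions.
# A 100 x 100 km savanna region on a 1-km grid, 60 mammal species, a
# 20-tree phylogeny sample, an Indigenous-estate-dominated tenure mosaic
# with 18% already protected, and 10% of species under-listed relative to
# their true risk.
sim:
  grid_nrows: 100
  grid_ncols: 100
  cell_size: 1.0
  n_species: 60
  n_trees: 20
  pa_fraction: 0.18
  suppressed_fraction: 0.1
  smooth_sigma: 8.0
  margin_cells: 30
  seed: 1
model:
  vif_threshold: 5.0
  skew_threshold: 1.0
  delta_aicc: 2.0
  estimate_cov: true
targets:
  latent_threshold: 1.5
  cap: 0.75
plan:
  side_km: 7.5
  w_floor: 0.01
  gap: 0.1
  node_limit: 150000
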