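# Shared helpers: tiny fast configs and small generated scenes.

# A 3x3 stand with a reduced ray budget: seconds per simulated day.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(nx = 3, ny = 3, n_competitors = 4, n_stands = 1, days = 6,
         source = light_source(n_rays = 4000, seed = 1),
         cover_resolution = 12L, tip_dirs = 16L),
    list(...))
  do.call(scenario_config, args)
}

inert_phenotype <- function() {
  sas_params(r_fr_threshold = 0, hyponasty_rate = 0, touch_enabled = FALSE)
}

# A random mini-canopy of fully grown leaves (deterministic per seed).
random_scene <- function(seed, n_plants = 4, n_leaves = 4, spread = 0.04) {
  set.seed(seed)
  plants <- lapply(seq_len(n_plants), function(i) {
    p <- build_rosette(inert_phenotype(), 0,
                       runif(2, -spread, spread), id = i,
                       azimuth0 = runif(1, 0, 360))
    for (r in seq_len(n_leaves)) {
      p <- add_leaf(p, r,
                    petiole_length = runif(1, 3, 15),
                    petiole_angle = runif(1, 0, 80),
                    azimuth = (p$azimuth0 + (r - 1) * 137.508) %% 360,
                    lamina_length = runif(1, 5, 25),
                    lamina_width = runif(1, 3, 12))
    }
    p
  })
  new_scene(plants)
}

# One plant with a single leaf whose lamina is centered on the origin (and
# so lies fully inside the `half` box when horizontal).
one_leaf_scene <- function(petiole = 5, L = 20, W = 10, angle = 0,
                           azimuth = 0, half = 0.02) {
  p <- build_rosette(inert_phenotype(), 0,
                     c(-(petiole + L / 2) * 1e-3, 0))
  p <- add_leaf(p, 1, petiole, angle, azimuth, L, W)
  new_scene(list(p), c(-half, half, -half, half))
}

opaque_optics <- function() {
  leaf_optics(par = c(1, 0, 0), r = c(1, 0, 0), fr = c(1, 0, 0))
}
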