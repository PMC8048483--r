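# Monte-Carlo two-band (R, FR) + PAR light transport over organ polygons,
# soil tiles and lamina-tip sensors.

BAND_NAMES <- c("PAR", "R", "FR")

#' Light source specification
#'
#' The source emits PAR at `par` umol m-2 s-1 on a horizontal unobstructed
#' plane with an R:FR ratio of `r_fr` — the defaults match the
#' growth-chamber calibration (220 and 2.3).
#'
#' @param par PAR intensity, umol m-2 s-1 (> 0).
#' @param r_fr red:far-red ratio of the source (> 0).
#' @param angular_model `"overcast-diffuse"` (cosine-weighted hemisphere,
#'   the default for growth-chamber diffuse lighting), `"vertical"`
#'   (analytic test mode) or `"uniform-hemisphere"`.
#' @param n_rays Monte-Carlo rays per band.
#' @param seed integer seed for the tracer.
#' @return object of class `light_source`.
#' @export
light_source <- function(par = 220, r_fr = 2.3,
                         angular_model = c("overcast-diffuse", "vertical",
                                           "uniform-hemisphere"),
                         n_rays = 200000L, seed = 1L) {
  stopifnot(par > 0, r_fr > 0, n_rays >= 1)
  angular_model <- match.arg(angular_model)
  structure(list(par = par, r_fr = r_fr, angular_model = angular_model,
                 n_rays = as.integer(n_rays), seed = as.integer(seed)),
            class = "light_source")
}

#' Leaf optical properties per band
#'
#' Per band (PAR, R, FR): absorptance, reflectance and transmittance summing
#' to one. Defaults follow typical leaf spectra — strong absorption of PAR
#' and red, strong scattering of far-red — so that the R:FR ratio collapses
#' under one or two leaf layers. Petioles are opaque black.
#'
#' @param par,r,fr length-3 numeric `c(absorptance, reflectance,
#'   transmittance)` for each band.
#' @return object of class `leaf_optics` (a 3 x 3 matrix, bands in rows).
#' @export
leaf_optics <- function(par = c(0.85, 0.075, 0.075),
                        r = c(0.90, 0.05, 0.05),
                        fr = c(0.10, 0.45, 0.45)) {
  m <- rbind(PAR = par, R = r, FR = fr)
  colnames(m) <- c("absorptance", "reflectance", "transmittance")
  if (any(m < 0) || any(m > 1)) stop("optical coefficients must be in [0,1]")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("absorptance + reflectance + transmittance must equal 1 per band")
  structure(m, class = c("leaf_optics", "matrix"))
}

default_optics_matrix <- function() unclass(leaf_optics())

#' Virtual soil-tile grid
#'
#' Tiles capture the PAR reaching the soil. The default covers the 10 cm x
#' 10 cm (100 cm2) region underneath the middle 16 canopy plants of the
#' default stand, split into `n x n` tiles.
#'
#' @param region `c(xmin, xmax, ymin, ymax)` m.
#' @param n tiles per axis.
#' @return data.frame with one row per tile (bounds and area), class
#'   `soil_tile_grid`.
#' @export
soil_tile_grid <- function(region = c(-0.05, 0.05, -0.05, 0.05), n = 5) {
  xs <- seq(region[1], region[2], length.out = n + 1)
  ys <- seq(region[3], region[4], length.out = n + 1)
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  df <- data.frame(tile = seq_len(nrow(g)),
                   xmin = xs[g$i], xmax = xs[g$i + 1],
                   ymin = ys[g$j], ymax = ys[g$j + 1])
  df$area <- (df$xmax - df$xmin) * (df$ymax - df$ymin)
  structure(df, class = c("soil_tile_grid", "data.frame"),
            region = region)
}

band_intensities <- function(source) {
  c(PAR = source$par, R = source$r_fr, FR = 1)
}

#' Trace radiation through a scene
#'
#' Forward Monte-Carlo transport of the three bands, each with its own
#' optical coefficients and independent rays. Scattering is Lambertian
#' (reflect or transmit), up to `max_bounces` bounces with Russian-roulette
#' termination, so far-red enrichment under leaves emerges from multiple
#' scattering. Lamina-tip R:FR sensing uses cosine-weighted upward
#' transmission sampling from each tip (the sensor does not occlude).
#' Rays are emitted over the scene bounds expanded by `margin`; results are
#' seed-reproducible.
#'
#' @param scene a `canopy_scene`.
#' @param source a [light_source()].
#' @param optics a [leaf_optics()].
#' @param tiles a [soil_tile_grid()].
#' @param max_bounces maximum scattering depth (default 5).
#' @param rr_threshold relative weight below which Russian roulette starts.
#' @param tip_dirs sensing directions per lamina tip.
#' @param margin emission margin beyond the scene bounds, m.
#' @return object of class `radiation_result`: per-organ absorbed PAR
#'   (umol s-1), per-tile soil PAR (umol m-2 s-1), per-leaf tip R:FR, and
#'   per-band energy totals with the Monte-Carlo imbalance estimate.
#' @export
trace <- function(scene, source = light_source(), optics = leaf_optics(),
                  tiles = soil_tile_grid(), max_bounces = 5,
                  rr_threshold = 1e-3, tip_dirs = 32L, margin = 0.05) {
  stopifnot(inherits(scene, "canopy_scene"), source$n_rays >= 1)
  prim <- scene_primitives(scene)
  b <- scene$bounds
  if (nrow(prim$lam) > 0) {
    rx <- abs(prim$lam[, 4]) * prim$lam[, 10] + abs(prim$lam[, 7]) * prim$lam[, 11]
    ry <- abs(prim$lam[, 5]) * prim$lam[, 10] + abs(prim$lam[, 8]) * prim$lam[, 11]
    b <- c(min(b[1], prim$lam[, 1] - rx), max(b[2], prim$lam[, 1] + rx),
           min(b[3], prim$lam[, 2] - ry), max(b[4], prim$lam[, 2] + ry))
  }
  bounds <- c(b[1] - margin, b[2] + margin, b[3] - margin, b[4] + margin)
  zmax <- if (nrow(prim$lam) > 0 || nrow(prim$pet) > 0)
    max(prim$lam[, 3], prim$pet[, c(3, 6)], 0) else 0
  z_emit <- max(zmax + 0.01, 0.05)
  model <- match(source$angular_model,
                 c("vertical", "overcast-diffuse", "uniform-hemisphere")) - 1L
  tm <- as.matrix(tiles[, c("xmin", "xmax", "ymin", "ymax")])
  inten <- band_intensities(source)
  res <- cpp_trace(prim$lam, prim$pet, unclass(optics), bounds, z_emit,
                   model, source$n_rays, source$seed, as.integer(max_bounces),
                   rr_threshold, unname(inten), tm, 0.025)

  # per-organ absorbed PAR in umol s-1 (tallies carry umol s-1 already:
  # weight = intensity * area / n_rays)
  laminas <- cbind(prim$index,
                   data.frame(absorbed_par = res$lamina_absorbed[, 1],
                              absorbed_r = res$lamina_absorbed[, 2],
                              absorbed_fr = res$lamina_absorbed[, 3]))
  pet_index <- if (nrow(prim$pet) > 0)
    data.frame(plant = prim$pet[, 8], leaf = prim$pet[, 9]) else
    data.frame(plant = integer(0), leaf = integer(0))
  petioles <- cbind(pet_index,
                    data.frame(absorbed_par = if (nrow(prim$pet)) res$petiole_absorbed[, 1] else numeric(0)))

  tile_df <- as.data.frame(tiles)
  tile_df$par <- res$tile_flux[, 1]

  # tip sensors: adjoint transmission sampling, bands R and FR
  if (nrow(prim$tips) > 0) {
    rel <- cpp_sense_tips(prim$lam, prim$pet, unclass(optics), bounds, z_emit,
                          prim$tips, as.integer(tip_dirs),
                          source$seed + 1000L, 0.025)
    r_flux <- inten["R"] * rel[, 2]
    fr_flux <- inten["FR"] * rel[, 3]
    ratio <- ifelse(fr_flux > 0, r_flux / fr_flux, Inf)
    tip_df <- data.frame(plant = prim$tips[, 4], leaf = prim$tips[, 5],
                         rel_r = rel[, 2], rel_fr = rel[, 3],
                         r_fr = ratio, n_dirs = as.integer(tip_dirs))
  } else {
    tip_df <- data.frame(plant = integer(0), leaf = integer(0),
                         rel_r = numeric(0), rel_fr = numeric(0),
                         r_fr = numeric(0), n_dirs = integer(0))
  }

  totals <- data.frame(band = BAND_NAMES, emitted = res$emitted,
                       absorbed = res$absorbed, soil_tiles = res$soil_tiles,
                       soil_other = res$soil_other, escaped = res$escaped,
                       imbalance = res$imbalance,
                       imbalance_se = res$imbalance_se)

  structure(list(laminas = laminas, petioles = petioles,
                 soil_tiles = tile_df, tips = tip_df, totals = totals,
                 source = source, n_degenerate = prim$n_degenerate,
                 bounds = bounds, z_emit = z_emit),
            class = "radiation_result")
}

#' @export
print.radiation_result <- function(x, ...) {
  cat("<radiation_result>", nrow(x$laminas), "laminas,",
      nrow(x$soil_tiles), "soil tiles; mean central soil PAR",
      signif(soil_par_summary(x), 4), "umol m-2 s-1\n")
  if (x$n_degenerate > 0)
    cat("  (", x$n_degenerate, "degenerate organ(s) skipped )\n")
  invisible(x)
}

#' Tip R:FR ratio for one leaf
#'
#' Ratio of red to far-red fluence at the lamina tip sensor; equals the
#' source ratio in an open scene and collapses under leaf layers. A tip
#' receiving zero far-red flux returns `Inf` (sentinel, never an error).
#'
#' @param result a `radiation_result`.
#' @param plant plant id.
#' @param leaf leaf rank.
#' @return dimensionless ratio.
#' @export
tip_r_fr <- function(result, plant, leaf) {
  i <- which(result$tips$plant == plant & result$tips$leaf == leaf)
  if (length(i) == 0) stop("no tip sensor for plant ", plant, " leaf ", leaf)
  result$tips$r_fr[i]
}

#' Mean soil PAR over the central tiles
#'
#' Area-weighted mean PAR across the soil-tile grid (umol m-2 s-1).
#' @param result a `radiation_result`.
#' @export
soil_par_summary <- function(result) {
  t <- result$soil_tiles
  sum(t$par * t$area) / sum(t$area)
}

#' Dump a radiation result to CSV files
#'
#' Writes `<prefix>_organs.csv` (plant, leaf, absorbed_par),
#' `<prefix>_tiles.csv` (tile, par) and `<prefix>_tips.csv`
#' (plant, leaf, r_fr).
#' @param result a `radiation_result`.
#' @param prefix path prefix.
#' @export
radiation_to_csv <- function(result, prefix) {
  write.csv(result$laminas[, c("plant", "leaf", "absorbed_par")],
            paste0(prefix, "_organs.csv"), row.names = FALSE)
  write.csv(result$soil_tiles[, c("tile", "par")],
            paste0(prefix, "_tiles.csv"), row.names = FALSE)
  write.csv(result$tips[, c("plant", "leaf", "r_fr")],
            paste0(prefix, "_tips.csv"), row.names = FALSE)
  invisible(prefix)
}
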