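# Deterministic synthetic micro-scenes with analytic expectations: the
# no-download test surface for every stage of the simulator.

inert_sas <- function() sas_params(r_fr_threshold = 0, hyponasty_rate = 0,
                                   touch_enabled = FALSE)

#' Build a named toy fixture
#'
#' Every fixture carries a scene (or a small config) plus a map of expected
#' metrics, each with a value, a tolerance and a provenance tag stating how
#' the expectation was computed (source calibration constant, closed form,
#' or brute-force oracle).
#'
#' Fixtures:
#' * `empty_scene` — no plants; soil PAR equals the source intensity (220)
#'   and any sensor would read the source R:FR (2.3).
#' * `single_leaf` — one horizontal 20 x 10 mm lamina; vertical cover over
#'   a 4 x 4 cm region equals the ellipse area over the region area.
#' * `overlapping_pair` — two plants whose laminas overlap at equal height;
#'   both leaves register touch.
#' * `two_layer_rfr` — a sensor leaf under two large horizontal laminas;
#'   the tip ratio is the closed-form two-layer transmission
#'   `r_fr * (tau_R / tau_FR)^2`.
#' * `mini_canopy_2x2` — four plants on a 3 cm grid whose leaf reach just
#'   exceeds half the spacing, so facing leaves touch.
#' * `saturating_hyponasty` — a single leaf at 30 degrees with rate 10;
#'   forced daily triggering reaches the 80 degree cap after
#'   `ceil((80 - 30) / 10) = 5` days.
#'
#' @param name fixture name (see above).
#' @return object of class `fixture_case`: `name`, `scene` (or `config`),
#'   `expected` (named list of `list(value, tolerance, provenance)`).
#' @export
make_fixture <- function(name = c("empty_scene", "single_leaf",
                                  "overlapping_pair", "two_layer_rfr",
                                  "mini_canopy_2x2",
                                  "saturating_hyponasty")) {
  if (!is.character(name) || !(name[1] %in% c(
    "empty_scene", "single_leaf", "overlapping_pair", "two_layer_rfr",
    "mini_canopy_2x2", "saturating_hyponasty")))
    stop("unknown fixture name: ", name[1])
  name <- name[1]
  sas <- inert_sas()
  fx <- switch(name,
    empty_scene = {
      list(scene = new_scene(list(), c(-0.125, 0.125, -0.125, 0.125)),
           expected = list(
             soil_par = list(value = 220, tolerance = "3 MC sigma",
                             provenance = "source calibration"),
             r_fr = list(value = 2.3, tolerance = "3 MC sigma",
                         provenance = "source calibration")))
    },
    single_leaf = {
      # lamina centered on the origin so its ellipse lies inside the region
      p <- build_rosette(sas, 0, c(-0.015, 0))
      p <- add_leaf(p, 1, petiole_length = 5, petiole_angle = 0, azimuth = 0,
                    lamina_length = 20, lamina_width = 10)
      region <- c(-0.02, 0.02, -0.02, 0.02)
      list(scene = new_scene(list(p), region),
           region = region,
           expected = list(
             cover = list(value = (pi * 20 * 10 / 4) / (40 * 40),
                          tolerance = "discretisation",
                          provenance = "analytic projection"),
             lamina_area_mm2 = list(value = pi * 20 * 10 / 4,
                                    tolerance = 1e-9,
                                    provenance = "ellipse area")))
    },
    overlapping_pair = {
      p1 <- build_rosette(sas, 0, c(-0.01, 0), id = 1)
      p1 <- add_leaf(p1, 1, 5, 0, 0, 20, 10)        # points +x
      p2 <- build_rosette(sas, 0, c(0.01, 0), id = 2)
      p2 <- add_leaf(p2, 1, 5, 0, 180, 20, 10)      # points -x, overlaps
      list(scene = new_scene(list(p1, p2)),
           expected = list(
             touched = list(value = TRUE, tolerance = 0,
                            provenance = "overlapping coplanar laminas")))
    },
    two_layer_rfr = {
      sensor <- build_rosette(sas, 0, c(0, 0), id = 1, base_z = 0.002)
      sensor <- add_leaf(sensor, 1, 5, 0, 0, 10, 5)   # tip at (15, 0) mm
      # covering layers are made very wide so that the cosine-weighted
      # upward sensing rays essentially never escape around their edges
      # (edge leakage << tau_R^2)
      mk_cover <- function(id, z) {
        p <- build_rosette(sas, 0, c(0.015 - 4.005, 0), id = id, base_z = z)
        add_leaf(p, 1, petiole_length = 5, petiole_angle = 0, azimuth = 0,
                 lamina_length = 8000, lamina_width = 8000)
      }
      op <- leaf_optics()
      tau <- op["R", "transmittance"] / op["FR", "transmittance"]
      list(scene = new_scene(list(sensor, mk_cover(2, 0.01),
                                  mk_cover(3, 0.02)),
                             c(-3, 3, -3, 3)),
           expected = list(
             tip_r_fr = list(value = 2.3 * tau^2, tolerance = "MC sigma",
                             provenance = "closed-form two-layer transmission")))
    },
    mini_canopy_2x2 = {
      spacing <- 0.03
      reach <- 15.5  # mm petiole+lamina; > half-spacing so facing leaves touch
      plants <- list()
      pos <- expand.grid(x = c(-spacing / 2, spacing / 2),
                         y = c(-spacing / 2, spacing / 2))
      for (i in 1:4) {
        p <- build_rosette(sas, 0, as.numeric(pos[i, ]), id = i)
        for (r in 1:4)
          p <- add_leaf(p, r, petiole_length = reach - 10, petiole_angle = 0,
                        azimuth = (r - 1) * 90, lamina_length = 10,
                        lamina_width = 5)
        plants[[i]] <- p
      }
      list(scene = new_scene(plants),
           expected = list(
             touched_any = list(value = TRUE, tolerance = 0,
                                provenance = "leaf reach exceeds half-spacing"),
             touch_onset_reach_mm = list(value = spacing * 1000 / 2,
                                         tolerance = "touch tolerance",
                                         provenance = "grid geometry")))
    },
    saturating_hyponasty = {
      p <- build_rosette(sas_params(hyponasty_rate = 10), 0, c(0, 0))
      p <- add_leaf(p, 1, 5, 30, 0, 10, 5)
      list(scene = new_scene(list(p)),
           sas = sas_params(hyponasty_rate = 10),
           expected = list(
             days_to_cap = list(value = ceiling((80 - 30) / 10), tolerance = 0,
                                provenance = "ceil((cap - theta0) / rate)"),
             final_angle = list(value = 80, tolerance = 0,
                                provenance = "angle cap")))
    })
  structure(c(list(name = name), fx), class = "fixture_case")
}

#' @export
print.fixture_case <- function(x, ...) {
  cat("<fixture_case>", x$name, "-", length(x$expected), "expectation(s)\n")
  invisible(x)
}

#' Brute-force vertical-ray soil map
#'
#' Independent oracle for the Monte-Carlo tracer in vertical-source mode:
#' exhaustive grid ray casting with exact ellipse intersection. Each grid
#' point reports the source PAR times the product of lamina transmittances
#' above it (petioles are opaque), which is exact for non-scattering
#' (opaque or purely transmitting) optics.
#'
#' @param scene a `canopy_scene`.
#' @param resolution grid points per axis.
#' @param par source intensity on the unobstructed plane.
#' @param optics a [leaf_optics()].
#' @param region `c(xmin, xmax, ymin, ymax)`; defaults to scene bounds.
#' @return data.frame (x, y, par).
#' @export
brute_force_light_oracle <- function(scene, resolution = 50, par = 220,
                                     optics = leaf_optics(),
                                     region = scene$bounds) {
  prim <- scene_primitives(scene)
  dx <- (region[2] - region[1]) / resolution
  dy <- (region[4] - region[3]) / resolution
  g <- expand.grid(jx = seq_len(resolution) - 1, jy = seq_len(resolution) - 1)
  xs <- region[1] + (g$jx + 0.5) * dx
  ys <- region[3] + (g$jy + 0.5) * dy
  if (nrow(prim$lam) == 0 && nrow(prim$pet) == 0)
    return(data.frame(x = xs, y = ys, par = par))
  zmax <- max(prim$lam[, 3], prim$pet[, c(3, 6)], 0) + 0.01
  m <- cpp_vertical_map(prim$lam, prim$pet, unclass(optics), region,
                        as.integer(resolution), zmax, 0.025)
  # cpp_vertical_map orders points y-major then x, matching expand.grid(jx, jy)
  data.frame(x = xs, y = ys, par = par * m$trans[, 1])
}

#' Write every fixture and its expectations as JSON
#'
#' @param path output file.
#' @return the path, invisibly.
#' @export
fixtures_to_json <- function(path) {
  names <- c("empty_scene", "single_leaf", "overlapping_pair",
             "two_layer_rfr", "mini_canopy_2x2", "saturating_hyponasty")
  out <- lapply(names, function(nm) {
    fx <- make_fixture(nm)
    list(name = fx$name, expected = fx$expected,
         n_plants = if (!is.null(fx$scene)) length(fx$scene$plants) else 0)
  })
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(js, path)
  invisible(path)
}
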