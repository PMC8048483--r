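# Daily-step orchestration of the three competition scenarios, replicate
# stands, metrics and summaries.
#
# Scenario 1: monoculture without competitors (soil-PAR time course).
# Scenario 2: + competitors with weak SAS (no hyponasty, slow elongation).
# Scenario 3: + competitors with strong SAS (16 deg/day hyponasty).

#' Scenario configuration
#'
#' Default stand: 10 x 10 canopy plants at 2.5 cm spacing (1,600 plants
#' m-2) with, for scenarios 2 and 3, 16 competitor plants interleaved
#' between the canopy plants and germinating 3 days late; 44 daily steps.
#'
#' @param scenario 1 (no competitors), 2 (weak-SAS competitors) or 3
#'   (strong-SAS competitors).
#' @param hyponasty_rate canopy hyponasty rate, degrees per day (the
#'   experimental variable; the sweep uses 1, 5, 10, 15, 20).
#' @param n_stands replicate stands per scenario/rate.
#' @param days simulated days (24 h per step).
#' @param nx,ny,spacing canopy grid.
#' @param n_competitors competitors interleaved (scenarios 2/3).
#' @param competitor_delay germination delay of competitors, days.
#' @param source a [light_source()]; its `n_rays` is the per-day ray budget
#'   per band.
#' @param optics a [leaf_optics()].
#' @param growth a [growth_params()].
#' @param tiles a [soil_tile_grid()] (default: the 100 cm2 under the middle
#'   16 canopy plants).
#' @param master_seed master seed; per-stand and per-day substreams are
#'   derived deterministically.
#' @param touch_tolerance virtual-touch distance, m.
#' @param tip_dirs sensing directions per lamina tip.
#' @param cover_resolution grid points per axis for the cover metric.
#' @param canopy_sas,competitor_sas optional [sas_params()] overriding the
#'   phenotype presets (the canopy preset at `hyponasty_rate`, and the
#'   weak/strong competitor preset implied by `scenario`).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = 1, hyponasty_rate = 5, n_stands = 10,
                            days = 44, nx = 10, ny = 10, spacing = 0.025,
                            n_competitors = 16, competitor_delay = 3,
                            source = light_source(), optics = leaf_optics(),
                            growth = growth_params(),
                            tiles = soil_tile_grid(), master_seed = 1,
                            touch_tolerance = 0.002, tip_dirs = 32L,
                            cover_resolution = 40L, canopy_sas = NULL,
                            competitor_sas = NULL) {
  stopifnot(scenario %in% 1:3, days >= 1, n_stands >= 1)
  structure(list(scenario = as.integer(scenario),
                 hyponasty_rate = hyponasty_rate,
                 n_stands = as.integer(n_stands), days = as.integer(days),
                 nx = nx, ny = ny, spacing = spacing,
                 n_competitors = n_competitors,
                 competitor_delay = competitor_delay,
                 source = source, optics = optics, growth = growth,
                 tiles = tiles, master_seed = as.integer(master_seed),
                 touch_tolerance = touch_tolerance,
                 tip_dirs = as.integer(tip_dirs),
                 cover_resolution = as.integer(cover_resolution),
                 canopy_sas = canopy_sas, competitor_sas = competitor_sas),
            class = "scenario_config")
}

stand_seed <- function(config, stand_index) {
  (config$master_seed + 7919L * as.integer(stand_index)) %% 2147483629L
}
day_seed <- function(sseed, day) (sseed + 131L * as.integer(day)) %% 2147483629L

competitor_phenotype <- function(scenario) {
  switch(scenario, NULL,
         sas_preset("weak_sas_competitor"),
         sas_preset("strong_sas_competitor"))
}

#' Initialise one vegetation stand
#'
#' Builds the layout and plants for one replicate; each plant's first-leaf
#' azimuth is drawn from the stand's seeded RNG.
#'
#' @param config a [scenario_config()].
#' @param stand_index replicate index (1-based).
#' @return a `stand_state` list.
#' @export
init_stand <- function(config, stand_index = 1) {
  layout <- uniform_grid(config$nx, config$ny, config$spacing)
  if (config$scenario > 1)
    layout <- interleave_competitors(layout, config$n_competitors)
  sseed <- stand_seed(config, stand_index)
  canopy_sas <- config$canopy_sas %||%
    sas_preset("canopy", hyponasty_rate = config$hyponasty_rate)
  comp_sas <- config$competitor_sas %||% competitor_phenotype(config$scenario)
  n_can <- nrow(layout$canopy_positions)
  n_com <- nrow(layout$competitor_positions)
  az <- withr_seed(sseed, function() runif(n_can + n_com, 0, 360))
  plants <- vector("list", n_can + n_com)
  for (i in seq_len(n_can)) {
    plants[[i]] <- build_rosette(canopy_sas, 0, layout$canopy_positions[i, ],
                                 id = i, role = "canopy", azimuth0 = az[i])
  }
  for (j in seq_len(n_com)) {
    plants[[n_can + j]] <- build_rosette(
      comp_sas, config$competitor_delay, layout$competitor_positions[j, ],
      id = n_can + j, role = "competitor", azimuth0 = az[n_can + j])
  }
  central <- central_selection(layout, min(16, n_can), min(4, n_com))
  structure(list(layout = layout, plants = plants, day = 0L,
                 stand_index = as.integer(stand_index), seed = sseed,
                 central = central, ts = list()),
            class = "stand_state")
}

# run f() under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

stand_scene <- function(stand) {
  new_scene(stand$plants, stand$layout$plot_bounds)
}

sas_lookup_for <- function(stand) {
  phen <- lapply(stand$plants, function(p) p$phenotype)
  function(id) phen[[id]]
}

#' Advance a stand by one day
#'
#' Executes the fixed daily order: leaf initiation, radiation trace, signal
#' evaluation, hyponasty and elongation responses, assimilation, carbon
#' allocation, organ growth, then metric recording. Deterministic given the
#' stand seed.
#'
#' @param stand a `stand_state`.
#' @param day stand day in `[0, days)`; must equal `stand$day`.
#' @param config a [scenario_config()].
#' @return the advanced `stand_state`.
#' @export
step_day <- function(stand, day, config) {
  if (day != stand$day)
    stop("step_day: expected day ", stand$day, " (got ", day, ")")
  # 1. leaf initiation (+ release of the seed carbon reserve at germination)
  stand$plants <- lapply(stand$plants, function(p) {
    if (day == p$germination_day)
      p$carbon_pool <- p$carbon_pool + config$growth$seed_carbon
    initiate_leaves(p, stand_day = day, params = config$growth)
  })
  scene <- stand_scene(stand)
  n_leaves <- sum(vapply(stand$plants, function(p) nrow(p$leaves), 0L))

  # 2. radiation
  src <- config$source
  src$seed <- day_seed(stand$seed, day)
  rad <- tryCatch(
    trace(scene, src, config$optics, config$tiles,
          tip_dirs = config$tip_dirs),
    error = function(e) stop("day ", day, ": ", conditionMessage(e)))

  assim_total <- 0
  if (n_leaves > 0) {
    # 3. signals
    sig <- evaluate_signals(scene, rad, sas_lookup_for(stand),
                            tolerance = config$touch_tolerance)
    sig_key <- paste(sig$plant, sig$leaf)
    abs_by_organ <- rbind(
      data.frame(plant = rad$laminas$plant, leaf = rad$laminas$leaf,
                 par = rad$laminas$absorbed_par),
      data.frame(plant = rad$petioles$plant, leaf = rad$petioles$leaf,
                 par = rad$petioles$absorbed_par))

    for (i in seq_along(stand$plants)) {
      p <- stand$plants[[i]]
      if (nrow(p$leaves) == 0) next
      key <- paste(p$id, p$leaves$rank)
      trig <- sig$triggered[match(key, sig_key)]
      trig[is.na(trig)] <- FALSE
      # 4. responses
      p$leaves$petiole_angle <- update_hyponasty(p$leaves$petiole_angle,
                                                 trig, p$phenotype)
      ef <- elongation_signal(trig, p$phenotype)
      # 5. assimilation
      par_organs <- abs_by_organ$par[abs_by_organ$plant == p$id]
      carbon <- daily_assimilation(p, par_organs, config$growth)
      assim_total <- assim_total + carbon
      # 6. allocation (pool + today's assimilate); triggered leaves pull
      # extra carbon into their petiole sinks
      boost <- petiole_sink_boost(trig, p$phenotype, config$growth)
      al <- allocate_carbon(p, p$carbon_pool + carbon, config$growth, boost)
      # 7. growth
      p <- grow_organs(p, al$increments, config$growth, ef)
      p$carbon_pool <- al$pool
      p$leaves$age_days <- p$leaves$age_days + 1
      stand$plants[[i]] <- p
    }
  }

  # 8. metrics
  scene2 <- stand_scene(stand)
  bio <- vapply(stand$plants, plant_biomass, 0)
  roles <- vapply(stand$plants, function(p) p$role, "")
  can_idx <- which(roles == "canopy")[stand$central$canopy]
  com_idx <- which(roles == "competitor")[stand$central$competitor]
  central_area <- length(stand$central$canopy) * config$spacing^2
  inner <- stand$layout$plot_bounds +
    c(config$spacing, -config$spacing, config$spacing, -config$spacing)
  cover <- if (sum(vapply(stand$plants, function(p) nrow(p$leaves), 0L)) > 0)
    vertical_cover_fraction(scene2, inner, config$cover_resolution) else 0
  stand$ts[[length(stand$ts) + 1]] <- data.frame(
    stand = stand$stand_index, day = day,
    soil_par = soil_par_summary(rad),
    canopy_biomass_gm2 = sum(bio[can_idx]) / 1000 / central_area,
    competitor_biomass_g = if (length(com_idx)) mean(bio[com_idx]) / 1000 else 0,
    lai = leaf_area_index(scene2, stand$layout$plot_bounds),
    cover = cover,
    total_biomass_mg = sum(bio),
    assimilation_mg = assim_total,
    seed_release_mg = sum(vapply(stand$plants, function(p)
      if (p$germination_day == day) config$growth$seed_carbon else 0, 0)))
  stand$day <- stand$day + 1L
  stand
}

#' Run one replicate stand
#'
#' @param config a [scenario_config()].
#' @param stand_index replicate index.
#' @return list with the daily `ts` data.frame (one row per day) and the
#'   final `stand_state`.
#' @export
run_stand <- function(config, stand_index = 1) {
  stand <- init_stand(config, stand_index)
  for (d in seq_len(config$days) - 1L) stand <- step_day(stand, d, config)
  list(ts = do.call(rbind, stand$ts), stand = stand)
}

#' Final metrics of one stand
#'
#' Day-final canopy biomass in g/m2 over the central-16 footprint, the mean
#' competitor biomass in g over the central 4 competitors, final LAI and
#' cover.
#'
#' @param ts daily time-series data.frame from [run_stand()].
#' @param layout the stand's `scene_layout` (unused beyond validation; the
#'   series already carries central-selection metrics).
#' @return one-row data.frame.
#' @export
summarize_stand <- function(ts, layout = NULL) {
  last <- ts[nrow(ts), ]
  data.frame(stand = last$stand, final_day = last$day,
             canopy_biomass_gm2 = last$canopy_biomass_gm2,
             competitor_biomass_g = last$competitor_biomass_g,
             lai = last$lai, cover = last$cover,
             soil_par_final = last$soil_par)
}

#' Run a scenario across replicate stands
#'
#' Runs `n_stands` independently seeded stands and summarises the final
#' canopy and competitor biomass (mean and SD across stands) plus the mean
#' soil-PAR time series.
#'
#' @param config a [scenario_config()].
#' @return object of class `scenario_result`: `stands` (list of per-stand
#'   ts), `ts` (stacked tidy series), `finals` (per-stand final metrics)
#'   and `summary`.
#' @export
run_scenario <- function(config) {
  runs <- lapply(seq_len(config$n_stands),
                 function(i) run_stand(config, i))
  tss <- lapply(runs, `[[`, "ts")
  finals <- do.call(rbind, lapply(tss, summarize_stand))
  ts_all <- do.call(rbind, tss)
  soil_by_day <- stats::aggregate(soil_par ~ day, ts_all, mean)
  summary <- data.frame(
    scenario = config$scenario, hyponasty_rate = config$hyponasty_rate,
    n_stands = config$n_stands,
    canopy_biomass_gm2_mean = mean(finals$canopy_biomass_gm2),
    canopy_biomass_gm2_sd = stats::sd(finals$canopy_biomass_gm2),
    competitor_biomass_g_mean = mean(finals$competitor_biomass_g),
    competitor_biomass_g_sd = stats::sd(finals$competitor_biomass_g),
    soil_par_final_mean = mean(finals$soil_par_final))
  structure(list(config = config, stands = tss, ts = ts_all,
                 finals = finals, summary = summary,
                 soil_par_by_day = soil_by_day),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> scenario", x$summary$scenario, "rate",
      x$summary$hyponasty_rate, "deg/day,", x$summary$n_stands, "stand(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sweep the canopy hyponasty rate
#'
#' One scenario run per rate (default 1, 5, 10, 15, 20 degrees/day) with
#' shared per-stand seed offsets, emitting the soil-PAR curves and the
#' final competitor/canopy biomass table.
#'
#' @param config a [scenario_config()].
#' @param rates hyponasty rates to sweep, degrees/day.
#' @return object of class `sweep_result`: `results` (per rate), `table`
#'   (one summary row per rate) and `soil_par` (tidy rate x day means).
#' @export
sweep_hyponasty <- function(config, rates = c(1, 5, 10, 15, 20)) {
  stopifnot(length(rates) >= 1)
  results <- lapply(rates, function(r) {
    cfg <- config
    cfg$hyponasty_rate <- r
    run_scenario(cfg)
  })
  names(results) <- as.character(rates)
  table <- do.call(rbind, lapply(results, `[[`, "summary"))
  soil <- do.call(rbind, lapply(seq_along(rates), function(i) {
    s <- results[[i]]$soil_par_by_day
    s$hyponasty_rate <- rates[i]
    s
  }))
  structure(list(results = results, table = table, soil_par = soil,
                 rates = rates),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> hyponasty rates:", paste(x$rates, collapse = ", "),
      "deg/day\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with unadjusted pairwise LSD letters
#'
#' Reporting plumbing for simulation outputs: groups sharing a letter are
#' not significantly different by Fisher's least-significant-difference
#' test at the given alpha (pairwise t on the ANOVA mean square error,
#' unadjusted).
#'
#' @param values numeric response.
#' @param groups factor-like group labels.
#' @param alpha significance level (default 0.05).
#' @return data.frame (group, mean, letters).
#' @export
lsd_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  fit <- aov(values ~ groups)
  mse <- sum(fit$residuals^2) / fit$df.residual
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  g <- names(sort(means, decreasing = TRUE))
  k <- length(g)
  different <- function(a, b) {
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tval <- abs(means[[a]] - means[[b]]) / se
    2 * stats::pt(tval, fit$df.residual, lower.tail = FALSE) < alpha
  }
  letters_of <- rep("", k); names(letters_of) <- g
  next_letter <- 1
  for (i in seq_len(k)) {
    if (nzchar(letters_of[g[i]])) next
    lab <- letters[next_letter]; next_letter <- next_letter + 1
    letters_of[g[i]] <- paste0(letters_of[g[i]], lab)
    for (j in seq_len(k)[-seq_len(i)]) {
      if (!different(g[i], g[j]))
        letters_of[g[j]] <- paste0(letters_of[g[j]], lab)
    }
  }
  data.frame(group = names(means), mean = as.numeric(means),
             letters = letters_of[names(means)], row.names = NULL)
}
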