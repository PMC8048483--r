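# Daily photosynthesis, carbon allocation and organ growth: absorbed PAR
# becomes biomass, biomass becomes architecture.

#' Growth parameters
#'
#' Light-use-efficiency photosynthesis with sink-regulated allocation. The
#' quantitative forms are deliberately simple stand-ins for an empirically
#' fitted rosette growth model: a linear LUE preserves the light-to-biomass
#' causality under study, and a symmetric beta-shaped sink curve over a
#' fixed expansion window is standard functional-structural practice.
#' Defaults are jointly calibrated so that the default monoculture closes
#' its canopy within roughly 30 days.
#'
#' @param photoperiod_h hours of light per day (short-day chamber: 9).
#' @param lue light-use efficiency, mg biomass per mol absorbed PAR.
#' @param plastochron_days days between successive leaf initiations.
#' @param sink_duration_days organ expansion window, days.
#' @param lamina_potential,petiole_potential potential final organ mass, mg,
#'   for mature-rank leaves; early ranks are scaled down by `rank_ramp`.
#' @param rank_ramp function(rank) in (0, 1\]: size ramp of juvenile leaves.
#' @param sla specific lamina area, mm2 per mg.
#' @param petiole_density petiole mass per length at reference thickness,
#'   mg per mm.
#' @param max_leaf_count leaves per plant cap.
#' @param shade_petiole_boost scale of the shade-induced reallocation of
#'   carbon towards petiole sinks (see [petiole_sink_boost()]).
#' @param initial_angle petiole elevation of a newly initiated leaf, deg.
#' @param seed_carbon germination carbon reserve, mg.
#' @param seed_lamina_length,seed_lamina_width,seed_petiole_length geometric
#'   germ size of a new leaf, mm (not counted as biomass).
#' @param beta_shape shape parameter of the symmetric beta sink curve.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(photoperiod_h = 9, lue = 1800,
                          plastochron_days = 1.5, sink_duration_days = 12,
                          lamina_potential = 10, petiole_potential = 8,
                          rank_ramp = function(rank) pmin(1, rank / 4),
                          sla = 25, petiole_density = 0.2,
                          max_leaf_count = 25L, shade_petiole_boost = 4,
                          initial_angle = 30,
                          seed_carbon = 0.4, seed_lamina_length = 2,
                          seed_lamina_width = 1, seed_petiole_length = 1.5,
                          beta_shape = 3) {
  stopifnot(photoperiod_h > 0, lue > 0, plastochron_days > 0,
            sink_duration_days > 0, sla > 0, petiole_density > 0,
            max_leaf_count >= 1, initial_angle >= 0, initial_angle <= 90)
  structure(list(photoperiod_h = photoperiod_h, lue = lue,
                 plastochron_days = plastochron_days,
                 sink_duration_days = sink_duration_days,
                 lamina_potential = lamina_potential,
                 petiole_potential = petiole_potential,
                 rank_ramp = rank_ramp, sla = sla,
                 petiole_density = petiole_density,
                 max_leaf_count = as.integer(max_leaf_count),
                 shade_petiole_boost = shade_petiole_boost,
                 initial_angle = initial_angle, seed_carbon = seed_carbon,
                 seed_lamina_length = seed_lamina_length,
                 seed_lamina_width = seed_lamina_width,
                 seed_petiole_length = seed_petiole_length,
                 beta_shape = beta_shape),
            class = "growth_params")
}

#' Daily carbon assimilation (mg)
#'
#' Linear light-use efficiency: carbon = lue x total absorbed PAR
#' integrated over the photoperiod. 1 umol s-1 absorbed over a 9 h
#' photoperiod is 0.0324 mol.
#'
#' @param plant a `plant_state` (used only for its identity; assimilation
#'   is driven by the absorbed flux).
#' @param absorbed_par numeric vector of per-organ absorbed PAR, umol s-1.
#' @param params a [growth_params()].
#' @return carbon gain in mg.
#' @export
daily_assimilation <- function(plant, absorbed_par, params) {
  stopifnot(all(absorbed_par >= 0))
  mol <- sum(absorbed_par) * 1e-6 * 3600 * params$photoperiod_h
  params$lue * mol
}

# Daily potential demand (mg) of each leaf: potential final mass times the
# increment of the symmetric beta CDF over the day's age interval.
# petiole_boost (>= 1) raises the petiole sink of shade-triggered leaves:
# the shade-avoidance reallocation of resources towards elongation.
sink_demand <- function(leaves, params, petiole_boost = 1) {
  if (nrow(leaves) == 0)
    return(data.frame(lamina = numeric(0), petiole = numeric(0)))
  dur <- params$sink_duration_days
  a0 <- pmin(leaves$age_days / dur, 1)
  a1 <- pmin((leaves$age_days + 1) / dur, 1)
  frac <- pbeta(a1, params$beta_shape, params$beta_shape) -
          pbeta(a0, params$beta_shape, params$beta_shape)
  ramp <- params$rank_ramp(leaves$rank)
  data.frame(lamina = params$lamina_potential * ramp * frac,
             petiole = params$petiole_potential * ramp * frac *
               rep_len(petiole_boost, nrow(leaves)))
}

#' Allocate carbon to organs by sink demand
#'
#' Increments are proportional to each organ's current potential demand;
#' their sum never exceeds the supplied carbon and any surplus beyond total
#' demand stays in the carbon pool. Organs past their expansion window have
#' zero demand. Conservation is exact: increments + pool change = carbon.
#'
#' @param plant a `plant_state`.
#' @param carbon carbon to distribute, mg (>= 0). Typically the day's
#'   assimilation plus the current carbon pool.
#' @param params a [growth_params()].
#' @param petiole_boost per-leaf petiole sink multiplier (>= 1), from
#'   [petiole_sink_boost()]: shade-triggered leaves reroute carbon towards
#'   petiole elongation at the expense of lamina growth.
#' @return list with data.frame `increments` (lamina, petiole per leaf) and
#'   `pool` (the carbon left unallocated).
#' @export
allocate_carbon <- function(plant, carbon, params, petiole_boost = 1) {
  stopifnot(carbon >= 0)
  dem <- sink_demand(plant$leaves, params, petiole_boost)
  total <- sum(dem$lamina) + sum(dem$petiole)
  if (total <= 0 || nrow(dem) == 0) {
    return(list(increments = data.frame(lamina = dem$lamina * 0,
                                        petiole = dem$petiole * 0),
                pool = carbon))
  }
  f <- min(1, carbon / total)
  inc <- data.frame(lamina = dem$lamina * f, petiole = dem$petiole * f)
  # pool clamped at zero: f < 1 spends everything up to fp rounding
  list(increments = inc,
       pool = max(0, carbon - sum(inc$lamina) - sum(inc$petiole)))
}

#' Grow organs from allocated carbon
#'
#' Lamina area grows by `sla` x lamina increment (dimensions follow the
#' 2:1 length:width ellipse); petiole length grows by the mass increment
#' divided by `petiole_density`, multiplied by the shade-avoidance
#' elongation factor for that leaf on triggered days. Biomass bookkeeping
#' is exact; the elongation factor changes geometry only.
#'
#' @param plant a `plant_state`.
#' @param increments data.frame from [allocate_carbon()].
#' @param params a [growth_params()].
#' @param elongation_factor numeric vector (one per leaf) of petiole
#'   elongation multipliers, from [elongation_signal()]; default 1.
#' @return the updated `plant_state` (carbon pool untouched).
#' @export
grow_organs <- function(plant, increments, params, elongation_factor = 1) {
  lv <- plant$leaves
  if (nrow(lv) == 0) return(plant)
  stopifnot(nrow(increments) == nrow(lv))
  ef <- rep_len(elongation_factor, nrow(lv))
  lv$lamina_biomass <- lv$lamina_biomass + increments$lamina
  lv$petiole_biomass <- lv$petiole_biomass + increments$petiole
  area <- params$sla * lv$lamina_biomass          # mm2
  len <- sqrt(8 * area / pi)                      # 2:1 ellipse
  lv$lamina_length <- pmax(lv$lamina_length, len)
  lv$lamina_width <- lv$lamina_length / 2
  lv$petiole_length <- lv$petiole_length +
    (increments$petiole / params$petiole_density) * ef
  plant$leaves <- lv
  plant
}

#' Shade-induced petiole sink boost
#'
#' On triggered days a leaf reroutes carbon towards petiole elongation —
#' the classic shade-avoidance investment at the expense of other organs.
#' The petiole sink of a triggered leaf is multiplied by
#' `1 + shade_petiole_boost * elongation_multiplier`, so phenotypes with a
#' weak elongation response also reallocate less.
#'
#' @param triggered logical vector (per leaf).
#' @param sas the plant's [sas_params()].
#' @param params a [growth_params()].
#' @return numeric vector of petiole demand multipliers (>= 1).
#' @export
petiole_sink_boost <- function(triggered, sas, params) {
  ifelse(triggered,
         1 + params$shade_petiole_boost * sas$elongation_multiplier, 1)
}

#' Initiate new leaves by the plastochron clock
#'
#' A plant has `floor(age / plastochron)` leaves (capped at
#' `max_leaf_count`), where age is days since its germination day; plants
#' carry no leaves before germination. New leaves start at the geometric
#' seed dimensions, zero biomass and the initial elevation angle, with
#' azimuths following the 137.5 degree golden-angle phyllotaxis from the
#' plant's first-leaf azimuth.
#'
#' @param plant a `plant_state`.
#' @param stand_day current day on the stand clock.
#' @param params a [growth_params()].
#' @return the updated `plant_state`.
#' @export
initiate_leaves <- function(plant, stand_day, params) {
  age <- stand_day - plant$germination_day
  if (age < 0) return(plant)
  target <- min(floor(age / params$plastochron_days), params$max_leaf_count)
  have <- nrow(plant$leaves)
  if (target <= have) return(plant)
  for (r in (have + 1):target) {
    plant <- add_leaf(plant, rank = r,
                      petiole_length = params$seed_petiole_length,
                      petiole_angle = min(params$initial_angle,
                                          plant$phenotype$max_angle),
                      azimuth = (plant$azimuth0 + (r - 1) * 137.508) %% 360,
                      lamina_length = params$seed_lamina_length,
                      lamina_width = params$seed_lamina_width)
  }
  plant
}
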