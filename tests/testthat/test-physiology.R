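# Photosynthesis, carbon allocation and organ growth.

test_that("daily assimilation is linear in absorbed PAR with the stated
           photoperiod integration", {
  g <- growth_params(photoperiod_h = 9, lue = 1000)
  p <- build_rosette(sas_params(), 0, c(0, 0))
  expect_equal(daily_assimilation(p, numeric(0), g), 0)
  expect_equal(daily_assimilation(p, c(0, 0), g), 0)
  # 1 umol s-1 over 9 h = 0.0324 mol
  expect_equal(daily_assimilation(p, 1, g), 1000 * 0.0324)
  expect_equal(daily_assimilation(p, c(1, 2), g),
               2 * daily_assimilation(p, c(0.5, 1), g))
  expect_error(daily_assimilation(p, -1, g))
})

test_that("allocation splits carbon by sink demand and conserves it", {
  g <- growth_params(rank_ramp = function(r) r,  # demand proportional to rank
                     sink_duration_days = 10)
  p <- build_rosette(sas_params(), 0, c(0, 0))
  p <- add_leaf(p, 1, 2, 30, 0, 2, 1, age_days = 3)
  p <- add_leaf(p, 2, 2, 30, 0, 2, 1, age_days = 3)
  al <- allocate_carbon(p, 0.3, g)        # supply below total demand
  inc <- al$increments
  expect_equal(inc$lamina[2] / inc$lamina[1], 2)       # 2:1 by rank ramp
  expect_equal(inc$petiole[2] / inc$petiole[1], 2)
  expect_equal(sum(inc$lamina) + sum(inc$petiole) + al$pool, 0.3,
               tolerance = 1e-12)
  # single growing organ receives everything
  q <- build_rosette(sas_params(), 0, c(0, 0))
  q <- add_leaf(q, 1, 2, 30, 0, 2, 1, age_days = 3)
  alq <- allocate_carbon(q, 0.2, g)
  expect_equal(sum(alq$increments$lamina) + sum(alq$increments$petiole) +
                 alq$pool, 0.2, tolerance = 1e-12)
  expect_lt(alq$pool, 0.2)
})

test_that("organs past their expansion window stop drawing carbon", {
  g <- growth_params(sink_duration_days = 5)
  p <- build_rosette(sas_params(), 0, c(0, 0))
  p <- add_leaf(p, 1, 2, 30, 0, 2, 1, age_days = 8)   # past the window
  al <- allocate_carbon(p, 1, g)
  expect_equal(sum(al$increments$lamina) + sum(al$increments$petiole), 0)
  expect_equal(al$pool, 1)
  expect_error(allocate_carbon(p, -0.1, g))
})

test_that("shade-triggered leaves pull extra carbon into their petiole", {
  g <- growth_params()
  p <- build_rosette(sas_params(), 0, c(0, 0))
  p <- add_leaf(p, 4, 2, 30, 0, 2, 1, age_days = 3)
  p <- add_leaf(p, 5, 2, 30, 120, 2, 1, age_days = 3)
  boost <- petiole_sink_boost(c(FALSE, TRUE), sas_params(), g)
  expect_equal(boost[1], 1)
  expect_gt(boost[2], 1)
  al <- allocate_carbon(p, 0.5, g, petiole_boost = boost)
  expect_gt(al$increments$petiole[2], al$increments$petiole[1])
  expect_equal(sum(al$increments$lamina) + sum(al$increments$petiole) +
                 al$pool, 0.5, tolerance = 1e-12)
})

test_that("grow_organs converts increments into geometry exactly", {
  g <- growth_params(sla = 25, petiole_density = 0.2)
  p <- build_rosette(sas_params(), 0, c(0, 0))
  p <- add_leaf(p, 1, 2, 30, 0, 2, 1)
  inc <- data.frame(lamina = 0.8, petiole = 0.4)
  p1 <- grow_organs(p, inc, g)
  expect_equal(p1$leaves$lamina_biomass, 0.8)
  expect_equal(p1$leaves$petiole_biomass, 0.4)
  area <- pi * p1$leaves$lamina_length * p1$leaves$lamina_width / 4
  expect_equal(area, 25 * 0.8, tolerance = 1e-9)       # sla x increment
  expect_equal(p1$leaves$petiole_length, 2 + 0.4 / 0.2)
  # zero increment leaves geometry untouched
  p0 <- grow_organs(p, data.frame(lamina = 0, petiole = 0), g)
  expect_equal(p0$leaves, p$leaves)
})

test_that("the elongation factor changes length, never mass", {
  g <- growth_params(petiole_density = 0.2)
  p <- build_rosette(sas_params(), 0, c(0, 0))
  p <- add_leaf(p, 1, 2, 30, 0, 2, 1)
  inc <- data.frame(lamina = 0, petiole = 0.4)
  plain <- grow_organs(p, inc, g, elongation_factor = 1)
  fast <- grow_organs(p, inc, g, elongation_factor = 1.5)
  expect_equal(fast$leaves$petiole_biomass, plain$leaves$petiole_biomass)
  expect_equal(fast$leaves$petiole_length - 2, 1.5 * (plain$leaves$petiole_length - 2))
})

test_that("leaves appear on the plastochron clock and never disappear", {
  g <- growth_params(plastochron_days = 2, max_leaf_count = 6)
  p <- build_rosette(sas_params(), 0, c(0, 0))
  p10 <- initiate_leaves(p, 10, g)
  expect_equal(nrow(p10$leaves), 5)          # floor(10 / 2)
  counts <- integer(0)
  q <- p
  for (d in 0:20) {
    q <- initiate_leaves(q, d, g)
    counts <- c(counts, nrow(q$leaves))
  }
  expect_true(all(diff(counts) >= 0))
  expect_equal(max(counts), 6)               # cap
  expect_true(all(diff(q$leaves$rank) > 0))
})

test_that("whole-stand mass balance holds exactly day by day", {
  cfg <- tiny_config(scenario = 2, days = 6)
  ts <- run_stand(cfg, 1)$ts
  gain <- diff(c(0, ts$total_biomass_mg))
  expect_equal(gain, ts$assimilation_mg + ts$seed_release_mg,
               tolerance = 1e-9)
  # biomass never decreases
  expect_true(all(diff(ts$total_biomass_mg) >= -1e-12))
})

test_that("a far-away plant leaves an isolated plant's light unchanged", {
  # light capture (hence growth) is invariant, in expectation, to plants
  # farther away than the plot diameter; ray density is matched because the
  # emission domain grows with the scene
  sc1 <- one_leaf_scene(petiole = 5, L = 20, W = 10, half = 0.05)
  far <- build_rosette(inert_phenotype(), 0, c(0.4, 0.4), id = 2)
  far <- add_leaf(far, 1, 5, 20, 10, 25, 12)
  sc2 <- new_scene(c(sc1$plants, list(far)), c(-0.05, 0.45, -0.05, 0.45))
  a1 <- trace(sc1, light_source(n_rays = 40000, seed = 8))
  area_ratio <- (0.6 / 0.2)^2            # emission bounds incl. margins
  a2 <- trace(sc2, light_source(n_rays = round(40000 * area_ratio), seed = 9))
  abs1 <- a1$laminas$absorbed_par[a1$laminas$plant == 1]
  abs2 <- a2$laminas$absorbed_par[a2$laminas$plant == 1]
  expect_equal(abs2, abs1, tolerance = 0.1)
})
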