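# Monte-Carlo two-band + PAR transport: calibration, occlusion,
# conservation, sensing, and the brute-force oracle cross-checks.

test_that("an empty scene returns the source intensity on every tile", {
  for (model in c("overcast-diffuse", "vertical")) {
    r <- trace(new_scene(list()),
               light_source(n_rays = 60000, seed = 11, angular_model = model))
    tiles <- r$soil_tiles$par
    se <- sd(tiles) / sqrt(length(tiles))
    expect_lt(abs(soil_par_summary(r) - 220), 3 * se + 0.5)
    expect_equal(nrow(r$tips), 0)
  }
})

test_that("a fully absorbing lamina blacks out its tile and spares others", {
  p <- build_rosette(inert_phenotype(), 0, c(0.02, 0))
  p <- add_leaf(p, 1, 0, 0, 180, 40, 40)   # disc of radius 20mm centered at 0
  sc <- new_scene(list(p), c(-0.125, 0.125, -0.125, 0.125))
  r <- trace(sc, light_source(n_rays = 80000, seed = 3,
                              angular_model = "vertical"),
             optics = opaque_optics())
  tiles <- r$soil_tiles
  center <- which(tiles$xmin < 0 & tiles$xmax > 0 & tiles$ymin < 0 &
                    tiles$ymax > 0)
  expect_lt(tiles$par[center], 1)
  # outer-ring tiles sit clear of the 20 mm disc: unshaded at the source
  # intensity (averaged to tame per-tile Monte-Carlo noise)
  cx <- (tiles$xmin + tiles$xmax) / 2
  cy <- (tiles$ymin + tiles$ymax) / 2
  ring <- pmax(abs(cx), abs(cy)) > 0.035
  expect_equal(mean(tiles$par[ring]), 220, tolerance = 0.02)
})

test_that("per-band energy is conserved within Monte-Carlo error", {
  for (seed in 1:3) {
    sc <- random_scene(seed)
    r <- trace(sc, light_source(n_rays = 20000, seed = seed + 50))
    with(r$totals, {
      expect_true(all(abs(emitted - (absorbed + soil_tiles + soil_other +
                                       escaped + imbalance)) <
                        1e-9 * emitted))
      expect_true(all(abs(imbalance) <= 3 * imbalance_se + 1e-9 * emitted))
    })
  }
})

test_that("Monte-Carlo error scales like 1/sqrt(n_rays)", {
  sc <- one_leaf_scene()
  soil_at <- function(n, seed)
    soil_par_summary(trace(sc, light_source(n_rays = n, seed = seed),
                           tiles = soil_tile_grid(c(-0.02, 0.02, -0.02, 0.02),
                                                  2)))
  lo <- vapply(1:12, function(s) soil_at(2000, s), 0)
  hi <- vapply(1:12, function(s) soil_at(32000, s + 100), 0)
  ratio <- sd(lo) / sd(hi)   # expect ~ sqrt(16) = 4
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 9)
})

test_that("R and FR are transported independently", {
  sc <- random_scene(2)
  src <- light_source(n_rays = 10000, seed = 9)
  a <- trace(sc, src, optics = leaf_optics())
  b <- trace(sc, src, optics = leaf_optics(fr = c(0.8, 0.1, 0.1)))
  # changing far-red optics must not move a single red or PAR tally
  expect_identical(a$totals[1:2, -1], b$totals[1:2, -1])
  expect_identical(a$soil_tiles$par, b$soil_tiles$par)
  expect_false(identical(a$totals[3, ], b$totals[3, ]))
})

test_that("adding an opaque lamina cannot brighten the soil", {
  sc1 <- random_scene(4)
  extra <- build_rosette(inert_phenotype(), 0, c(0.01, 0.01), id = 99)
  extra <- add_leaf(extra, 1, 5, 10, 45, 25, 12)
  sc2 <- new_scene(c(sc1$plants, list(extra)), sc1$bounds)
  src <- light_source(n_rays = 30000, seed = 21, angular_model = "vertical")
  s1 <- soil_par_summary(trace(sc1, src, optics = opaque_optics()))
  s2 <- soil_par_summary(trace(sc2, src, optics = opaque_optics()))
  expect_lte(s2, s1 + 1e-9)
})

test_that("tip sensors read the source R:FR in the open", {
  sc <- one_leaf_scene()
  r <- trace(sc, light_source(n_rays = 2000, seed = 2), tip_dirs = 64)
  expect_equal(tip_r_fr(r, 1, 1), 2.3, tolerance = 1e-12)
  expect_error(tip_r_fr(r, 9, 9))
})

test_that("one leaf layer depresses tip R:FR by the transmission ratio", {
  sensor <- build_rosette(inert_phenotype(), 0, c(0, 0), base_z = 0.002)
  sensor <- add_leaf(sensor, 1, 5, 0, 0, 10, 5)
  cover <- build_rosette(inert_phenotype(), 0, c(0.015 - 4.005, 0), id = 2,
                         base_z = 0.02)
  cover <- add_leaf(cover, 1, 5, 0, 0, 8000, 8000)
  sc <- new_scene(list(sensor, cover), c(-3, 3, -3, 3))
  op <- leaf_optics()
  r <- trace(sc, light_source(n_rays = 2000, seed = 5), optics = op,
             tip_dirs = 512)
  expected <- 2.3 * op["R", "transmittance"] / op["FR", "transmittance"]
  expect_equal(tip_r_fr(r, 1, 1), expected, tolerance = 0.05)
  expect_lt(tip_r_fr(r, 1, 1), 2.3)
  # identical band optics leave the ratio at the source value everywhere
  sym <- leaf_optics(r = c(0.5, 0.25, 0.25), fr = c(0.5, 0.25, 0.25))
  r2 <- trace(sc, light_source(n_rays = 2000, seed = 5), optics = sym,
              tip_dirs = 256)
  expect_equal(tip_r_fr(r2, 1, 1), 2.3, tolerance = 1e-9)
})

test_that("zero far-red flux yields the +Inf sentinel, not a crash", {
  sensor <- build_rosette(inert_phenotype(), 0, c(0, 0), base_z = 0.002)
  sensor <- add_leaf(sensor, 1, 5, 0, 0, 10, 5)
  cover <- build_rosette(inert_phenotype(), 0, c(0.015 - 4.005, 0), id = 2,
                         base_z = 0.02)
  cover <- add_leaf(cover, 1, 5, 0, 0, 8000, 8000)
  sc <- new_scene(list(sensor, cover), c(-3, 3, -3, 3))
  blocked_fr <- leaf_optics(fr = c(1, 0, 0))   # far-red fully absorbed
  r <- trace(sc, light_source(n_rays = 1000, seed = 6), optics = blocked_fr,
             tip_dirs = 64)
  expect_identical(tip_r_fr(r, 1, 1), Inf)
})

test_that("soil PAR summary is the area-weighted tile mean", {
  r <- trace(new_scene(list()), light_source(n_rays = 20000, seed = 31))
  m <- soil_par_summary(r)
  expect_gte(m, min(r$soil_tiles$par))
  expect_lte(m, max(r$soil_tiles$par))
  r$soil_tiles$par <- rep(7, nrow(r$soil_tiles))
  expect_equal(soil_par_summary(r), 7)
})

test_that("optical coefficients are validated", {
  expect_error(leaf_optics(par = c(0.5, 0.1, 0.1)))
  expect_error(leaf_optics(par = c(1.2, -0.1, -0.1)))
  op <- leaf_optics()
  expect_equal(rowSums(unclass(op)), c(PAR = 1, R = 1, FR = 1))
})

test_that("degenerate organs are skipped and counted", {
  p <- build_rosette(inert_phenotype(), 0, c(0, 0))
  p <- add_leaf(p, 1, 5, 0, 0, 20, 10)
  p$leaves <- rbind(p$leaves, within(p$leaves[1, ], {
    rank <- 2; lamina_length <- 0
  }))
  r <- trace(new_scene(list(p)), light_source(n_rays = 2000, seed = 1))
  expect_equal(r$n_degenerate, 1)
  expect_equal(nrow(r$laminas), 1)
})

test_that("radiation results dump to CSV", {
  sc <- one_leaf_scene()
  r <- trace(sc, light_source(n_rays = 2000, seed = 2))
  prefix <- tempfile()
  radiation_to_csv(r, prefix)
  organs <- read.csv(paste0(prefix, "_organs.csv"))
  expect_equal(nrow(organs), 1)
  expect_true(file.exists(paste0(prefix, "_tiles.csv")))
  expect_true(file.exists(paste0(prefix, "_tips.csv")))
})
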