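# Rosette and stand geometry: organ shapes, layouts, projections.

test_that("build_rosette starts empty, deterministic, with valid fields", {
  ph <- sas_params()
  p1 <- build_rosette(ph, 0, c(0, 0))
  expect_s3_class(p1, "plant_state")
  expect_equal(nrow(p1$leaves), 0)
  expect_equal(plant_biomass(p1), 0)
  p2 <- build_rosette(ph, 0, c(0, 0))
  expect_identical(p1, p2)
  expect_error(build_rosette(ph, -1, c(0, 0)))
})

test_that("plants produce no leaves before their germination day", {
  g <- growth_params(plastochron_days = 2)
  p <- build_rosette(sas_params(), 3, c(0, 0))
  for (d in 0:2) {
    p <- initiate_leaves(p, d, g)
    expect_equal(nrow(p$leaves), 0)
  }
  p <- initiate_leaves(p, 9, g)   # age 6, plastochron 2
  expect_equal(nrow(p$leaves), 3)
})

test_that("lamina mesh area converges to the ellipse area pi*L*W/4", {
  leaf <- list(petiole_length = 5, petiole_angle = 0, azimuth = 0,
               lamina_length = 20, lamina_width = 10)
  target <- pi * 20 * 10 / 4               # 157.0796 mm2
  for (k in c(8, 32, 512)) {
    mesh <- lamina_mesh(leaf, k)
    a_mm2 <- polygon_area3d(mesh) * 1e6
    # inscribed k-gon area = pi*a*b * (k/(2*pi)) * sin(2*pi/k)
    expect_equal(a_mm2, target * (k / (2 * pi)) * sin(2 * pi / k),
                 tolerance = 1e-9)
  }
  expect_lt(abs(polygon_area3d(lamina_mesh(leaf, 4096)) * 1e6 - target),
            target * 1e-5)
})

test_that("degenerate laminas give empty polygons, not errors", {
  leaf <- list(petiole_length = 5, petiole_angle = 0, azimuth = 0,
               lamina_length = 0, lamina_width = 10)
  expect_equal(nrow(lamina_mesh(leaf, 16)), 0)
  expect_error(lamina_mesh(list(lamina_length = 1), refinement = 2))
})

test_that("mesh centroid sits on the leaf axis beyond the petiole", {
  leaf <- list(petiole_length = 8, petiole_angle = 0, azimuth = 30,
               lamina_length = 20, lamina_width = 10)
  mesh <- lamina_mesh(leaf, 256)
  cen <- colMeans(mesh)
  d <- c(cos(30 * pi / 180), sin(30 * pi / 180), 0)
  expect_equal(cen[1:2], (c(0, 0) + d[1:2] * (8 + 10) * 1e-3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("uniform grid density matches footprint arithmetic", {
  expect_equal(uniform_grid(10, 10, 0.025)$density, 1600)
  expect_equal(uniform_grid(1, 1, 0.05)$density, 1 / 0.05^2)
  g <- uniform_grid(2, 2, 0.03)
  expect_equal(nrow(g$canopy_positions), 4)
  expect_equal(g$density, 4 / 0.0036, tolerance = 0.005)
  expect_equal(max(dist(g$canopy_positions)), sqrt(2) * 0.03)
  expect_error(uniform_grid(2, 2, 0))
})

test_that("row layout geometry and errors", {
  r <- row_layout(3, 0.05, 0.006, 8)
  expect_equal(r$pattern, "row")
  d <- as.matrix(dist(r$canopy_positions))
  diag(d) <- Inf
  expect_equal(min(d), 0.006)       # within-row gap, high density
  r2 <- row_layout(3, 0.05, 0.02, 5)
  d2 <- as.matrix(dist(r2$canopy_positions))
  diag(d2) <- Inf
  expect_equal(min(d2), 0.02)       # nearest neighbour within rows
  r3 <- row_layout(1, 0.05, 0.01, 6)
  expect_true(all(r3$canopy_positions[, 1] == 0))  # single row is a line
  expect_error(row_layout(2, 0, 0.01, 4))
})

test_that("interleaved competitors form a centered symmetric arrangement", {
  lay <- interleave_competitors(uniform_grid(10, 10, 0.025), 16)
  cp <- lay$competitor_positions
  expect_equal(nrow(cp), 16)
  expect_equal(sort(unique(cp[, 1])), c(-0.075, -0.025, 0.025, 0.075))
  expect_equal(sort(unique(cp[, 2])), c(-0.075, -0.025, 0.025, 0.075))
  # symmetric about the plot center, strictly inside bounds
  expect_equal(colMeans(cp), c(x = 0, y = 0))
  expect_true(all(cp[, 1] > lay$plot_bounds[1] & cp[, 1] < lay$plot_bounds[2]))
  expect_true(all(cp[, 2] > lay$plot_bounds[3] & cp[, 2] < lay$plot_bounds[4]))
  # n = 0 leaves the layout unchanged; oversubscription errors
  expect_identical(interleave_competitors(uniform_grid(4, 4, 0.02), 0),
                   uniform_grid(4, 4, 0.02))
  expect_error(interleave_competitors(uniform_grid(3, 3, 0.02), 16))
})

test_that("central selection picks the middle plants deterministically", {
  lay <- interleave_competitors(uniform_grid(10, 10, 0.025), 16)
  sel <- central_selection(lay, 16, 4)
  pos <- lay$canopy_positions[sel$canopy, ]
  expect_true(all(abs(pos) <= 0.0375 + 1e-12))   # central 4x4 block
  expect_equal(length(sel$canopy), 16)
  cpos <- lay$competitor_positions[sel$competitor, ]
  expect_true(all(abs(cpos) <= 0.025 + 1e-12))   # central 4 competitors
  # k = all is the identity as a set
  expect_setequal(central_selection(lay, 100)$canopy, 1:100)
})

test_that("vertical cover matches the analytic single-leaf projection", {
  expect_equal(vertical_cover_fraction(new_scene(list())), 0)
  sc <- one_leaf_scene(petiole = 5, L = 20, W = 10, angle = 0)
  cov <- vertical_cover_fraction(sc, resolution = 160)
  expect_equal(cov, (pi * 20 * 10 / 4) / (40 * 40), tolerance = 0.05)
  # coincident laminas cover like one (idempotent overlap)
  p2 <- build_rosette(inert_phenotype(), 0, sc$plants[[1]]$position, id = 2)
  p2 <- add_leaf(p2, 1, 5, 0, 0, 20, 10)
  sc2 <- new_scene(c(sc$plants, list(p2)), sc$bounds)
  expect_equal(vertical_cover_fraction(sc2, resolution = 160), cov)
  expect_error(vertical_cover_fraction(sc, region = c(0, 0, 0, 0)))
})

test_that("blade display lags an erect petiole by the architectural bend", {
  # an erect leaf still displays its blade flatter than the petiole, so the
  # vertical projection shrinks with cos(petiole angle - bend), not cos(angle)
  A <- pi * 20 * 10 / 4
  for (ang in c(0, 40, 80)) {
    sc <- one_leaf_scene(petiole = 0, L = 20, W = 10, angle = ang)
    cov <- vertical_cover_fraction(sc, resolution = 160)
    expect_equal(cov, A * cos(max(ang - 25, 0) * pi / 180) / 1600,
                 tolerance = 0.08)
  }
})

test_that("LAI is one-sided area over ground area, angle-independent", {
  expect_equal(leaf_area_index(new_scene(list())), 0)
  # one plant, 50 cm2 lamina on a 100 cm2 region
  p <- build_rosette(inert_phenotype(), 0, c(0, 0))
  L <- sqrt(8 * 5000 / pi)  # ellipse L (2:1) with area 5000 mm2
  p <- add_leaf(p, 1, 5, 0, 0, L, L / 2)
  sc <- new_scene(list(p), c(-0.05, 0.05, -0.05, 0.05))
  expect_equal(leaf_area_index(sc), 0.5, tolerance = 1e-9)
  p2 <- p; p2$leaves$petiole_angle <- 70
  sc2 <- new_scene(list(p2), sc$bounds)
  expect_equal(leaf_area_index(sc2), leaf_area_index(sc))
})

test_that("cover never exceeds min(1, LAI) and no organ dips underground", {
  for (seed in 1:5) {
    sc <- random_scene(seed)
    region <- sc$bounds
    cov <- vertical_cover_fraction(sc, region, resolution = 60)
    lai <- leaf_area_index(sc, region)
    expect_lte(cov, min(1, lai) + 0.02)
    prim <- scene_primitives(sc)
    expect_true(all(prim$lam[, 3] >= 0))
    expect_true(all(prim$tips[, 3] >= -1e-12))
  }
})

test_that("scenes serialise to JSON and layouts to CSV", {
  sc <- random_scene(1, n_plants = 2, n_leaves = 2)
  js <- jsonlite::fromJSON(scene_to_json(sc), simplifyVector = FALSE)
  expect_length(js$plants, 2)
  expect_length(js$plants[[1]]$leaves, 2)   # one object per leaf
  expect_equal(js$plants[[1]]$leaves[[2]]$rank, 2)
  f <- tempfile(fileext = ".csv")
  layout_to_csv(interleave_competitors(uniform_grid(4, 4, 0.02), 4), f)
  df <- read.csv(f)
  expect_equal(nrow(df), 20)
  expect_setequal(names(df), c("id", "role", "x", "y"))
  expect_equal(sum(df$role == "competitor"), 4)
})
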