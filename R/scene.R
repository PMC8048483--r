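# 3D rosette and stand geometry: organ shapes, phyllotactic placement,
# planting layouts, projections. Internal coordinates are SI meters (z-up,
# soil plane z = 0, plot centered at the origin); organ dimensions are held
# in mm and converted when primitives are built.

ROSETTE_Z <- 0.002    # rosette center height above the soil plane (m)
PETIOLE_RADIUS <- 5e-4  # petiole cylinder radius (m)

# Hyponasty raises the petiole; the blade stays displayed flatter. The
# lamina's elevation is the petiole elevation minus this backward bend
# (floored at horizontal), so an untriggered leaf at the default 30 degree
# petiole angle displays its lamina horizontally.
LAMINA_BEND_DEG <- 25

lamina_elevation <- function(petiole_angle, bend = LAMINA_BEND_DEG) {
  pmax(petiole_angle - bend, 0)
}

leaf_columns <- function() {
  c("rank", "age_days", "petiole_length", "petiole_angle", "azimuth",
    "lamina_length", "lamina_width", "lamina_biomass", "petiole_biomass")
}

empty_leaves <- function() {
  as.data.frame(stats::setNames(rep(list(numeric(0)), 9), leaf_columns()))
}

#' Create a rosette plant
#'
#' Returns a plant with an empty leaf list and zero carbon pool. Leaves
#' appear later through [initiate_leaves()] once the stand clock passes the
#' plant's germination day.
#'
#' @param phenotype an [sas_params()] object.
#' @param germination_day stand day (>= 0) at which the plant germinates.
#'   Competitor plants germinate 3 days after the canopy plants.
#' @param position length-2 numeric, (x, y) in meters.
#' @param id integer plant identifier.
#' @param role `"canopy"` or `"competitor"`.
#' @param azimuth0 azimuth of the first leaf in degrees; successive leaves
#'   follow at the 137.5 degree golden angle. The stand initialiser draws
#'   this from a seeded RNG per plant.
#' @param base_z height of the rosette center above the soil plane, m.
#' @return an object of class `plant_state`.
#' @export
build_rosette <- function(phenotype, germination_day, position, id = 1L,
                          role = c("canopy", "competitor"), azimuth0 = 0,
                          base_z = ROSETTE_Z) {
  stopifnot(germination_day >= 0, length(position) == 2, base_z >= 0)
  role <- match.arg(role)
  structure(list(id = as.integer(id), role = role,
                 position = as.numeric(position),
                 germination_day = as.integer(germination_day),
                 leaves = empty_leaves(), carbon_pool = 0,
                 phenotype = phenotype, azimuth0 = azimuth0,
                 base_z = base_z),
            class = "plant_state")
}

#' Append a leaf organ to a plant
#'
#' Low-level constructor used by [initiate_leaves()] and by the test
#' fixtures to assemble scenes directly. Lengths in mm, angles in degrees,
#' biomass in mg.
#'
#' @param plant a `plant_state`.
#' @param rank leaf rank (strictly increasing within a plant).
#' @param petiole_length,lamina_length,lamina_width organ dimensions (mm).
#' @param petiole_angle elevation from horizontal, degrees in \[0, 90\].
#' @param azimuth degrees in \[0, 360).
#' @param lamina_biomass,petiole_biomass organ dry mass (mg).
#' @param age_days organ age in days.
#' @return the updated `plant_state`.
#' @export
add_leaf <- function(plant, rank, petiole_length, petiole_angle, azimuth,
                     lamina_length, lamina_width,
                     lamina_biomass = 0, petiole_biomass = 0, age_days = 0) {
  stopifnot(inherits(plant, "plant_state"),
            petiole_angle >= 0, petiole_angle <= 90,
            petiole_length >= 0, lamina_length >= 0, lamina_width >= 0)
  if (nrow(plant$leaves) > 0 && rank <= max(plant$leaves$rank))
    stop("leaf ranks must be strictly increasing")
  plant$leaves <- rbind(plant$leaves, data.frame(
    rank = rank, age_days = age_days, petiole_length = petiole_length,
    petiole_angle = petiole_angle, azimuth = azimuth %% 360,
    lamina_length = lamina_length, lamina_width = lamina_width,
    lamina_biomass = lamina_biomass, petiole_biomass = petiole_biomass))
  plant
}

#' Total plant biomass (mg)
#'
#' Sum of organ biomass plus the unallocated carbon pool.
#' @param plant a `plant_state`.
#' @return biomass in mg.
#' @export
plant_biomass <- function(plant) {
  sum(plant$leaves$lamina_biomass) + sum(plant$leaves$petiole_biomass) +
    plant$carbon_pool
}

#' @export
print.plant_state <- function(x, ...) {
  cat("<plant_state>", x$role, "plant", x$id, "at (",
      paste(signif(x$position, 3), collapse = ", "), ") m;",
      nrow(x$leaves), "leaves;", signif(plant_biomass(x), 4), "mg\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Layouts

new_layout <- function(pattern, canopy, competitor, bounds, density) {
  structure(list(pattern = pattern, canopy_positions = canopy,
                 competitor_positions = competitor, plot_bounds = bounds,
                 density = density),
            class = "scene_layout")
}

#' Uniform planting grid
#'
#' A centered nx-by-ny rectangular grid of canopy positions. The default
#' stand uses a 10 x 10 grid at 2.5 cm spacing, i.e. 1,600 plants per m2.
#' Density is computed over the grid footprint `(nx*spacing) x (ny*spacing)`.
#'
#' @param nx,ny grid dimensions (>= 1).
#' @param spacing inter-plant distance in meters (> 0).
#' @return a `scene_layout`.
#' @export
uniform_grid <- function(nx = 10, ny = 10, spacing = 0.025) {
  stopifnot(nx >= 1, ny >= 1)
  if (spacing <= 0) stop("spacing must be positive")
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing
  pos <- as.matrix(expand.grid(x = xs, y = ys))
  w <- nx * spacing; h <- ny * spacing
  new_layout("uniform", pos, matrix(numeric(0), 0, 2),
             c(-w / 2, w / 2, -h / 2, h / 2), nx * ny / (w * h))
}

#' Row planting pattern
#'
#' Parallel rows (along y) separated by `row_spacing` in x, with
#' `within_spacing` between plants inside a row. The experimental row
#' pattern keeps rows 5 cm apart with 0.6, 1.25 or 2 cm within rows for the
#' high, medium and low densities.
#'
#' @param n_rows number of rows.
#' @param row_spacing distance between rows, m.
#' @param within_spacing distance between plants within a row, m.
#' @param plants_per_row plants in each row.
#' @return a `scene_layout`.
#' @export
row_layout <- function(n_rows, row_spacing, within_spacing, plants_per_row) {
  stopifnot(n_rows >= 1, plants_per_row >= 1)
  if (within_spacing <= 0) stop("within-row spacing must be positive")
  if (row_spacing <= 0) stop("rows overlap: row spacing must be positive")
  xs <- (seq_len(n_rows) - (n_rows + 1) / 2) * row_spacing
  ys <- (seq_len(plants_per_row) - (plants_per_row + 1) / 2) * within_spacing
  pos <- as.matrix(expand.grid(x = xs, y = ys))
  w <- n_rows * row_spacing; h <- plants_per_row * within_spacing
  new_layout("row", pos, matrix(numeric(0), 0, 2),
             c(-w / 2, w / 2, -h / 2, h / 2),
             n_rows * plants_per_row / (w * h))
}

# Pick k symmetric coordinates from the sorted vector g (gap centers).
pick_symmetric <- function(g, k) {
  n <- length(g)
  if (k > n) stop("not enough interior gaps")
  if ((n - k) %% 2 == 0) {            # centered contiguous block
    off <- (n - k) / 2
    g[(off + 1):(off + k)]
  } else {                             # skip alternate cells around the center
    m <- (n + 1) / 2                   # n odd, k even here
    idx <- m + c(-rev(seq(1, k - 1, by = 2)), seq(1, k - 1, by = 2))
    g[idx]
  }
}

#' Place competitor plants between canopy plants
#'
#' Competitors sit at interior between-plant cell centers of a uniform
#' canopy grid, arranged symmetrically about the plot center. The default
#' stand interleaves 16 competitors as a centered 4 x 4 arrangement.
#'
#' @param layout a uniform `scene_layout`.
#' @param n number of competitors (a perfect square gives a centered
#'   square arrangement; other n take the gap centers nearest the plot
#'   center).
#' @return the layout with `competitor_positions` filled in.
#' @export
interleave_competitors <- function(layout, n) {
  stopifnot(inherits(layout, "scene_layout"))
  if (n == 0) return(layout)
  xs <- sort(unique(layout$canopy_positions[, 1]))
  ys <- sort(unique(layout$canopy_positions[, 2]))
  gx <- (xs[-1] + xs[-length(xs)]) / 2
  gy <- (ys[-1] + ys[-length(ys)]) / 2
  if (n > length(gx) * length(gy)) stop("too many competitors for the grid")
  k <- sqrt(n)
  if (k == round(k)) {
    pos <- as.matrix(expand.grid(x = pick_symmetric(gx, k),
                                 y = pick_symmetric(gy, k)))
  } else {
    all <- as.matrix(expand.grid(x = gx, y = gy))
    d <- sqrt(all[, 1]^2 + all[, 2]^2)
    ord <- order(d, all[, 1], all[, 2])
    pos <- all[ord[seq_len(n)], , drop = FALSE]
  }
  layout$competitor_positions <- pos
  layout
}

#' Select the central plants of a layout
#'
#' Metrics exclude plot edges: plot biomass uses the middle 16 canopy
#' plants and competitor biomass the middle 4 competitors. Selection takes
#' the k plants nearest the plot centroid, ties broken by x then y.
#'
#' @param layout a `scene_layout`.
#' @param k_canopy,k_competitor how many central plants of each role.
#' @return list with integer index vectors `canopy` and `competitor`.
#' @export
central_selection <- function(layout, k_canopy, k_competitor = 0) {
  pick <- function(pos, k) {
    if (k == 0 || nrow(pos) == 0) return(integer(0))
    stopifnot(k <= nrow(pos))
    cx <- mean(range(pos[, 1])); cy <- mean(range(pos[, 2]))
    d <- sqrt((pos[, 1] - cx)^2 + (pos[, 2] - cy)^2)
    order(d, pos[, 1], pos[, 2])[seq_len(k)]
  }
  list(canopy = pick(layout$canopy_positions, k_canopy),
       competitor = pick(layout$competitor_positions, k_competitor))
}

#' @export
print.scene_layout <- function(x, ...) {
  cat("<scene_layout>", x$pattern, "pattern;",
      nrow(x$canopy_positions), "canopy +",
      nrow(x$competitor_positions), "competitor positions;",
      "density", round(x$density), "plants/m2\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Scenes and derived geometry

#' Assemble a canopy scene
#'
#' @param plants list of `plant_state` objects.
#' @param bounds plot bounds `c(xmin, xmax, ymin, ymax)` in m; derived from
#'   plant positions (with a 5 cm margin) when omitted.
#' @return an object of class `canopy_scene`.
#' @export
new_scene <- function(plants, bounds = NULL) {
  if (is.null(bounds)) {
    if (length(plants) > 0) {
      xs <- vapply(plants, function(p) p$position[1], 0)
      ys <- vapply(plants, function(p) p$position[2], 0)
      bounds <- c(min(xs) - 0.05, max(xs) + 0.05,
                  min(ys) - 0.05, max(ys) + 0.05)
    } else bounds <- c(-0.125, 0.125, -0.125, 0.125)
  }
  structure(list(plants = plants, bounds = bounds), class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  nl <- sum(vapply(x$plants, function(p) nrow(p$leaves), 0L))
  cat("<canopy_scene>", length(x$plants), "plants,", nl, "leaves; bounds [",
      paste(signif(x$bounds, 3), collapse = ", "), "] m\n")
  invisible(x)
}

leaf_direction <- function(angle_deg, azimuth_deg) {
  th <- angle_deg * pi / 180; ph <- azimuth_deg * pi / 180
  cbind(cos(th) * cos(ph), cos(th) * sin(ph), sin(th))
}

#' Flatten a scene into ray-tracing primitives
#'
#' Internal representation consumed by the radiation kernels: laminas as
#' planar ellipses (center, axis, side, semi-axes), petioles as opaque
#' cylinders, plus lamina-tip sensor points. Degenerate (zero-dimension)
#' organs are skipped and counted.
#'
#' @param scene a `canopy_scene`.
#' @return list of matrices `lam`, `pet`, `tips`, the per-row `index`
#'   data.frame, and `n_degenerate`.
#' @keywords internal
#' @export
scene_primitives <- function(scene) {
  lam <- list(); pet <- list(); tips <- list(); idx <- list()
  ndeg <- 0L
  for (p in scene$plants) {
    lv <- p$leaves
    if (nrow(lv) == 0) next
    d <- leaf_direction(lv$petiole_angle, lv$azimuth)
    dl <- leaf_direction(lamina_elevation(lv$petiole_angle), lv$azimuth)
    s <- cbind(-sin(lv$azimuth * pi / 180), cos(lv$azimuth * pi / 180), 0)
    bz <- if (is.null(p$base_z)) ROSETTE_Z else p$base_z
    base <- matrix(rep(c(p$position, bz), each = nrow(lv)), ncol = 3)
    p1 <- base + d * (lv$petiole_length * 1e-3)
    keep_l <- lv$lamina_length > 0 & lv$lamina_width > 0
    ndeg <- ndeg + sum(!keep_l)
    cen <- p1 + dl * (lv$lamina_length * 1e-3 / 2)
    tip <- p1 + dl * (lv$lamina_length * 1e-3)
    if (any(keep_l)) {
      lam[[length(lam) + 1]] <- cbind(
        cen[keep_l, , drop = FALSE], dl[keep_l, , drop = FALSE],
        s[keep_l, , drop = FALSE],
        lv$lamina_length[keep_l] * 1e-3 / 2, lv$lamina_width[keep_l] * 1e-3 / 2,
        p$id, lv$rank[keep_l])
      idx[[length(idx) + 1]] <- data.frame(plant = p$id,
                                           leaf = lv$rank[keep_l])
    }
    keep_p <- lv$petiole_length > 0
    if (any(keep_p)) {
      pet[[length(pet) + 1]] <- cbind(
        base[keep_p, , drop = FALSE], p1[keep_p, , drop = FALSE],
        PETIOLE_RADIUS, p$id, lv$rank[keep_p])
    }
    tips[[length(tips) + 1]] <- cbind(tip, p$id, lv$rank)
  }
  bind <- function(l, nc) if (length(l)) do.call(rbind, l) else
    matrix(numeric(0), 0, nc)
  list(lam = bind(lam, 13), pet = bind(pet, 9), tips = bind(tips, 5),
       index = if (length(idx)) do.call(rbind, idx) else
         data.frame(plant = integer(0), leaf = integer(0)),
       n_degenerate = ndeg)
}

#' Lamina outline polygon
#'
#' The lamina is a planar ellipse attached at the distal end of a straight
#' petiole; its polygonal discretisation converges to area pi*L*W/4 as the
#' refinement grows. A zero-dimension lamina yields an empty polygon.
#'
#' @param leaf one-row data.frame or list with `petiole_length`,
#'   `petiole_angle`, `azimuth`, `lamina_length`, `lamina_width` (mm / deg).
#' @param refinement number of polygon vertices (>= 3).
#' @param base attachment point of the petiole, length-3, meters.
#' @return a `refinement` x 3 matrix of vertex coordinates in meters
#'   (0 rows when degenerate).
#' @export
lamina_mesh <- function(leaf, refinement = 32, base = c(0, 0, ROSETTE_Z)) {
  stopifnot(refinement >= 3)
  if (leaf$lamina_length <= 0 || leaf$lamina_width <= 0)
    return(matrix(numeric(0), 0, 3))
  d <- drop(leaf_direction(leaf$petiole_angle, leaf$azimuth))
  dl <- drop(leaf_direction(lamina_elevation(leaf$petiole_angle),
                            leaf$azimuth))
  s <- c(-sin(leaf$azimuth * pi / 180), cos(leaf$azimuth * pi / 180), 0)
  cen <- base + (d * leaf$petiole_length + dl * leaf$lamina_length / 2) * 1e-3
  a <- leaf$lamina_length * 1e-3 / 2; b <- leaf$lamina_width * 1e-3 / 2
  th <- 2 * pi * (seq_len(refinement) - 1) / refinement
  t(cen + t(outer(cos(th), dl * a) + outer(sin(th), s * b)))
}

#' Lamina tip point
#'
#' The distal point of the leaf, where the R:FR sensor sits.
#' @inheritParams lamina_mesh
#' @return length-3 numeric, meters.
#' @export
leaf_tip <- function(leaf, base = c(0, 0, ROSETTE_Z)) {
  d <- drop(leaf_direction(leaf$petiole_angle, leaf$azimuth))
  dl <- drop(leaf_direction(lamina_elevation(leaf$petiole_angle),
                            leaf$azimuth))
  base + (d * leaf$petiole_length + dl * leaf$lamina_length) * 1e-3
}

#' Area of a planar polygon in 3D
#'
#' Shoelace-style area from the vertex cross-product sum; used to check
#' lamina meshes against the closed-form ellipse area.
#' @param v n x 3 matrix of vertices in order.
#' @return area in the square of the coordinate unit.
#' @export
polygon_area3d <- function(v) {
  if (nrow(v) < 3) return(0)
  n <- c(0, 0, 0)
  for (i in seq_len(nrow(v))) {
    j <- if (i == nrow(v)) 1 else i + 1
    n <- n + c(v[i, 2] * v[j, 3] - v[i, 3] * v[j, 2],
               v[i, 3] * v[j, 1] - v[i, 1] * v[j, 3],
               v[i, 1] * v[j, 2] - v[i, 2] * v[j, 1])
  }
  sqrt(sum(n^2)) / 2
}

#' One-sided lamina area of a leaf (mm2)
#' @inheritParams lamina_mesh
#' @export
lamina_area <- function(leaf) {
  pi * leaf$lamina_length * leaf$lamina_width / 4
}

#' Vertical canopy cover fraction
#'
#' Fraction of a ground region whose vertical ray intersects at least one
#' lamina — the simulated analogue of canopy-cover estimates from top-view
#' photographs.
#'
#' @param scene a `canopy_scene`.
#' @param region `c(xmin, xmax, ymin, ymax)` m; defaults to scene bounds.
#' @param resolution grid points per axis (>= 1).
#' @return fraction in \[0, 1\].
#' @export
vertical_cover_fraction <- function(scene, region = scene$bounds,
                                    resolution = 50) {
  stopifnot(resolution >= 1)
  if (region[2] <= region[1] || region[4] <= region[3])
    stop("empty region")
  prim <- scene_primitives(scene)
  if (nrow(prim$lam) == 0) return(0)
  zmax <- max(prim$lam[, 3], 0) + 0.01
  m <- cpp_vertical_map(prim$lam, prim$pet, default_optics_matrix(),
                        region, as.integer(resolution), zmax, 0.025)
  mean(m$covered)
}

#' Leaf area index
#'
#' One-sided lamina area of the plants whose base lies in the region,
#' divided by the region area. Independent of leaf angles.
#'
#' @inheritParams vertical_cover_fraction
#' @return LAI in m2 leaf per m2 ground.
#' @export
leaf_area_index <- function(scene, region = scene$bounds) {
  area <- (region[2] - region[1]) * (region[4] - region[3])
  stopifnot(area > 0)
  tot <- 0
  for (p in scene$plants) {
    if (p$position[1] < region[1] || p$position[1] > region[2] ||
        p$position[2] < region[3] || p$position[2] > region[4]) next
    if (nrow(p$leaves) > 0)
      tot <- tot + sum(pi * p$leaves$lamina_length * p$leaves$lamina_width / 4)
  }
  (tot * 1e-6) / area
}

# ---------------------------------------------------------------------------
# Serialisation

#' Serialise a scene to JSON
#'
#' Plants with their leaves and fields, plus the plot bounds, in a plain
#' JSON schema.
#' @param scene a `canopy_scene`.
#' @param path optional file; when omitted the JSON string is returned.
#' @export
scene_to_json <- function(scene, path = NULL) {
  obj <- list(
    bounds = scene$bounds,
    plants = lapply(scene$plants, function(p) {
      list(id = p$id, role = p$role, position = p$position,
           germination_day = p$germination_day,
           carbon_pool = p$carbon_pool,
           phenotype = unclass(p$phenotype), leaves = p$leaves)
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Export a layout as CSV (id, role, x, y)
#' @param layout a `scene_layout`.
#' @param path output file.
#' @export
layout_to_csv <- function(layout, path) {
  cp <- layout$canopy_positions; mp <- layout$competitor_positions
  df <- rbind(
    if (nrow(cp)) data.frame(id = seq_len(nrow(cp)), role = "canopy",
                             x = cp[, 1], y = cp[, 2]),
    if (nrow(mp)) data.frame(id = nrow(cp) + seq_len(nrow(mp)),
                             role = "competitor", x = mp[, 1], y = mp[, 2]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
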