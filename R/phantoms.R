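# ---------------------------------------------------------------------------
# Voxel phantoms, coordinate conventions and water-equivalent ray tracing.
#
# Coordinates: right-handed, millimetres. Voxel indexing is 1-based in R but
# voxel [1,1,1] covers [origin, origin + spacing); a voxel's dose point is its
# center. For water studies the beam travels along +z and the phantom surface
# is the minimum-z face (the isocenter plane).
# ---------------------------------------------------------------------------

#' Construct a voxel phantom
#'
#' @param rsp 3-D array of relative stopping power (water = 1.0)
#' @param origin mm triplet: position of the corner of voxel `[1,1,1]`
#' @param spacing mm triplet (or scalar) voxel size
#' @param structures named list of logical arrays with the same shape as `rsp`
#' @return object of class `voxel_phantom`
#' @export
voxel_phantom <- function(rsp, origin = c(0, 0, 0), spacing = c(2, 2, 2),
                          structures = list()) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(dim(rsp)) != 3) stop("rsp must be a 3-D array", call. = FALSE)
  if (any(!is.finite(rsp)) || any(rsp < 0))
    stop("rsp values must be finite and >= 0", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing components must be > 0", call. = FALSE)
  for (nm in names(structures)) {
    if (!identical(dim(structures[[nm]]), dim(rsp)))
      stop("structure '", nm, "' shape differs from rsp", call. = FALSE)
    storage.mode(structures[[nm]]) <- "logical"
  }
  structure(list(rsp = rsp, origin = origin, spacing = spacing,
                 structures = structures),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom>", paste(dim(x$rsp), collapse = "x"), "voxels,",
      paste(x$spacing, collapse = "x"), "mm spacing\n")
  if (length(x$structures))
    cat("  structures:", paste(names(x$structures), collapse = ", "), "\n")
  invisible(x)
}

#' Voxel-center coordinates along one axis
#'
#' @param phantom a [voxel_phantom()]
#' @param axis 1, 2 or 3
#' @return numeric vector of voxel-center positions, mm
#' @export
voxel_centers <- function(phantom, axis) {
  n <- dim(phantom$rsp)[axis]
  phantom$origin[axis] + (seq_len(n) - 0.5) * phantom$spacing[axis]
}

#' Volume of a structure in cc
#'
#' @param phantom a [voxel_phantom()]
#' @param name structure name
#' @return volume, cm^3
#' @export
structure_volume_cc <- function(phantom, name) {
  if (!name %in% names(phantom$structures))
    stop("no structure named '", name, "'", call. = FALSE)
  sum(phantom$structures[[name]]) * prod(phantom$spacing) / 1000
}

#' Water-box phantom
#'
#' Uniform water box; the beam enters through the minimum-z face, which is
#' placed at z = 0 (the isocenter plane).
#'
#' @param lateral_size lateral extent (x and y), mm; positive multiple of
#'   `spacing`
#' @param depth extent along the beam (z), mm; positive multiple of `spacing`
#' @param spacing isotropic voxel size, mm
#' @return a [voxel_phantom()] with rsp 1.0 and a `"water"` structure
#' @export
make_water_phantom <- function(lateral_size, depth, spacing = 2) {
  if (lateral_size <= 0 || depth <= 0 || spacing <= 0)
    stop("dimensions must be positive", call. = FALSE)
  if (abs(lateral_size / spacing - round(lateral_size / spacing)) > 1e-9 ||
      abs(depth / spacing - round(depth / spacing)) > 1e-9)
    stop("dimensions must be multiples of spacing", call. = FALSE)
  nl <- round(lateral_size / spacing)
  nd <- round(depth / spacing)
  rsp <- array(1.0, dim = c(nl, nl, nd))
  voxel_phantom(rsp,
                origin = c(-lateral_size / 2, -lateral_size / 2, 0),
                spacing = rep(spacing, 3),
                structures = list(water = array(TRUE, dim = c(nl, nl, nd))))
}

# mask of voxel centers inside an ellipsoid
.ellipsoid_mask <- function(cx, cy, cz, center, semi) {
  E <- outer(((cx - center[1]) / semi[1])^2,
             ((cy - center[2]) / semi[2])^2, `+`)
  arr <- array(0, dim = c(length(cx), length(cy), length(cz)))
  zt <- ((cz - center[3]) / semi[3])^2
  for (k in seq_along(cz)) arr[, , k] <- E + zt[k]
  arr <= 1
}

#' Synthetic head phantom
#'
#' Builds a reproducible head-phantom analog: an ellipsoidal brain (rsp 1.0)
#' inside a skull shell (rsp 1.6) surrounded by air, a spherical GTV of the
#' requested diameter placed off-center, and small spherical/tubular OARs
#' (brainstem, chiasm, left/right optic nerves) at fixed documented offsets
#' from the GTV. The layout is invented (no patient geometry is modelled);
#' it supports directional trend checks only.
#'
#' @param gtv_diameter GTV diameter, mm
#' @param seed integer seed (the default phantom is fully deterministic; the
#'   seed is retained for API stability and recorded in the output)
#' @param spacing isotropic voxel size, mm
#' @return a [voxel_phantom()] with structures `brain`, `skull`, `GTV`,
#'   `brainstem`, `chiasm`, `optic_nerve_L`, `optic_nerve_R`
#' @export
make_head_phantom <- function(gtv_diameter = 37, seed = 20260428,
                              spacing = 2) {
  if (gtv_diameter <= 0) stop("gtv_diameter must be > 0", call. = FALSE)
  set.seed(seed)
  # grid: 180 x 200 x 160 mm centered on the brain
  ext <- c(180, 200, 160)
  n <- round(ext / spacing)
  origin <- -ext / 2
  cx <- origin[1] + (seq_len(n[1]) - 0.5) * spacing
  cy <- origin[2] + (seq_len(n[2]) - 0.5) * spacing
  cz <- origin[3] + (seq_len(n[3]) - 0.5) * spacing
  brain_semi <- c(70, 85, 62)
  skull_semi <- brain_semi + 6
  brain <- .ellipsoid_mask(cx, cy, cz, c(0, 0, 0), brain_semi)
  skull_out <- .ellipsoid_mask(cx, cy, cz, c(0, 0, 0), skull_semi)
  skull <- skull_out & !brain
  rsp <- array(material_properties("air")$rsp, dim = n)
  rsp[skull] <- 1.6
  rsp[brain] <- 1.0
  # GTV off-center in the right posterior quadrant
  gtv_center <- c(25, 20, 8)
  r <- gtv_diameter / 2
  if (any(abs(gtv_center) + r > brain_semi - 4))
    stop("GTV not fully inside brain", call. = FALSE)
  gtv <- .ellipsoid_mask(cx, cy, cz, gtv_center, rep(r, 3))
  sphere <- function(center, radius)
    .ellipsoid_mask(cx, cy, cz, center, rep(radius, 3))
  tube_y <- function(center, radius, half_len) {
    m <- .ellipsoid_mask(cx, cy, cz, center, c(radius, half_len, radius))
    m
  }
  oars <- list(
    brainstem     = tube_y(c(0, -15, -35), 8, 22),
    chiasm        = sphere(c(0, -35, -20), 5),
    optic_nerve_L = tube_y(c(-12, -48, -20), 3, 12),
    optic_nerve_R = tube_y(c(12, -48, -20), 3, 12)
  )
  structures <- c(list(brain = brain, skull = skull, GTV = gtv), oars)
  ph <- voxel_phantom(rsp, origin = origin, spacing = rep(spacing, 3),
                      structures = structures)
  ph$seed <- seed
  ph
}

#' Water-equivalent thickness along a ray
#'
#' Voxel-traversal line integral of relative stopping power from the point
#' where the ray enters the phantom grid up to a path length of `stop_depth`
#' beyond the entry point. Additive over sub-segments.
#'
#' @param phantom a [voxel_phantom()]
#' @param entry mm point (may be outside the grid; the integral starts at the
#'   grid entry)
#' @param direction unit vector of travel
#' @param stop_depth path length from the phantom entry point, mm
#' @return water-equivalent thickness, mm; if the ray misses the grid,
#'   returns 0 with attribute `missed = TRUE` and a warning
#' @export
wet_along_ray <- function(phantom, entry, direction, stop_depth) {
  d <- direction / sqrt(sum(direction^2))
  dims <- dim(phantom$rsp)
  lo <- phantom$origin
  hi <- phantom$origin + dims * phantom$spacing
  # slab clipping for grid entry/exit parameters
  t0 <- -Inf; t1 <- Inf
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-12) {
      if (entry[ax] < lo[ax] || entry[ax] > hi[ax]) { t0 <- Inf; break }
    } else {
      ta <- (lo[ax] - entry[ax]) / d[ax]
      tb <- (hi[ax] - entry[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (!is.finite(t0) || t0 > t1) {
    warning("ray misses the phantom grid")
    return(structure(0, missed = TRUE))
  }
  t0 <- max(t0, 0)
  t_end <- min(t1, t0 + stop_depth)
  if (t_end <= t0) return(0)
  # march voxel boundaries
  ts <- c(t0, t_end)
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-12) next
    planes <- lo[ax] + (0:dims[ax]) * phantom$spacing[ax]
    tv <- (planes - entry[ax]) / d[ax]
    ts <- c(ts, tv[tv > t0 & tv < t_end])
  }
  ts <- sort(unique(ts))
  mids <- (ts[-1] + ts[-length(ts)]) / 2
  lens <- diff(ts)
  pts <- t(vapply(mids, function(t) entry + t * d, numeric(3)))
  idx <- sapply(1:3, function(ax)
    pmin(dims[ax], pmax(1L, floor((pts[, ax] - lo[ax]) /
                                    phantom$spacing[ax]) + 1L)))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  rspv <- phantom$rsp[cbind(idx[, 1], idx[, 2], idx[, 3])]
  sum(rspv * lens)
}
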