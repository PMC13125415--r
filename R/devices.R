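# ---------------------------------------------------------------------------
# Beamline devices: universal range shifter (URS), range compensator (RC),
# and beam's-eye-view (BEV) aperture.
# ---------------------------------------------------------------------------

#' Default URS plate set (water-equivalent thicknesses, mm)
#' @export
default_urs_plates <- function() c(10, 20, 50, 100, 150, 200, 300)

#' Design the URS plate combination
#'
#' Selects the subset of available plates maximizing the total pullback
#' subject to `beam$range_water - total_wet >= max(target_distal_wets)` (the
#' deepest ray stays reachable and RC thicknesses remain minimal and
#' non-negative). Ties are broken toward fewer plates.
#'
#' @param target_distal_wets per-ray distal water-equivalent depths, mm
#' @param beam a [beam_model()]
#' @param plates available plate WETs, mm
#' @return object of class `urs_setting` with `plate_wets`, `selected`,
#'   `total_wet`, `material`, `physical_thickness`
#' @export
design_urs <- function(target_distal_wets, beam = beam_model(),
                       plates = default_urs_plates()) {
  dmax <- max(target_distal_wets)
  if (dmax >= beam$range_water)
    stop("infeasible: distal target WET exceeds beam range", call. = FALSE)
  budget <- beam$range_water - dmax
  n <- length(plates)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    tot <- sum(plates[sel])
    if (tot > budget + 1e-9) next
    cand <- list(selected = plates[sel], total_wet = tot, nplates = sum(sel))
    if (is.null(best) || tot > best$total_wet + 1e-9 ||
        (abs(tot - best$total_wet) < 1e-9 && cand$nplates < best$nplates))
      best <- cand
  }
  if (is.null(best))
    stop("infeasible: no plate combination fits the budget", call. = FALSE)
  structure(list(plate_wets = plates, selected = best$selected,
                 total_wet = best$total_wet, material = "pmma",
                 physical_thickness =
                   best$total_wet / material_properties("pmma")$rsp),
            class = "urs_setting")
}

#' Fixed-pullback URS setting (no plate search)
#'
#' Used by the water sweep, where the pullback is the controlled variable.
#'
#' @param total_wet pullback, mm WET
#' @return an `urs_setting`
#' @export
urs_from_pullback <- function(total_wet) {
  structure(list(plate_wets = total_wet, selected = total_wet,
                 total_wet = total_wet, material = "pmma",
                 physical_thickness =
                   total_wet / material_properties("pmma")$rsp),
            class = "urs_setting")
}

#' Field geometry
#'
#' @param axis beam travel direction; must be an axis-aligned unit vector
#' @param air_gap aperture downstream face to phantom surface, mm
#' @param aperture_thickness mm
#' @return object of class `beam_geometry`
#' @export
beam_geometry <- function(axis = c(0, 0, 1), air_gap = 100,
                          aperture_thickness = 50) {
  if (air_gap < 0) stop("air_gap must be >= 0", call. = FALSE)
  nz <- which(abs(axis) > 1e-9)
  if (length(nz) != 1 || abs(abs(axis[nz]) - 1) > 1e-9)
    stop("axis must be an axis-aligned unit vector", call. = FALSE)
  structure(list(axis = axis, air_gap = air_gap,
                 aperture_thickness = aperture_thickness),
            class = "beam_geometry")
}

# lateral axes (indices) and travel axis/sign for an axis-aligned geometry
.axis_frame <- function(geometry) {
  ax <- which(abs(geometry$axis) > 1e-9)
  list(travel = ax, sign = sign(geometry$axis[ax]),
       lat = setdiff(1:3, ax))
}

#' Design the range compensator by ray tracing
#'
#' For each BEV lattice ray intersecting the target,
#' `rc_wet = range_water - urs_total - distal target WET(ray)`; rays inside
#' the lattice that miss the target receive the maximum in-field thickness
#' (conservative: their peaks are pulled shallowest).
#'
#' @param phantom a [voxel_phantom()]
#' @param geometry a [beam_geometry()]
#' @param target name of the target structure
#' @param urs an `urs_setting` (designed first)
#' @param beam a [beam_model()]
#' @param lattice_pitch BEV lattice pitch, mm
#' @return object of class `rc_map` with lattice coordinates `u`, `v` (the
#'   two lateral axes in grid order), matrix `wet` (mm), and `material`
#' @export
design_rc <- function(phantom, geometry, target, urs, beam = beam_model(),
                      lattice_pitch = 2) {
  fr <- .axis_frame(geometry)
  mask <- phantom$structures[[target]]
  if (is.null(mask) || !any(mask)) stop("target mask empty", call. = FALSE)
  cu <- voxel_centers(phantom, fr$lat[1])
  cv <- voxel_centers(phantom, fr$lat[2])
  ct <- voxel_centers(phantom, fr$travel)
  # project: for each (u,v) column, distal (last along travel direction)
  # target voxel and the WET from the surface to its distal face
  perm <- c(fr$lat[1], fr$lat[2], fr$travel)
  m <- aperm(mask, perm)
  r <- aperm(phantom$rsp, perm)
  nt <- dim(m)[3]
  ord <- if (fr$sign > 0) seq_len(nt) else rev(seq_len(nt))
  m <- m[, , ord, drop = FALSE]
  r <- r[, , ord, drop = FALSE]
  h <- phantom$spacing[fr$travel]
  # cumulative WET to the distal face of each slab along travel
  cw <- aperm(apply(r, c(1, 2), cumsum), c(2, 3, 1)) * h
  anyt <- apply(m, c(1, 2), any)
  if (!any(anyt)) stop("target mask empty in BEV", call. = FALSE)
  distal_wet <- matrix(NA_real_, nrow = dim(m)[1], ncol = dim(m)[2])
  for (i in seq_len(dim(m)[1])) for (j in seq_len(dim(m)[2])) {
    if (!anyt[i, j]) next
    k <- max(which(m[i, j, ]))
    distal_wet[i, j] <- cw[i, j, k]
  }
  rc <- beam$range_water - urs$total_wet - distal_wet
  if (any(rc < -1e-9, na.rm = TRUE))
    stop("infeasible RC: URS too thick for the deepest ray", call. = FALSE)
  rc[is.na(rc)] <- max(rc, na.rm = TRUE)
  # resample the voxel-pitch BEV map onto the requested lattice pitch
  ug <- seq(min(cu), max(cu), by = lattice_pitch)
  vg <- seq(min(cv), max(cv), by = lattice_pitch)
  iu <- pmin(length(cu), pmax(1L, round((ug - cu[1]) / (cu[2] - cu[1])) + 1L))
  iv <- pmin(length(cv), pmax(1L, round((vg - cv[1]) / (cv[2] - cv[1])) + 1L))
  structure(list(u = ug, v = vg, wet = rc[iu, iv, drop = FALSE],
                 material = "pmma", lat_axes = fr$lat,
                 urs_total_wet = urs$total_wet),
            class = "rc_map")
}

#' Design the BEV aperture opening
#'
#' The opening is the morphological dilation of the target's BEV projection
#' (parallel projection along the field axis) by the margin, on a lattice of
#' pitch <= 1 mm.
#'
#' @param phantom a [voxel_phantom()] (or `NULL` when `square_half_size` is
#'   given)
#' @param geometry a [beam_geometry()]
#' @param target name of the target structure
#' @param margin aperture margin, mm (>= 0)
#' @param pitch lattice pitch, mm (<= 1)
#' @param square_half_size if given, bypass projection and build a centered
#'   square opening of half-size `square_half_size + margin` (water sweep)
#' @return object of class `aperture_design` with `u`, `v`, logical `mask`,
#'   `margin`, `thickness`, `material`; square openings also carry `half_u`,
#'   `half_v`
#' @export
design_aperture <- function(phantom = NULL, geometry = beam_geometry(),
                            target = NULL, margin = 5, pitch = 1,
                            square_half_size = NULL) {
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  if (pitch > 1) stop("lattice pitch must be <= 1 mm", call. = FALSE)
  if (!is.null(square_half_size)) {
    a <- square_half_size + margin
    u <- seq(-a - 5, a + 5, by = pitch)
    mask <- outer(abs(u) <= a, abs(u) <= a, `&`)
    return(structure(list(u = u, v = u, mask = mask, margin = margin,
                          thickness = geometry$aperture_thickness,
                          material = "brass", half_u = a, half_v = a),
                     class = "aperture_design"))
  }
  fr <- .axis_frame(geometry)
  mask3 <- phantom$structures[[target]]
  if (is.null(mask3) || !any(mask3))
    stop("target projects to an empty BEV region", call. = FALSE)
  proj <- apply(aperm(mask3, c(fr$lat[1], fr$lat[2], fr$travel)),
                c(1, 2), any)
  cu <- voxel_centers(phantom, fr$lat[1])
  cv <- voxel_centers(phantom, fr$lat[2])
  pts <- which(proj, arr.ind = TRUE)
  pu <- cu[pts[, 1]]; pv <- cv[pts[, 2]]
  half_vox <- phantom$spacing[fr$lat] / 2
  u <- seq(min(pu) - margin - 3, max(pu) + margin + 3, by = pitch)
  v <- seq(min(pv) - margin - 3, max(pv) + margin + 3, by = pitch)
  # dilation: lattice point is open iff within `margin` of the projected
  # target region (voxel footprints treated as rectangles)
  mask <- matrix(FALSE, length(u), length(v))
  for (k in seq_along(pu)) {
    du <- pmax(0, abs(u - pu[k]) - half_vox[1])
    dv <- pmax(0, abs(v - pv[k]) - half_vox[2])
    sel_u <- which(du <= margin)
    if (!length(sel_u)) next
    d2 <- outer(du[sel_u]^2, dv^2, `+`)
    mask[sel_u, ] <- mask[sel_u, ] | (d2 <= margin^2 + 1e-9)
  }
  structure(list(u = u, v = v, mask = mask, margin = margin,
                 thickness = geometry$aperture_thickness,
                 material = "brass"),
            class = "aperture_design")
}

#' Aperture opening area
#'
#' @param aperture an `aperture_design`
#' @return area, mm^2
#' @export
aperture_opening_area <- function(aperture) {
  pu <- diff(aperture$u[1:2])
  pv <- diff(aperture$v[1:2])
  sum(aperture$mask) * pu * pv
}

# opening interval [lo, hi] along u at lateral position v (and vice versa);
# returns NULL when the slab is fully blocked
.aperture_interval <- function(aperture, along = c("u", "v"), at) {
  along <- match.arg(along)
  if (!is.null(aperture$half_u)) {
    h <- if (along == "u") aperture$half_u else aperture$half_v
    ho <- if (along == "u") aperture$half_v else aperture$half_u
    if (abs(at) > ho) return(NULL)
    return(c(-h, h))
  }
  if (along == "u") {
    j <- which.min(abs(aperture$v - at))
    open <- aperture$mask[, j]
    coord <- aperture$u
  } else {
    i <- which.min(abs(aperture$u - at))
    open <- aperture$mask[i, ]
    coord <- aperture$v
  }
  if (!any(open)) return(NULL)
  range(coord[open])
}
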