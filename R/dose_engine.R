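# ---------------------------------------------------------------------------
# Field setup and the separable 3-D pencil-beam dose engine.
# ---------------------------------------------------------------------------

#' Field setup
#'
#' One irradiation field: geometry (axis-aligned direction and air gap), URS
#' setting, optional range compensator, optional aperture, and the spot map.
#'
#' @param geometry a [beam_geometry()]
#' @param urs an `urs_setting`
#' @param spotmap a `spot_map` (spot x/y are along the two lateral axes of
#'   the geometry, in ascending-axis order)
#' @param rc an `rc_map` or `NULL`
#' @param aperture an `aperture_design` or `NULL`
#' @param field_id label
#' @return object of class `field_setup`
#' @export
field_setup <- function(geometry, urs, spotmap, rc = NULL, aperture = NULL,
                        field_id = "field") {
  structure(list(geometry = geometry, urs = urs, spotmap = spotmap,
                 rc = rc, aperture = aperture, field_id = field_id),
            class = "field_setup")
}

#' Spot fluence at the aperture exit plane
#'
#' Gaussian fluence of one spot evaluated at the aperture exit plane (core +
#' degrader-halo mixture), multiplied by the binary opening indicator (brass
#' is a perfect absorber). Returns the fluence map and the transmitted
#' fraction of the spot's protons.
#'
#' @param spot list or one-row data.frame with `x`, `y`, `mu`
#' @param aperture an `aperture_design`
#' @param beam a [beam_model()]
#' @param urs an `urs_setting`
#' @param geometry a [beam_geometry()]
#' @return list with `u`, `v`, `fluence` (protons/mm^2), `transmission`
#' @export
spot_fluence_at_aperture <- function(spot, aperture, beam = beam_model(),
                                     urs = urs_from_pullback(0),
                                     geometry = beam_geometry()) {
  tm <- transport_model(urs$total_wet, geometry$air_gap, depths = 1,
                        beam = beam,
                        aperture_thickness = geometry$aperture_thickness)
  z_out_drift <- geometry$aperture_thickness  # entrance face -> exit face
  sig_comp <- function(comp) {
    sqrt(comp$Sxx + 2 * comp$Sxt * z_out_drift +
           comp$Stt * z_out_drift^2)
  }
  sigs <- c(core = sig_comp(tm$core), halo = sig_comp(tm$halo))
  wgts <- c(core = 1 - tm$halo_weight, halo = tm$halo_weight)
  du <- diff(aperture$u[1:2])
  dv <- diff(aperture$v[1:2])
  fl <- matrix(0, length(aperture$u), length(aperture$v))
  trans <- 0
  square <- !is.null(aperture$half_u)
  for (ci in seq_along(sigs)) {
    s <- sigs[ci]
    fl <- fl + wgts[ci] *
      (outer(dnorm(aperture$u, spot$x, s),
             dnorm(aperture$v, spot$y, s)) * aperture$mask)
    if (square) {
      # exact Gaussian mass through the rectangular opening
      trans <- trans + wgts[ci] *
        (pnorm((aperture$half_u - spot$x) / s) -
           pnorm((-aperture$half_u - spot$x) / s)) *
        (pnorm((aperture$half_v - spot$y) / s) -
           pnorm((-aperture$half_v - spot$y) / s))
    } else {
      # cell-integrated Gaussian mass (each lattice cell spans +/- pitch/2)
      iu <- pnorm((aperture$u + du / 2 - spot$x) / s) -
        pnorm((aperture$u - du / 2 - spot$x) / s)
      ivv <- pnorm((aperture$v + dv / 2 - spot$y) / s) -
        pnorm((aperture$v - dv / 2 - spot$y) / s)
      trans <- trans + wgts[ci] * sum(outer(iu, ivv) * aperture$mask)
    }
  }
  n_protons <- spot$mu * beam$protons_per_mu
  list(u = aperture$u, v = aperture$v, fluence = n_protons * fl,
       transmission = unname(trans))
}

# permute a phantom array into the beam frame: dims (lat1, lat2, travel),
# travel slices ordered along the beam direction
.to_beam_frame <- function(arr, fr) {
  a <- aperm(arr, c(fr$lat[1], fr$lat[2], fr$travel))
  if (fr$sign < 0) a <- a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
  a
}
.from_beam_frame <- function(arr, fr, dims) {
  if (fr$sign < 0) arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
  inv <- order(c(fr$lat[1], fr$lat[2], fr$travel))
  aperm(arr, inv)
}

#' Compute the dose of one field
#'
#' Separable analytic pencil-beam transport: per depth layer along the beam
#' axis, the integral depth-dose is indexed by each lateral column's
#' water-equivalent depth (including the local RC thickness), and the lateral
#' kernel is the product of the two per-axis profile factors from
#' [spot_axis_profiles()] (aperture handled per spot by the opening's slab
#' intervals at the spot position; exact for rectangular openings). Dose in
#' voxels with rsp < 0.05 (air) is set to zero.
#'
#' @param field a [field_setup()]
#' @param phantom a [voxel_phantom()]
#' @param beam a [beam_model()]
#' @param rbe if `TRUE`, multiply physical dose by `rbe_factor`
#' @param rbe_factor relative biological effectiveness (default 1.1)
#' @param influence_mask optional logical array (phantom shape): when given,
#'   the per-spot dose contributions at these voxels are returned as a dense
#'   matrix (`length(which(mask))` x n_spots)
#' @param nodes Gauss-Hermite node count for aperture transport
#' @return object of class `dose_grid`: list with `dose` (array, Gy),
#'   `per_spot` (matrix or `NULL`), `mask_index` (voxel indices of the
#'   influence rows), `field_id`
#' @export
compute_field_dose <- function(field, phantom, beam = beam_model(),
                               rbe = FALSE, rbe_factor = 1.1,
                               influence_mask = NULL, nodes = 15) {
  sp <- field$spotmap$spots
  if (!nrow(sp)) stop("empty field: no spots", call. = FALSE)
  fr <- .axis_frame(field$geometry)
  rsp_b <- .to_beam_frame(phantom$rsp, fr)
  dims_b <- dim(rsp_b)
  h <- phantom$spacing[fr$travel]
  cu <- voxel_centers(phantom, fr$lat[1])
  cv <- voxel_centers(phantom, fr$lat[2])
  # WET to each voxel center per column (plus RC)
  wet_cum <- aperm(apply(rsp_b, c(1, 2), cumsum), c(2, 3, 1)) * h
  wet_ctr <- wet_cum - rsp_b * h / 2
  if (!is.null(field$rc)) {
    rc_w <- matrix(0, dims_b[1], dims_b[2])
    iu <- pmin(length(field$rc$u),
               pmax(1L, round((cu - field$rc$u[1]) /
                                diff(field$rc$u[1:2])) + 1L))
    iv <- pmin(length(field$rc$v),
               pmax(1L, round((cv - field$rc$v[1]) /
                                diff(field$rc$v[1:2])) + 1L))
    rc_w <- field$rc$wet[iu, iv, drop = FALSE]
    wet_ctr <- wet_ctr + array(rep(rc_w, dims_b[3]), dim = dims_b)
    rc_central <- rc_w[which.min(abs(cu)), which.min(abs(cv))]
  } else rc_central <- 0
  # total WET for the depth-dose lookup includes the upstream URS pullback
  wet_ctr <- wet_ctr + field$urs$total_wet
  # physical surface: first slab with substantial density on the central axis
  icu <- which.min(abs(cu)); icv <- which.min(abs(cv))
  central_rsp <- rsp_b[icu, icv, ]
  surf <- which(central_rsp > 0.1)[1]
  if (is.na(surf)) surf <- 1L
  depth <- (seq_len(dims_b[3]) - surf + 0.5) * h
  depth <- pmax(depth, 0.25)
  # transport model at all layer depths (sigma indexed by geometric depth
  # from the surface; IDD by per-column WET)
  tm <- transport_model(field$urs$total_wet + rc_central,
                        field$geometry$air_gap, depths = depth, beam = beam,
                        aperture_thickness =
                          field$geometry$aperture_thickness)
  idd_map <- array(bragg_depth_dose(pmax(0, wet_ctr), beam), dim = dims_b)
  n_protons <- sp$mu * beam$protons_per_mu
  want_inf <- !is.null(influence_mask)
  if (want_inf) {
    mask_b <- .to_beam_frame(influence_mask, fr)
    mask_index_b <- which(mask_b)
    per_spot <- matrix(0, length(mask_index_b), nrow(sp))
    mk_ij <- arrayInd(mask_index_b, dims_b)
  } else per_spot <- NULL
  # per-spot aperture intervals along each axis (slab approximation)
  ap <- field$aperture
  iv_u <- iv_v <- vector("list", nrow(sp))
  keep <- rep(TRUE, nrow(sp))
  if (!is.null(ap)) {
    for (s in seq_len(nrow(sp))) {
      iu_s <- .aperture_interval(ap, "u", at = sp$y[s])
      iv_s <- .aperture_interval(ap, "v", at = sp$x[s])
      if (is.null(iu_s) || is.null(iv_s)) { keep[s] <- FALSE; next }
      iv_u[[s]] <- iu_s
      iv_v[[s]] <- iv_s
    }
  }
  dose_b <- array(0, dim = dims_b)
  peak_idd <- max(idd_map)
  for (k in seq_len(dims_b[3])) {
    layer_idd <- idd_map[, , k]
    if (max(layer_idd) < 1e-6 * peak_idd) next
    if (is.null(ap)) {
      Kx <- spot_axis_profiles(tm, k, sp$x, cu, aperture = NULL)
      Ky <- spot_axis_profiles(tm, k, sp$y, cv, aperture = NULL)
    } else {
      Kx <- matrix(0, length(cu), nrow(sp))
      Ky <- matrix(0, length(cv), nrow(sp))
      for (s in which(keep)) {
        Kx[, s] <- spot_axis_profiles(tm, k, sp$x[s], cu,
                                      aperture = iv_u[[s]], nodes = nodes)
        Ky[, s] <- spot_axis_profiles(tm, k, sp$y[s], cv,
                                      aperture = iv_v[[s]], nodes = nodes)
      }
    }
    fl <- Kx %*% (n_protons * t(Ky))
    dose_b[, , k] <- layer_idd * fl
    if (want_inf) {
      in_k <- which(mk_ij[, 3] == k)
      if (length(in_k)) {
        iuu <- mk_ij[in_k, 1]; ivv <- mk_ij[in_k, 2]
        contrib <- (Kx[iuu, , drop = FALSE] * Ky[ivv, , drop = FALSE]) *
          rep(n_protons, each = length(in_k)) *
          layer_idd[cbind(iuu, ivv)]
        per_spot[in_k, ] <- contrib
      }
    }
  }
  dose_b[rsp_b < 0.05] <- 0
  if (want_inf) {
    # zero out influence rows in air as well
    air_rows <- rsp_b[mask_index_b] < 0.05
    per_spot[air_rows, ] <- 0
  }
  scale <- if (rbe) rbe_factor else 1
  dose <- .from_beam_frame(dose_b, fr, dim(phantom$rsp)) * scale
  mask_index <- NULL
  if (want_inf) {
    # rows of per_spot are ordered by beam-frame index; map to phantom-frame
    # mask ordering
    idx_arr <- array(seq_len(prod(dims_b)), dims_b)
    idx_ph <- .from_beam_frame(idx_arr, fr, dim(phantom$rsp))
    ph_mask_idx <- which(influence_mask)
    beam_idx_of_ph <- idx_ph[ph_mask_idx]
    ord <- match(beam_idx_of_ph, mask_index_b)
    per_spot <- per_spot[ord, , drop = FALSE] * scale
    mask_index <- ph_mask_idx
  }
  structure(list(dose = dose, per_spot = per_spot,
                 mask_index = mask_index, field_id = field$field_id,
                 rbe = rbe),
            class = "dose_grid")
}
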