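# ---------------------------------------------------------------------------
# Fermi-Eyges lateral transport with differential Highland scattering power,
# degrader halo, diverging source, and thick-aperture phase-space transmission.
#
# Geometry convention: beam travels along +z; the phantom surface is at z = 0
# (isocenter); upstream device coordinates are negative.
# ---------------------------------------------------------------------------

# Engine constants. The Highland calibration factor is determined once against
# an independent literature benchmark: the in-water scattering sigma at the
# end of range is ~2.1% of the range (Gottschalk's rule); the uncalibrated
# differential-Highland integral overestimates it by a few percent.
.engine <- new.env(parent = emptyenv())
.engine$halo_frac_slope  <- 4e-4   # in-phantom nuclear halo fraction per mm
.engine$halo_frac_max    <- 0.15   # cap on halo fraction
.engine$halo_sigma_slope <- 0.05   # in-phantom halo sigma growth, mm per mm
.engine$urs_halo_frac    <- 0.10   # degrader (URS) halo proton fraction
.engine$urs_halo_ratio   <- 3      # degrader halo angular sigma ratio
.engine$mcs_sigma_fraction_of_range <- 0.021  # calibration benchmark

# step table for a stack of slabs: data.frame(u=mid z, h=step, rsp, X0, urs)
.build_steps <- function(segments, z_start, dl = 1) {
  rows <- vector("list", length(segments))
  z <- z_start
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    if (seg$len <= 0) { rows[[i]] <- NULL; next }
    n <- max(1L, ceiling(seg$len / dl))
    h <- seg$len / n
    m <- material_properties(seg$mat)
    rows[[i]] <- data.frame(u = z + (seq_len(n) - 0.5) * h, h = h,
                            rsp = m$rsp, X0 = m$X0,
                            urs = isTRUE(seg$urs))
    z <- z + seg$len
  }
  do.call(rbind, rows)
}

# differential Highland scattering power per step (rad^2), calibrated
.scat_power <- function(steps, beam) {
  wet_mid <- cumsum(steps$rsp * steps$h) - steps$rsp * steps$h / 2
  r <- pmax(0.5, beam$range_water - wet_mid)
  pvv <- .pv_of_energy(proton_energy_from_range(r, beam))
  tX <- cumsum(steps$h / steps$X0)
  corr <- (1 + 0.038 * log(pmax(tX, 1e-12)))^2
  corr[tX < 1e-6] <- 0
  .highland_calibration(beam) * corr * (14.1 / pvv)^2 * steps$h / steps$X0
}

# calibration factor: sigma(end of range in water) must equal the benchmark
.highland_cal_env <- new.env(parent = emptyenv())
.highland_calibration <- function(beam) {
  key <- paste(beam$range_water, beam$energy, beam$bragg_kleeman_p, sep = "_")
  if (!is.null(.highland_cal_env[[key]])) return(.highland_cal_env[[key]])
  # uncalibrated A2 at end of range in pure water
  steps <- .build_steps(list(list(mat = "water", len = beam$range_water)), 0)
  wet_mid <- cumsum(steps$rsp * steps$h) - steps$rsp * steps$h / 2
  r <- pmax(0.5, beam$range_water - wet_mid)
  pvv <- .pv_of_energy(proton_energy_from_range(r, beam))
  tX <- cumsum(steps$h / steps$X0)
  corr <- (1 + 0.038 * log(pmax(tX, 1e-12)))^2
  corr[tX < 1e-6] <- 0
  Tv <- corr * (14.1 / pvv)^2 * steps$h / steps$X0
  A2 <- sum(Tv * (beam$range_water - steps$u)^2)
  target <- (.engine$mcs_sigma_fraction_of_range * beam$range_water)^2
  f <- target / A2
  .highland_cal_env[[key]] <- f
  f
}

# diverging source covariance at plane z (waist far upstream; fully
# correlated): sigma(z) = sigma_iso + div * z, clamped at 0.5 mm
.source_cov <- function(z, beam) {
  s <- pmax(0.5, beam$sigma_iso + beam$divergence * z)
  list(xx = s^2, xt = beam$divergence * s, tt = beam$divergence^2)
}

#' Beamline transport model for one sweep/field geometry
#'
#' Builds the lateral phase-space description of a pencil beam that traverses
#' a PMMA universal range shifter (URS), an air gap containing a (possibly
#' absent) 5 cm aperture block, and enters a water-equivalent phantom. Both a
#' Highland "core" component and a degrader-halo component (a fixed fraction
#' of protons leaving the URS with a 3x angular spread) are propagated. For
#' each requested depth the model records the total no-aperture sigma, the
#' scattering accumulated downstream of the aperture entrance face, and the
#' lever arm from that face.
#'
#' @param urs_wet URS water-equivalent thickness (the range pullback), mm
#' @param air_gap aperture downstream face to phantom surface, mm
#' @param depths in-phantom depths at which transport moments are needed, mm
#' @param beam a [beam_model()]
#' @param aperture_thickness aperture block thickness, mm
#' @param phantom_material in-phantom material name (default water)
#' @return object of class `transport_model` with components `core` and
#'   `halo`, each holding the phase-space covariance (`Sxx`, `Sxt`, `Stt`) at
#'   the aperture entrance face and a list `layers` of per-depth records
#'   (`z`, `L`, `sp`, `sig_tot`); plus `halo_weight`, `z_in`, `ap_thick`
#' @export
transport_model <- function(urs_wet, air_gap, depths, beam = beam_model(),
                            aperture_thickness = 50,
                            phantom_material = "water") {
  stopifnot(urs_wet >= 0, air_gap >= 0, all(depths >= 0))
  t_urs <- urs_wet / material_properties("pmma")$rsp
  z_in <- -air_gap - aperture_thickness   # aperture entrance face
  z0 <- z_in - t_urs
  segs <- list(list(mat = "pmma", len = t_urs, urs = TRUE),
               list(mat = "air", len = aperture_thickness + air_gap),
               list(mat = phantom_material, len = max(depths) + 5))
  segs <- Filter(function(s) s$len > 0, segs)
  steps <- .build_steps(segs, z0)
  Tv <- .scat_power(steps, beam)
  urs_sel <- steps$urs
  mom_sel <- function(sel, z) {
    s2 <- sel & steps$u < z
    c(A0 = sum(Tv[s2]),
      A1 = sum(Tv[s2] * (z - steps$u[s2])),
      A2 = sum(Tv[s2] * (z - steps$u[s2])^2))
  }
  a2_post <- function(z_from, z) {
    sel <- steps$u > z_from & steps$u < z
    sum(Tv[sel] * (z - steps$u[sel])^2)
  }
  comp <- function(scale_urs) {
    m_u <- mom_sel(urs_sel, z_in)
    m_o <- mom_sel(!urs_sel, z_in)
    sv <- .source_cov(z_in, beam)
    lay <- lapply(depths, function(z) {
      mu <- mom_sel(urs_sel, z)
      mo <- mom_sel(!urs_sel, z)
      list(z = z, L = z - z_in,
           sp = sqrt(a2_post(z_in, z)),
           sig_tot = unname(sqrt(scale_urs * mu[["A2"]] + mo[["A2"]] +
                                   .source_cov(z, beam)$xx)))
    })
    list(Sxx = unname(scale_urs * m_u[["A2"]] + m_o[["A2"]] + sv$xx),
         Sxt = unname(scale_urs * m_u[["A1"]] + m_o[["A1"]] + sv$xt),
         Stt = unname(scale_urs * m_u[["A0"]] + m_o[["A0"]] + sv$tt),
         layers = lay)
  }
  structure(list(core = comp(1),
                 halo = comp(.engine$urs_halo_ratio^2),
                 halo_weight = .engine$urs_halo_frac,
                 z_in = z_in, ap_thick = aperture_thickness,
                 depths = depths),
            class = "transport_model")
}

#' Total lateral sigma at depth (no aperture, Highland core)
#'
#' Quadrature combination of the diverging source, the MCS angular spread of
#' all upstream slabs drifted to depth, and the in-phantom MCS growth, as
#' accumulated by the Fermi-Eyges moments. Strictly increasing in air gap and
#' in URS thickness.
#'
#' @param wet_depth in-phantom depth, mm (water phantom: equals geometric)
#' @param urs_wet URS water-equivalent thickness, mm
#' @param air_gap air gap, mm
#' @param beam a [beam_model()]
#' @return sigma, mm
#' @export
lateral_sigma <- function(wet_depth, urs_wet = 0, air_gap = 0,
                          beam = beam_model()) {
  tm <- transport_model(urs_wet, air_gap, depths = wet_depth, beam = beam)
  vapply(seq_along(wet_depth),
         function(i) tm$core$layers[[i]]$sig_tot, numeric(1))
}

# in-phantom nuclear halo parameters at depth z (mm)
.halo_frac <- function(z) pmin(.engine$halo_frac_max,
                               .engine$halo_frac_slope * z)
.halo_sigma <- function(z) .engine$halo_sigma_slope * z

# Gauss-Hermite nodes/weights for N(0,1) expectation (Golub-Welsch)
.gauss_hermite <- function(n = 31) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values * sqrt(2), w = e$vectors[1, ]^2)
}

# --------------------------------------------------------------------------
# 1-D per-axis spot profiles (the high-fidelity edge model)
# --------------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# Aperture-transmitted 1-D profile of one phase-space component.
# Theta-resolved two-face acceptance: for each angular node, the conditional
# position Gaussian at the aperture entrance face is truncated to
# [max(-a, -a - T*th), min(a, a - T*th)] (entrance and exit faces of the
# a-half-opening, T-thick absorber), drifted th*L to depth, and convolved with
# the downstream scattering sp (closed form).
.profile_on <- function(tm, which_comp, layer_idx, centers, opening, x,
                        extra_sp = 0, nodes = 31) {
  comp <- tm[[which_comp]]
  lay <- comp$layers[[layer_idx]]
  q <- .gauss_hermite(nodes)
  th <- q$x * sqrt(comp$Stt)
  w <- q$w
  mu_c <- comp$Sxt / comp$Stt * th
  sc2 <- comp$Sxx - comp$Sxt^2 / comp$Stt
  sc <- sqrt(sc2)
  Tap <- tm$ap_thick
  L <- lay$L
  sp <- sqrt(lay$sp^2 + extra_sp^2)
  s2 <- sc2 + sp^2
  s <- sqrt(s2)
  P <- matrix(0, length(x), length(centers))
  for (k in seq_along(th)) {
    lo <- max(opening[1], opening[1] - Tap * th[k])
    hi <- min(opening[2], opening[2] - Tap * th[k])
    if (lo >= hi) next
    for (j in seq_along(centers)) {
      muk <- centers[j] + mu_c[k]
      ctr <- muk + th[k] * L
      if (sp < 1e-3) {
        acc <- as.numeric(x - th[k] * L >= lo & x - th[k] * L <= hi)
        P[, j] <- P[, j] + w[k] * dnorm(x - th[k] * L, muk, sc) * acc
      } else {
        mx <- muk + sc2 * (x - th[k] * L - muk) / s2
        sx <- sc * sp / s
        P[, j] <- P[, j] + w[k] * dnorm(x, ctr, s) *
          (pnorm((hi - mx) / sx) - pnorm((lo - mx) / sx))
      }
    }
  }
  P
}

#' Per-spot 1-D lateral profiles at depth
#'
#' Evaluates, for each spot center, the 1-D lateral dose profile factor at a
#' given depth layer, with or without the thick aperture, including the
#' degrader-halo and in-phantom-halo mixture components. For square fields
#' and openings the full 2-D profile is the product of the two axis factors,
#' so these are the building blocks of both the edge-metric fast path and the
#' separable 3-D engine.
#'
#' @param tm a [transport_model()] whose `depths` include the layer
#' @param layer_idx index into `tm$depths`
#' @param centers spot center coordinates along the axis, mm
#' @param x evaluation positions, mm
#' @param aperture `NULL` for no aperture, a scalar half-opening `a` (mm)
#'   for the centered interval `[-a, a]`, or an interval `c(lo, hi)`
#' @param nodes Gauss-Hermite node count for the angular quadrature
#' @return matrix `length(x)` x `length(centers)` of profile values
#' @export
spot_axis_profiles <- function(tm, layer_idx, centers, x, aperture = NULL,
                               nodes = 31) {
  stopifnot(inherits(tm, "transport_model"))
  lay <- tm$core$layers[[layer_idx]]
  f <- .halo_frac(lay$z)
  sh <- .halo_sigma(lay$z)
  fu <- tm$halo_weight
  if (is.null(aperture)) {
    off_comp <- function(comp, wgt) {
      st <- comp$layers[[layer_idx]]$sig_tot
      wgt * ((1 - f) * outer(x, centers, function(xx, cc) dnorm(xx, cc, st)) +
               f * outer(x, centers, function(xx, cc)
                 dnorm(xx, cc, sqrt(st^2 + sh^2))))
    }
    off_comp(tm$core, 1 - fu) + off_comp(tm$halo, fu)
  } else {
    opening <- if (length(aperture) == 1) c(-aperture, aperture)
               else aperture
    on_comp <- function(which_comp, wgt) {
      wgt * ((1 - f) * .profile_on(tm, which_comp, layer_idx, centers,
                                   opening, x, 0, nodes) +
               f * .profile_on(tm, which_comp, layer_idx, centers,
                               opening, x, sh, nodes))
    }
    on_comp("core", 1 - fu) + on_comp("halo", fu)
  }
}
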