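#' @importFrom stats approx dnorm pnorm qnorm convolve optimize rnorm setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Materials
# ---------------------------------------------------------------------------

.materials <- list(
  water = list(rsp = 1.0,   X0 = 360.8),
  pmma  = list(rsp = 1.16,  X0 = 344),
  air   = list(rsp = 0.001, X0 = 3.04e5),
  brass = list(rsp = NA,    X0 = NA, absorber = TRUE)
)

#' Material properties used by the transport engine
#'
#' Returns relative stopping power and radiation length for a named material.
#' Brass is modelled as a perfect absorber (a 5 cm brass block exceeds the
#' 250 MeV proton range in brass) and has no transport properties.
#'
#' @param name one of `"water"`, `"pmma"`, `"air"`, `"brass"`
#' @return list with elements `rsp` (relative stopping power) and `X0`
#'   (radiation length, mm); brass additionally has `absorber = TRUE`
#' @export
material_properties <- function(name) {
  if (!name %in% names(.materials))
    stop("unknown material: ", name, call. = FALSE)
  .materials[[name]]
}

# ---------------------------------------------------------------------------
# Beam model
# ---------------------------------------------------------------------------

#' Machine beam model
#'
#' Bundles the machine description: single energy, range in water, spot sigma
#' at isocenter, beam divergence, protons per MU, MU rate, minimum MU per spot
#' and minimum spot time (MST). Defaults describe a 250 MeV scanned proton
#' beam whose pristine peak reaches 379 mm in water, with a 3.5 mm isocenter
#' spot sigma, 3 mrad divergence, 6.09e6 protons per MU, a 400 MU minimum and
#' a 0.5 ms MST; the default MU rate is `min_mu / min_spot_time` = 8e5 MU/s,
#' the unique value at which the minimum spot exactly saturates the MST.
#'
#' @param energy beam energy, MeV
#' @param range_water range of the pristine beam in water, mm
#' @param sigma_iso spot sigma at isocenter, mm
#' @param divergence beam divergence, rad (beam diverging through isocenter)
#' @param protons_per_mu protons per monitor unit
#' @param mu_rate MU delivery rate, MU/s
#' @param min_mu minimum deliverable MU per spot
#' @param min_spot_time minimum spot time, s
#' @param bragg_kleeman_p exponent of the Bragg-Kleeman range-energy relation
#' @return object of class `beam_model`
#' @export
beam_model <- function(energy = 250, range_water = 379, sigma_iso = 3.5,
                       divergence = 0.003, protons_per_mu = 6.09e6,
                       mu_rate = min_mu / min_spot_time, min_mu = 400,
                       min_spot_time = 5e-4, bragg_kleeman_p = 1.77) {
  vals <- c(energy = energy, range_water = range_water, sigma_iso = sigma_iso,
            divergence = divergence, protons_per_mu = protons_per_mu,
            mu_rate = mu_rate, min_mu = min_mu,
            min_spot_time = min_spot_time, bragg_kleeman_p = bragg_kleeman_p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all beam_model fields must be finite and strictly positive",
         call. = FALSE)
  if (min_mu / mu_rate < min_spot_time - 1e-12)
    stop("inconsistent delivery model: min_mu / mu_rate must be >= ",
         "min_spot_time", call. = FALSE)
  structure(as.list(vals), class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat("<beam_model>", x$energy, "MeV, range", x$range_water,
      "mm, sigma_iso", x$sigma_iso, "mm, div", x$divergence * 1e3, "mrad\n")
  cat("  ", format(x$protons_per_mu, scientific = TRUE), "p/MU, rate",
      x$mu_rate, "MU/s, min MU", x$min_mu, ", MST", x$min_spot_time * 1e3,
      "ms\n")
  invisible(x)
}

# Bragg-Kleeman alpha (cm/MeV^p), anchored so range(energy) = range_water
.bk_alpha_cm <- function(beam) {
  (beam$range_water / 10) / beam$energy^beam$bragg_kleeman_p
}

#' Residual proton energy from residual range
#'
#' Inverts the Bragg-Kleeman relation R = alpha E^p, with alpha anchored so
#' that the model energy maps exactly to the model range in water.
#'
#' @param residual_range_mm residual range in water, mm (vectorized)
#' @param beam a [beam_model()]
#' @return energy, MeV
#' @export
proton_energy_from_range <- function(residual_range_mm, beam = beam_model()) {
  pmax(0, (residual_range_mm / 10) / .bk_alpha_cm(beam))^
    (1 / beam$bragg_kleeman_p)
}

# pv = E(E+2m)/(E+m), MeV (m = proton rest mass)
.pv_of_energy <- function(E) {
  m <- 938.272
  E * (E + 2 * m) / (E + m)
}

# ---------------------------------------------------------------------------
# Pristine Bragg depth-dose
# ---------------------------------------------------------------------------

# Unscaled, unshifted Bortfeld-style curve on a fine grid. The analytic core
# (R-z)^(1/p-1) + 0.0134 (R-z)^(1/p) is convolved with the range-straggling
# Gaussian sigma_str = 0.012 (R_cm)^0.935 cm.
.bragg_curve_raw <- function(range_water, p, dz = 0.25) {
  R0 <- range_water
  z <- seq(0, R0 + 50, by = dz)
  base <- ifelse(z < R0,
                 (R0 - z)^(1 / p - 1) + 0.0134 * (R0 - z)^(1 / p), 0)
  sig <- 0.012 * (R0 / 10)^0.935 * 10
  ks <- seq(-4 * sig, 4 * sig, by = dz)
  k <- dnorm(ks, 0, sig)
  k <- k / sum(k)
  D <- stats::convolve(base, rev(k), type = "open")
  nk <- length(k)
  D <- D[((nk - 1) / 2 + 1):(length(D) - (nk - 1) / 2)]
  list(z = z, D = D)
}

# Cached, scaled table: distal 80% at range_water; integral = E/rho per proton
.bragg_table_env <- new.env(parent = emptyenv())
.bragg_table <- function(beam) {
  key <- paste(beam$range_water, beam$bragg_kleeman_p, beam$energy, sep = "_")
  if (!is.null(.bragg_table_env[[key]])) return(.bragg_table_env[[key]])
  raw <- .bragg_curve_raw(beam$range_water, beam$bragg_kleeman_p)
  peak <- max(raw$D)
  # distal 80% crossing of the raw curve
  ipk <- which.max(raw$D)
  distal <- raw$D[ipk:length(raw$D)]
  zd <- raw$z[ipk:length(raw$z)]
  i <- which(distal[-1] < 0.8 * peak & distal[-length(distal)] >= 0.8 * peak)[1]
  d80 <- zd[i] + (0.8 * peak - distal[i]) * (zd[i + 1] - zd[i]) /
    (distal[i + 1] - distal[i])
  shift <- beam$range_water - d80   # move curve so d80 sits at range_water
  z <- raw$z + shift
  # prepend the entrance plateau back to z = 0
  if (shift > 0) {
    zpre <- seq(0, shift, by = 0.25)
    z <- c(zpre, z[z > shift + 1e-9])
    D <- c(rep(raw$D[1], length(zpre)), raw$D[raw$z + shift > shift + 1e-9])
  } else {
    keep <- z >= 0
    z <- z[keep]; D <- raw$D[keep]
  }
  # energy conservation: integral over depth = E / rho (Gy mm^3 per proton)
  e_joule <- beam$energy * 1.602176634e-13
  rho <- 1e-6  # kg/mm^3 for water
  integ <- sum((D[-1] + D[-length(D)]) / 2 * diff(z))
  D <- D * (e_joule / rho) / integ
  tab <- list(z = z, D = D, peak_depth = z[which.max(D)])
  .bragg_table_env[[key]] <- tab
  tab
}

#' Pristine Bragg depth-dose per proton
#'
#' Analytic Bortfeld-style pristine Bragg curve for the beam's single energy,
#' positioned so that the distal 80% fall-off lies at `beam$range_water`, and
#' scaled so that the depth integral equals the beam energy deposited per unit
#' mass column (E/rho, energy conservation). Values are Gy mm^2 per proton as
#' a function of water-equivalent depth.
#'
#' @param wet_depth water-equivalent depth, mm (vectorized, must be >= 0)
#' @param beam a [beam_model()]
#' @return dose in Gy mm^2 per proton at each depth
#' @export
bragg_depth_dose <- function(wet_depth, beam = beam_model()) {
  if (any(wet_depth < 0)) stop("wet_depth must be >= 0", call. = FALSE)
  tab <- .bragg_table(beam)
  out <- approx(tab$z, tab$D, xout = wet_depth, yleft = tab$D[1],
                yright = 0, rule = 2)$y
  out[wet_depth > max(tab$z)] <- 0
  out
}

#' Depth of the Bragg-peak maximum
#'
#' @param beam a [beam_model()]
#' @return water-equivalent depth of the pristine-peak maximum, mm
#' @export
bragg_peak_depth <- function(beam = beam_model()) {
  .bragg_table(beam)$peak_depth
}
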