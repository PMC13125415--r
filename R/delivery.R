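# ---------------------------------------------------------------------------
# Spot-delivery timeline, per-voxel Average Dose Rate (ADR), dose-rate-volume
# histograms and V40Gy/s.
# ---------------------------------------------------------------------------

#' Build the spot-delivery timeline
#'
#' Serpentine row-major order (rows of constant y scanned in alternating x
#' direction); dwell per spot is `max(min_spot_time, mu / mu_rate)`; travel
#' between consecutive spots is Euclidean distance / scan speed with the beam
#' off. Beam-switching time between fields is excluded.
#'
#' @param spotmap a `spot_map` whose spots all have `mu >= min_mu`
#' @param beam a [beam_model()]
#' @param scan_speed mm/s (may be `Inf` for instantaneous travel)
#' @return object of class `delivery_timeline`: data.frame `events` with
#'   columns `spot` (row index into `spotmap$spots`), `start`, `dwell`,
#'   `travel` (seconds; `travel` is the transit after this spot), plus
#'   `total_time`
#' @export
build_timeline <- function(spotmap, beam = beam_model(), scan_speed = 8000) {
  if (scan_speed <= 0) stop("scan_speed must be > 0", call. = FALSE)
  sp <- spotmap$spots
  if (any(sp$mu < beam$min_mu - 1e-9))
    stop("all spot MUs must be >= min_mu", call. = FALSE)
  ord <- order(sp$y, sp$x)
  rows <- split(ord, sp$y[ord])
  flip <- FALSE
  seqn <- integer(0)
  for (r in rows) {
    seqn <- c(seqn, if (flip) rev(r) else r)
    flip <- !flip
  }
  dwell <- pmax(beam$min_spot_time, sp$mu[seqn] / beam$mu_rate)
  nx <- length(seqn)
  travel <- c(if (nx > 1)
    sqrt(diff(sp$x[seqn])^2 + diff(sp$y[seqn])^2) / scan_speed else
      numeric(0), 0)
  travel[!is.finite(travel)] <- 0
  start <- cumsum(c(0, head(dwell + travel, -1)))
  ev <- data.frame(spot = seqn, start = start, dwell = dwell,
                   travel = travel)
  structure(list(events = ev, total_time = start[nx] + dwell[nx]),
            class = "delivery_timeline")
}

#' Per-voxel Average Dose Rate
#'
#' For each voxel, builds the piecewise-linear cumulative dose curve `d(t)`
#' (dose accrues uniformly during each spot's dwell in proportion to that
#' spot's contribution) and returns
#' `ADR = (D - 2 w) / (t1 - t0)` where `t0` is the first time
#' `d(t) = w`, `t1` the first time `d(t) = D - w`, and `w` the
#' `window_dose`. With `window_dose = 0` this is the total dose divided by
#' the span from first to last nonzero accrual.
#'
#' @param influence matrix (voxels x spots) of per-spot dose at each voxel,
#'   in the same spot order as `spotmap$spots`
#' @param timeline a [build_timeline()] result
#' @param window_dose Gy
#' @return numeric vector of ADR values, Gy/s; `NA` where the voxel dose is
#'   zero or `window_dose >= D/2`
#' @export
compute_adr <- function(influence, timeline, window_dose = 0) {
  if (window_dose < 0) stop("window_dose must be >= 0", call. = FALSE)
  ev <- timeline$events
  influence <- as.matrix(influence)
  # reorder columns into delivery order
  contrib <- influence[, ev$spot, drop = FALSE]
  D <- rowSums(contrib)
  n <- nrow(contrib)
  adr <- rep(NA_real_, n)
  t_on0 <- ev$start
  t_on1 <- ev$start + ev$dwell
  if (window_dose == 0) {
    pos <- contrib > 0
    anyd <- D > 0
    first <- apply(pos, 1, function(p) if (any(p)) which(p)[1] else NA)
    last <- apply(pos, 1, function(p) if (any(p)) tail(which(p), 1) else NA)
    span <- t_on1[last] - t_on0[first]
    one <- anyd & (first == last)
    adr[anyd] <- D[anyd] / span[anyd]
    return(adr)
  }
  # general window: per-voxel piecewise-linear cumulative curve
  for (i in seq_len(n)) {
    if (D[i] <= 0 || window_dose >= D[i] / 2) next
    ci <- contrib[i, ]
    act <- which(ci > 0)
    cum <- cumsum(ci[act])
    cum0 <- c(0, head(cum, -1))
    t_at <- function(dlev) {
      k <- which(cum >= dlev - 1e-15)[1]
      j <- act[k]
      frac <- (dlev - cum0[k]) / ci[j]
      t_on0[j] + frac * ev$dwell[j]
    }
    t0 <- t_at(window_dose)
    t1 <- t_at(D[i] - window_dose)
    adr[i] <- (D[i] - 2 * window_dose) / (t1 - t0)
  }
  adr
}

#' V40: FLASH dose-rate coverage
#'
#' Fraction (percent) of eligible (voxel, field) observations inside the ROI
#' whose ADR is at least `rate_threshold`. An observation is eligible when
#' that field's dose at the voxel exceeds `dose_threshold`. Fields are
#' pooled. Returns `NA` when no observation is eligible.
#'
#' @param adr_by_field list (one element per field) of per-voxel ADR vectors
#'   over the ROI voxels
#' @param dose_by_field list of per-voxel per-field dose vectors (same order)
#' @param dose_threshold Gy
#' @param rate_threshold Gy/s (default 40; comparison is inclusive `>=`)
#' @return percent
#' @export
v40 <- function(adr_by_field, dose_by_field, dose_threshold = 0,
                rate_threshold = 40) {
  if (!length(adr_by_field) || !length(adr_by_field[[1]]))
    stop("empty ROI", call. = FALSE)
  elig <- ok <- 0L
  for (f in seq_along(adr_by_field)) {
    e <- dose_by_field[[f]] > dose_threshold
    a <- adr_by_field[[f]]
    e <- e & !is.na(a)
    elig <- elig + sum(e)
    ok <- ok + sum(e & a >= rate_threshold)
  }
  if (elig == 0L) return(NA_real_)
  100 * ok / elig
}

#' Dose-rate-volume histogram (DRVH)
#'
#' Complementary cumulative distribution of ADR over the eligible pooled
#' (voxel, field) observations: `curve(r)` is the percent of observations
#' with ADR `>= r`. [v40()] equals the curve evaluated at 40 Gy/s.
#'
#' @inheritParams v40
#' @param rates dose-rate grid for the curve, Gy/s (default: data-driven)
#' @return data.frame with columns `rate` and `volume_pct` (non-increasing)
#' @export
drvh <- function(adr_by_field, dose_by_field, dose_threshold = 0,
                 rates = NULL) {
  if (!length(adr_by_field) || !length(adr_by_field[[1]]))
    stop("empty ROI", call. = FALSE)
  vals <- numeric(0)
  for (f in seq_along(adr_by_field)) {
    e <- dose_by_field[[f]] > dose_threshold & !is.na(adr_by_field[[f]])
    vals <- c(vals, adr_by_field[[f]][e])
  }
  if (!length(vals))
    return(data.frame(rate = numeric(0), volume_pct = numeric(0)))
  if (is.null(rates))
    rates <- sort(unique(c(0, vals, 40)))
  volume <- vapply(rates, function(r) 100 * mean(vals >= r), numeric(1))
  data.frame(rate = rates, volume_pct = volume)
}
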