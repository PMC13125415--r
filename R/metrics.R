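# ---------------------------------------------------------------------------
# Penumbra extraction, DVH, conformity index and summary dose metrics.
# ---------------------------------------------------------------------------

#' 80-20% penumbra of a lateral edge profile
#'
#' Normalizes the profile to its central-plateau value (mean of samples
#' within 5% of the value at the central position), locates the 80% and 20%
#' crossings on each lateral edge by linear interpolation between bracketing
#' samples, and returns the mean of the left-edge and right-edge 80-to-20
#' distances. The result is invariant to uniform scaling of the values and
#' to translation of the axis.
#'
#' For a non-monotone edge the outermost 20% and innermost 80% crossings are
#' used and a warning is emitted.
#'
#' @param x axis positions, mm (strictly increasing)
#' @param value profile values (>= 0)
#' @return penumbra, mm
#' @export
penumbra_80_20 <- function(x, value) {
  if (is.data.frame(x)) { value <- x$value; x <- x$x }
  if (any(diff(x) <= 0)) stop("positions must be strictly increasing",
                              call. = FALSE)
  if (any(value < 0)) stop("profile values must be >= 0", call. = FALSE)
  i0 <- which.min(abs(x - mean(range(x))))
  central <- value[i0]
  plateau <- mean(value[abs(value - central) <= 0.05 * central])
  if (!is.finite(plateau) || plateau <= 0)
    stop("no central plateau", call. = FALSE)
  v <- value / plateau
  edge <- function(xs, vs) {
    # vs starts at the plateau and falls outward along xs
    cross <- function(lev, outermost) {
      idx <- which(vs[-length(vs)] >= lev & vs[-1] < lev)
      if (!length(idx)) stop("no-penumbra: profile never crosses ",
                             lev * 100, "%", call. = FALSE)
      if (length(idx) > 1)
        warning("non-monotone edge; using ",
                if (outermost) "outermost" else "innermost", " crossing")
      i <- if (outermost) max(idx) else min(idx)
      xs[i] + (lev - vs[i]) * (xs[i + 1] - xs[i]) / (vs[i + 1] - vs[i])
    }
    x80 <- cross(0.8, outermost = FALSE)
    x20 <- cross(0.2, outermost = TRUE)
    x20 - x80
  }
  right <- edge(x[i0:length(x)], v[i0:length(v)])
  left <- edge(rev(-x[1:i0]), rev(v[1:i0]))
  (right + left) / 2
}

#' Cumulative dose-volume histogram
#'
#' @param dose dose values of the ROI voxels, Gy
#' @param bins dose grid for the curve (default: 0.1 Gy pitch over the range)
#' @return data.frame with columns `dose` and `volume_pct` (percent of ROI
#'   with dose >= the bin value; non-increasing)
#' @export
dvh <- function(dose, bins = NULL) {
  if (!length(dose)) stop("empty ROI", call. = FALSE)
  if (is.null(bins)) bins <- seq(0, max(dose) + 0.1, by = 0.1)
  data.frame(dose = bins,
             volume_pct = vapply(bins, function(d) 100 * mean(dose >= d),
                                 numeric(1)))
}

#' VxGy: percent of an ROI receiving at least a dose level
#'
#' @param dose ROI voxel doses, Gy
#' @param level Gy
#' @return percent
#' @export
v_gy <- function(dose, level) {
  if (!length(dose)) stop("empty ROI", call. = FALSE)
  100 * mean(dose >= level)
}

#' Summary dose statistics for an ROI
#'
#' @param dose ROI voxel doses, Gy
#' @return list with `dmax`, `dmean`
#' @export
dose_stats <- function(dose) {
  if (!length(dose)) stop("empty ROI", call. = FALSE)
  list(dmax = max(dose), dmean = mean(dose))
}

#' RTOG conformity index
#'
#' Ratio of the total volume receiving the prescription dose to the target
#' volume.
#'
#' @param dose full dose grid (array or vector)
#' @param target_mask logical mask of the same shape
#' @param rx prescription dose, Gy
#' @return CI (dimensionless)
#' @export
conformity_index <- function(dose, target_mask, rx) {
  if (rx <= 0) stop("rx must be > 0", call. = FALSE)
  nt <- sum(target_mask)
  if (nt == 0) stop("empty target", call. = FALSE)
  sum(dose >= rx) / nt
}
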