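# Shared lag-statistic machinery -------------------------------------------

#' Log-spaced lag grid
#'
#' Integer frame lags on an approximately log-spaced grid (default 30 per
#' decade, deduplicated), from 1 frame up to `max_frac` of the series length.
#'
#' @param n_frames number of frames available.
#' @param per_decade grid density.
#' @param max_frac largest lag as a fraction of the series length (keeps the
#'   time-origin average well populated).
#' @return increasing integer vector of frame lags.
#' @export
lag_grid <- function(n_frames, per_decade = 30, max_frac = 0.25) {
  max_lag <- max(1, floor((n_frames - 1) * max_frac))
  raw <- 10^(seq(0, log10(max_lag), by = 1 / per_decade))
  unique(pmin(max_lag, round(raw)))
}

new_lag_statistic <- function(lag, value, n, observable) {
  structure(data.frame(lag = lag, value = value, n = n),
            observable = observable,
            class = c("lag_statistic", "data.frame"))
}

#' @export
print.lag_statistic <- function(x, ...) {
  cat(sprintf("<lag_statistic: %s> %d lags in [%g, %g] tau\n",
              attr(x, "observable"), nrow(x), min(x$lag), max(x$lag)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
plot.lag_statistic <- function(x, ..., log = "xy") {
  graphics::plot(x$lag, x$value, log = log, xlab = "lag (tau)",
                 ylab = attr(x, "observable"), type = "b", ...)
  invisible(x)
}

# Displacement matrix over a lag: rows are pooled (time origin, rod) samples,
# columns the 3 (or k) Cartesian components stacked as [x1..xR, y1..yR, ...].
# X is an n_frames x R x k array.  Returns list(D, t0).
lag_displacements <- function(X, L, origin_stride = 1, max_origins = 1e4) {
  nf <- dim(X)[1]
  t0 <- seq.int(1L, nf - L, by = origin_stride)
  if (length(t0) > max_origins)
    t0 <- t0[seq.int(1L, length(t0), length.out = max_origins)]
  M <- matrix(X, nf)
  list(D = M[t0 + L, , drop = FALSE] - M[t0, , drop = FALSE], t0 = t0)
}

series_arrays <- function(series) {
  stopifnot(inherits(series, "rod_series"))
  series
}

#' Assemble a rod series from raw arrays
#'
#' Builds the container consumed by the analysis functions from centre-of-mass
#' (and optionally axis) arrays, e.g. from an external engine or an ideal
#' generator.
#'
#' @param times frame times (tau), uniformly spaced.
#' @param com n_frames x n_rods x 3 array of unwrapped centres of mass.
#' @param axis optional n_frames x n_rods x 3 array of unit major-axis
#'   vectors (sign-continuous).
#' @return a `rod_series`.
#' @export
rod_series <- function(times, com, axis = NULL) {
  stopifnot(length(dim(com)) == 3, dim(com)[3] == 3,
            length(times) == dim(com)[1])
  if (!is.null(axis)) stopifnot(identical(dim(axis), dim(com)))
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  structure(list(times = times, dt_frame = dt, com = com, axis = axis,
                 ree2 = NULL, gyration_eigs = NULL), class = "rod_series")
}

# Translational MSD ---------------------------------------------------------

#' Mean-square displacement
#'
#' MSD(t) = < |r(t0 + t) - r(t0)|^2 >, averaged over all rods and over time
#' origins on a stride (capped at `max_origins` origins per lag).
#'
#' @param series a `rod_series` (unwrapped centres of mass).
#' @param lags integer frame lags; `NULL` uses [lag_grid()].
#' @param origin_stride spacing of time origins (frames).
#' @param max_origins cap on the number of origins per lag.
#' @return a `lag_statistic` with `lag` (tau), `value` (sigma^2), `n` samples.
#' @export
msd <- function(series, lags = NULL, origin_stride = 1, max_origins = 1e4) {
  s <- series_arrays(series)
  nf <- dim(s$com)[1]; R <- dim(s$com)[2]
  if (is.null(lags)) lags <- lag_grid(nf)
  lags <- lags[lags < nf]
  out <- vapply(lags, function(L) {
    D <- lag_displacements(s$com, L, origin_stride, max_origins)$D
    r2 <- D[, 1:R, drop = FALSE]^2 + D[, R + 1:R, drop = FALSE]^2 +
          D[, 2 * R + 1:R, drop = FALSE]^2
    c(mean(r2), length(r2))
  }, numeric(2))
  new_lag_statistic(lags * s$dt_frame, out[1, ], out[2, ], "MSD")
}

#' Axis-decomposed mean-square displacement
#'
#' Projects each displacement r(t0+t) - r(t0) onto the rod's body frame taken
#' at the origin time t0: the major axis e_par(t0) and the two perpendicular
#' unit vectors e_perp1(t0), e_perp2(t0) (the frame is not re-tracked during
#' the interval). The perpendicular MSD is the average of the two
#' perpendicular components, so MSD_par + 2 MSD_perp = MSD sample by sample.
#'
#' @inheritParams msd
#' @return list of `lag_statistic`s: `total`, `parallel`, `perpendicular`
#'   (average of the two components, the curve conventionally plotted against
#'   the parallel MSD), `perp_plane` (their sum, the full in-plane squared
#'   displacement, the curve whose slope/4 gives D_perp), `perp1`, `perp2`.
#' @export
msd_decomposed <- function(series, lags = NULL, origin_stride = 1,
                           max_origins = 1e4) {
  s <- series_arrays(series)
  if (is.null(s$axis)) stop("msd_decomposed: series carries no axis data")
  nf <- dim(s$com)[1]; R <- dim(s$com)[2]
  if (is.null(lags)) lags <- lag_grid(nf)
  lags <- lags[lags < nf]
  A <- matrix(s$axis, nf)
  out <- vapply(lags, function(L) {
    ld <- lag_displacements(s$com, L, origin_stride, max_origins)
    D <- ld$D
    e0 <- A[ld$t0, , drop = FALSE]
    Dx <- D[, 1:R, drop = FALSE]; Dy <- D[, R + 1:R, drop = FALSE]
    Dz <- D[, 2 * R + 1:R, drop = FALSE]
    ex <- e0[, 1:R, drop = FALSE]; ey <- e0[, R + 1:R, drop = FALSE]
    ez <- e0[, 2 * R + 1:R, drop = FALSE]
    pf <- perpendicular_frame(cbind(as.vector(ex), as.vector(ey), as.vector(ez)))
    dim1 <- dim(ex)
    p_par <- Dx * ex + Dy * ey + Dz * ez
    p1 <- Dx * array(pf$e1[, 1], dim1) + Dy * array(pf$e1[, 2], dim1) +
          Dz * array(pf$e1[, 3], dim1)
    p2 <- Dx * array(pf$e2[, 1], dim1) + Dy * array(pf$e2[, 2], dim1) +
          Dz * array(pf$e2[, 3], dim1)
    c(mean(Dx^2 + Dy^2 + Dz^2), mean(p_par^2), mean(p1^2), mean(p2^2),
      length(p_par))
  }, numeric(5))
  lt <- lags * s$dt_frame
  list(total = new_lag_statistic(lt, out[1, ], out[5, ], "MSD"),
       parallel = new_lag_statistic(lt, out[2, ], out[5, ], "MSD_par"),
       perpendicular = new_lag_statistic(lt, (out[3, ] + out[4, ]) / 2,
                                         out[5, ], "MSD_perp"),
       perp_plane = new_lag_statistic(lt, out[3, ] + out[4, ],
                                      out[5, ], "MSD_perp_plane"),
       perp1 = new_lag_statistic(lt, out[3, ], out[5, ], "MSD_perp1"),
       perp2 = new_lag_statistic(lt, out[4, ], out[5, ], "MSD_perp2"))
}

#' Anisotropy parameter A(t)
#'
#' A(t) = 3 MSD_par(t) / MSD(t) - 1, bounded in [-1, 2]: 0 for isotropic
#' diffusion, 2 for motion purely along the major axis, -1 for motion
#' confined to the perpendicular plane.
#'
#' @param msd_par `lag_statistic` of the parallel MSD component.
#' @param msd_total `lag_statistic` of the total MSD on the same lag grid.
#' @return a `lag_statistic`; lags with zero total MSD are dropped.
#' @export
anisotropy <- function(msd_par, msd_total) {
  if (!isTRUE(all.equal(msd_par$lag, msd_total$lag)))
    stop("anisotropy: lag grids differ")
  keep <- msd_total$value > 0
  new_lag_statistic(msd_total$lag[keep],
                    3 * msd_par$value[keep] / msd_total$value[keep] - 1,
                    msd_total$n[keep], "A(t)")
}

#' Local anomalous-diffusion exponent
#'
#' alpha(t), the local slope of log MSD versus log lag, estimated by ordinary
#' least squares over a sliding window of `window_pts` consecutive grid
#' points and reported at the window-centre lag. alpha = 1 is normal
#' diffusion, alpha < 1 sub-diffusion, alpha = 2 ballistic motion.
#'
#' @param ls a `lag_statistic` (MSD or MSAD); non-positive values are
#'   excluded.
#' @param window_pts sliding-window length (grid points, >= 2).
#' @return a `lag_statistic` of exponents.
#' @export
anomalous_exponent <- function(ls, window_pts = 5) {
  stopifnot(window_pts >= 2)
  keep <- ls$value > 0 & ls$lag > 0
  lx <- log(ls$lag[keep]); ly <- log(ls$value[keep])
  m <- length(lx)
  if (m < window_pts) stop("anomalous_exponent: need at least window_pts usable lags")
  nw <- m - window_pts + 1
  alpha <- numeric(nw); centre <- numeric(nw)
  for (w in seq_len(nw)) {
    i <- w:(w + window_pts - 1)
    x <- lx[i] - mean(lx[i])
    alpha[w] <- sum(x * ly[i]) / sum(x^2)
    centre[w] <- exp(mean(lx[i]))
  }
  new_lag_statistic(centre, alpha, rep(window_pts, nw), "alpha")
}

# Diffusion-coefficient fits -------------------------------------------------

#' Fit a diffusion coefficient from an MSD curve
#'
#' Ordinary least-squares slope of MSD versus lag over a time window, divided
#' by 2d: D = lim MSD/(2 d t) with d = 3 for the total MSD, d = 1 for the
#' parallel component (MSD_par/2t) and d = 2 for the perpendicular component
#' (MSD_perp/4t). With `window = NULL` the window is chosen automatically as
#' the final decade of lags over which the local exponent exceeds 0.9 (falling
#' back to the final decade of the grid); the window used is recorded in the
#' returned object.
#'
#' @param ls a `lag_statistic`.
#' @param window `c(t_lo, t_hi)` in tau, or `NULL` for automatic selection.
#' @param d dimensionality of the motion (1, 2 or 3).
#' @return object of class `diffusion_fit` with fields `D`, `stderr`,
#'   `window`, `d`, `n_points`.
#' @export
fit_D <- function(ls, window = NULL, d = 3) {
  stopifnot(d %in% 1:3)
  if (is.null(window)) window <- auto_fit_window(ls)
  sel <- ls$lag >= window[1] & ls$lag <= window[2]
  if (sum(sel) < 3) stop("fit_D: fewer than 3 lags in the fit window")
  fit <- lm(value ~ lag, data = as.data.frame(ls)[sel, ])
  sl <- suppressWarnings(summary(fit))$coefficients["lag", ]
  structure(list(D = unname(sl["Estimate"]) / (2 * d),
                 stderr = unname(sl["Std. Error"]) / (2 * d),
                 window = window, d = d, n_points = sum(sel),
                 observable = attr(ls, "observable")),
            class = "diffusion_fit")
}

auto_fit_window <- function(ls) {
  keep <- ls$value > 0
  lag <- ls$lag[keep]
  if (length(lag) < 8) return(range(lag))
  al <- tryCatch(anomalous_exponent(ls), error = function(e) NULL)
  hi <- max(lag)
  if (!is.null(al) && any(al$value > 0.9)) hi <- max(al$lag[al$value > 0.9])
  c(hi / 10, hi)
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %s: D = %.4g +/- %.2g (d = %d, window [%g, %g] tau, %d pts)\n",
              x$observable, x$D, x$stderr, x$d, x$window[1], x$window[2],
              x$n_points))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) c(D = object$D)

# Non-Gaussian parameter -----------------------------------------------------

#' Non-Gaussian parameter alpha2(t)
#'
#' alpha2(t) = <r^4(t)> / ((1 + 2/d) <r^2(t)>^2) - 1, where r(t) is the
#' d-dimensional displacement over lag t: the full 3D displacement
#' (`component = "total"`, d = 3), its projection on the origin-time major
#' axis (`"parallel"`, d = 1), or the in-plane displacement perpendicular to
#' it (`"perpendicular"`, d = 2). Zero for Gaussian displacements; positive
#' values flag heterogeneous dynamics.
#'
#' @inheritParams msd
#' @param component which displacement component to analyse.
#' @param d override the dimensionality (defaults to 3/1/2 by component).
#' @return a `lag_statistic`; lags with vanishing second moment are dropped.
#' @export
non_gaussian <- function(series, component = c("total", "parallel", "perpendicular"),
                         lags = NULL, origin_stride = 1, max_origins = 1e4,
                         d = NULL) {
  component <- match.arg(component)
  s <- series_arrays(series)
  if (component != "total" && is.null(s$axis))
    stop("non_gaussian: series carries no axis data")
  if (is.null(d)) d <- switch(component, total = 3, parallel = 1, perpendicular = 2)
  nf <- dim(s$com)[1]; R <- dim(s$com)[2]
  if (is.null(lags)) lags <- lag_grid(nf)
  lags <- lags[lags < nf]
  if (component != "total") A <- matrix(s$axis, nf)
  out <- vapply(lags, function(L) {
    ld <- lag_displacements(s$com, L, origin_stride, max_origins)
    D <- ld$D
    Dx <- D[, 1:R, drop = FALSE]; Dy <- D[, R + 1:R, drop = FALSE]
    Dz <- D[, 2 * R + 1:R, drop = FALSE]
    r2 <- if (component == "total") {
      Dx^2 + Dy^2 + Dz^2
    } else {
      e0 <- A[ld$t0, , drop = FALSE]
      ex <- e0[, 1:R, drop = FALSE]; ey <- e0[, R + 1:R, drop = FALSE]
      ez <- e0[, 2 * R + 1:R, drop = FALSE]
      p_par <- Dx * ex + Dy * ey + Dz * ez
      if (component == "parallel") p_par^2
      else (Dx^2 + Dy^2 + Dz^2) - p_par^2
    }
    m2 <- mean(r2)
    c(m2, mean(r2^2), length(r2))
  }, numeric(3))
  keep <- out[1, ] > 0
  a2 <- out[2, keep] / ((1 + 2 / d) * out[1, keep]^2) - 1
  new_lag_statistic(lags[keep] * s$dt_frame, a2, out[3, keep],
                    paste0("alpha2_", component))
}

# Power-law scaling fits -----------------------------------------------------

#' Fit a power-law scaling exponent
#'
#' Least-squares fit of log y on log x, giving y ~ prefactor * x^exponent.
#' Used for the D ~ N^l and Drot ~ ka^l scaling laws.
#'
#' @param x,y positive numeric vectors (>= 2 points).
#' @return object of class `scaling_fit` with `exponent`, `prefactor`, `r2`
#'   and the `points` used.
#' @export
fit_scaling <- function(x, y) {
  if (length(x) < 2 || length(x) != length(y)) stop("fit_scaling: need >= 2 (x, y) pairs")
  if (any(x <= 0) || any(y <= 0)) stop("fit_scaling: x and y must be positive")
  fit <- lm(log(y) ~ log(x))
  structure(list(exponent = unname(coef(fit)[2]),
                 prefactor = exp(unname(coef(fit)[1])),
                 r2 = suppressWarnings(summary(fit))$r.squared,
                 points = data.frame(x = x, y = y)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> y = %.4g * x^%.3f (r^2 = %.4f, %d points)\n",
              x$prefactor, x$exponent, x$r2, nrow(x$points)))
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...)
  c(exponent = object$exponent, prefactor = object$prefactor)
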