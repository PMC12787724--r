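#' Integrated angular-displacement vectors
#'
#' From the sign-continuous major-axis series, forms the per-step rotation
#' vector: its magnitude is acos(e(t+dt) . e(t)) (after flipping the later
#' axis when the dot product is negative -- rods are apolar) and its direction
#' is the unit cross product e(t+dt) x e(t), the instantaneous rotation axis.
#' The cumulative sum phi(t) = sum of increments is the rotational analogue of
#' an unwrapped coordinate; phi(0) = 0.
#'
#' The save stride must resolve the rotation: the function warns when the
#' median per-step increment exceeds 0.2 rad and refuses to proceed when the
#' 99th percentile exceeds pi/4 (the acos map aliases larger steps).
#'
#' @param series a `rod_series` with an `axis` component.
#' @return object of class `angular_series`: `times`, `dt_frame`, and `phi`
#'   (n_frames x n_rods x 3 array of cumulative rotation vectors, radians).
#' @export
angular_increments <- function(series) {
  s <- series
  stopifnot(inherits(s, "rod_series"))
  if (is.null(s$axis)) stop("angular_increments: series carries no axis data")
  ax <- s$axis
  nf <- dim(ax)[1]; R <- dim(ax)[2]
  nrm <- sqrt(ax[, , 1]^2 + ax[, , 2]^2 + ax[, , 3]^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("angular_increments: axes must be unit vectors")
  A1 <- matrix(ax[, , 1], nf, R); A2 <- matrix(ax[, , 2], nf, R)
  A3 <- matrix(ax[, , 3], nf, R)
  i0 <- seq_len(nf - 1); i1 <- i0 + 1
  a1 <- A1[i0, , drop = FALSE]; a2 <- A2[i0, , drop = FALSE]
  a3 <- A3[i0, , drop = FALSE]                     # e(t)
  b1 <- A1[i1, , drop = FALSE]; b2 <- A2[i1, , drop = FALSE]
  b3 <- A3[i1, , drop = FALSE]                     # e(t+dt)
  dt_dot <- a1 * b1 + a2 * b2 + a3 * b3
  sgn <- ifelse(dt_dot < 0, -1, 1)                 # apolar: acute-angle convention
  ang <- acos(pmin(1, abs(dt_dot)))
  if (nf > 1) {
    q <- stats::quantile(ang, c(0.5, 0.99), names = FALSE)
    if (q[2] > pi / 4)
      stop("angular_increments: 99th-percentile step rotation ",
           signif(q[2], 3), " rad exceeds pi/4; save stride too coarse")
    if (q[1] > 0.2)
      warning("angular_increments: median step rotation ", signif(q[1], 3),
              " rad exceeds 0.2 rad; consider a finer save stride")
  }
  # cross product e(t+dt) x e(t), with the later axis sign-flipped when needed
  cx <- sgn * (b2 * a3 - b3 * a2)
  cy <- sgn * (b3 * a1 - b1 * a3)
  cz <- sgn * (b1 * a2 - b2 * a1)
  cn <- sqrt(cx^2 + cy^2 + cz^2)
  ok <- cn > 1e-14                  # parallel axes rotate by zero
  scl <- ifelse(ok, ang / cn, 0)
  phi <- array(0, dim(ax))
  phi[i1, , 1] <- apply(scl * cx, 2, cumsum)
  phi[i1, , 2] <- apply(scl * cy, 2, cumsum)
  phi[i1, , 3] <- apply(scl * cz, 2, cumsum)
  structure(list(times = s$times, dt_frame = s$dt_frame, phi = phi),
            class = "angular_series")
}

#' @export
print.angular_series <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("<angular_series> %d frames x %d rods, dt_frame = %g tau\n",
              d[1], d[2], x$dt_frame))
  invisible(x)
}

#' Mean-square angular displacement
#'
#' MSAD(t) = < |phi(t0 + t) - phi(t0)|^2 >, averaged over rods and time
#' origins; the rotational analogue of the MSD, computed on the cumulative
#' rotation vectors from [angular_increments()].
#'
#' @param ang an `angular_series`.
#' @inheritParams msd
#' @return a `lag_statistic` (rad^2).
#' @export
msad <- function(ang, lags = NULL, origin_stride = 1, max_origins = 1e4) {
  stopifnot(inherits(ang, "angular_series"))
  nf <- dim(ang$phi)[1]; R <- dim(ang$phi)[2]
  if (is.null(lags)) lags <- lag_grid(nf)
  lags <- lags[lags < nf]
  out <- vapply(lags, function(L) {
    D <- lag_displacements(ang$phi, L, origin_stride, max_origins)$D
    r2 <- D[, 1:R, drop = FALSE]^2 + D[, R + 1:R, drop = FALSE]^2 +
          D[, 2 * R + 1:R, drop = FALSE]^2
    c(mean(r2), length(r2))
  }, numeric(2))
  new_lag_statistic(lags * ang$dt_frame, out[1, ], out[2, ], "MSAD")
}

#' Fit the rotational diffusion coefficient
#'
#' Drot = lim MSAD/(4t): least-squares slope of the MSAD over the window,
#' divided by 4 (a rod has two rotational degrees of freedom).
#'
#' @param msad_ls a `lag_statistic` from [msad()].
#' @param window `c(t_lo, t_hi)` in tau, or `NULL` for the automatic window
#'   (see [fit_D()]).
#' @return a `diffusion_fit` (D slot holds Drot, rad^2/tau).
#' @export
fit_Drot <- function(msad_ls, window = NULL) fit_D(msad_ls, window, d = 2)

#' Local rotational anomalous exponent
#'
#' alpha_rot(t), the local log-log slope of the MSAD (MSAD ~ t^alpha_rot);
#' identical estimator to [anomalous_exponent()].
#'
#' @inheritParams anomalous_exponent
#' @return a `lag_statistic`.
#' @export
rotational_alpha <- function(ls, window_pts = 5) anomalous_exponent(ls, window_pts)

#' Rotational non-Gaussian parameter
#'
#' alpha2_rot(t) = 3 <dphi^4(t)> / (5 <dphi^2(t)>^2) - 1, with dphi(t) the
#' magnitude of the net rotation-vector difference |phi(t0+t) - phi(t0)|.
#' The 3/5 coefficient is the 3D Gaussian normalization of the rotation
#' vector; alpha2_rot = 0 for Gaussian rotational increments.
#'
#' @inheritParams msad
#' @return a `lag_statistic`; lags with vanishing second moment are dropped.
#' @export
rotational_non_gaussian <- function(ang, lags = NULL, origin_stride = 1,
                                    max_origins = 1e4) {
  stopifnot(inherits(ang, "angular_series"))
  nf <- dim(ang$phi)[1]; R <- dim(ang$phi)[2]
  if (is.null(lags)) lags <- lag_grid(nf)
  lags <- lags[lags < nf]
  out <- vapply(lags, function(L) {
    D <- lag_displacements(ang$phi, L, origin_stride, max_origins)$D
    r2 <- D[, 1:R, drop = FALSE]^2 + D[, R + 1:R, drop = FALSE]^2 +
          D[, 2 * R + 1:R, drop = FALSE]^2
    c(mean(r2), mean(r2^2), length(r2))
  }, numeric(3))
  keep <- out[1, ] > 0
  a2 <- 3 * out[2, keep] / (5 * out[1, keep]^2) - 1
  new_lag_statistic(lags[keep] * ang$dt_frame, a2, out[3, keep], "alpha2_rot")
}
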