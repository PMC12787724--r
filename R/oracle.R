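#' Configuration for the ideal rigid-rod Brownian generator
#'
#' Ground-truth generator of rigid-rod trajectories with prescribed body-frame
#' translational diffusivities and rotational diffusivity, used to validate
#' the whole analysis stack against known inputs.
#'
#' @param n_rods number of independent rods.
#' @param n_frames frames per rod.
#' @param dt_frame frame spacing (tau); keep `D_rot * dt_frame < 0.01` so the
#'   small-angle orientation update is valid.
#' @param D_par,D_perp translational diffusivities along / perpendicular to
#'   the axis (sigma^2/tau).
#' @param D_rot rotational diffusivity (rad^2/tau).
#' @param seed integer seed.
#' @return object of class `oracle_config`.
#' @export
oracle_config <- function(n_rods = 100, n_frames = 1000, dt_frame = 0.1,
                          D_par = 0.4, D_perp = 0.1, D_rot = 0.01, seed = 1) {
  stopifnot(D_par >= 0, D_perp >= 0, D_rot >= 0, dt_frame > 0,
            n_rods >= 1, n_frames >= 1)
  structure(list(n_rods = as.integer(n_rods), n_frames = as.integer(n_frames),
                 dt_frame = dt_frame, D_par = D_par, D_perp = D_perp,
                 D_rot = D_rot, seed = as.integer(seed)),
            class = "oracle_config")
}

#' Generate ideal rigid-rod Brownian trajectories
#'
#' Per frame, each rod's orientation is rotated by Gaussian angular increments
#' of variance 2 D_rot dt about two axes perpendicular to the current major
#' axis (exact Rodrigues rotation, so the axis stays unit-norm without bias),
#' and its centre of mass is displaced by Gaussian steps of variance
#' 2 D_par dt along the axis and 2 D_perp dt along each perpendicular
#' direction. Initial orientations are uniform on the sphere.
#'
#' The output is a [rod_series()], so oracle data and MD data feed the
#' analysis stack identically.
#'
#' @param cfg an [oracle_config()].
#' @return a `rod_series` with `com` and `axis` arrays.
#' @export
generate_rod_oracle <- function(cfg) {
  stopifnot(inherits(cfg, "oracle_config"))
  R <- cfg$n_rods; nf <- cfg$n_frames; dt <- cfg$dt_frame
  com <- array(0, c(nf, R, 3))
  axis <- array(0, c(nf, R, 3))
  s_par <- sqrt(2 * cfg$D_par * dt)
  s_perp <- sqrt(2 * cfg$D_perp * dt)
  s_rot <- sqrt(2 * cfg$D_rot * dt)
  with_seed(cfg$seed, {
    e <- matrix(rnorm(3 * R), R, 3)
    e <- e / sqrt(rowSums(e^2))
    x <- matrix(0, R, 3)
    axis[1, , ] <- e
    for (f in seq_len(nf)[-1]) {
      pf <- perpendicular_frame(e)
      # translation in the body frame of the *current* orientation
      if (s_par > 0 || s_perp > 0) {
        dp <- rnorm(R, sd = s_par)
        d1 <- rnorm(R, sd = s_perp)
        d2 <- rnorm(R, sd = s_perp)
        x <- x + dp * e + d1 * pf$e1 + d2 * pf$e2
      }
      # rotation: Gaussian angular increments about the two perpendicular axes
      if (s_rot > 0) {
        g1 <- rnorm(R, sd = s_rot)
        g2 <- rnorm(R, sd = s_rot)
        w <- g1 * pf$e1 + g2 * pf$e2          # rotation vector
        th <- sqrt(rowSums(w^2))
        ok <- th > 1e-300
        u <- w / ifelse(th > 0, th, 1)
        # Rodrigues: e' = e cos th + (u x e) sin th + u (u.e)(1 - cos th);
        # u is perpendicular to e here, so the last term vanishes
        uxe <- cbind(u[, 2] * e[, 3] - u[, 3] * e[, 2],
                     u[, 3] * e[, 1] - u[, 1] * e[, 3],
                     u[, 1] * e[, 2] - u[, 2] * e[, 1])
        enew <- e * cos(th) + uxe * sin(th)
        e <- ifelse(matrix(ok, R, 3), enew, e)
        e <- e / sqrt(rowSums(e^2))
      }
      com[f, , ] <- x
      axis[f, , ] <- e
    }
  })
  rod_series(times = (seq_len(nf) - 1) * dt, com = com, axis = axis)
}
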