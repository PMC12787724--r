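# axis series rotating uniformly about z at omega rad/frame
uniform_rotation_series <- function(omega, nf = 200, R = 2) {
  ax <- array(0, c(nf, R, 3))
  t <- seq_len(nf) - 1
  ax[, , 1] <- cos(omega * t)
  ax[, , 2] <- sin(omega * t)
  rod_series(t, com = array(0, c(nf, R, 3)), axis = ax)
}

test_that("angular increments of simple motions are exact", {
  # constant axis: phi identically zero
  ser <- uniform_rotation_series(0)
  ang <- angular_increments(ser)
  expect_true(all(ang$phi == 0))
  # uniform rotation: |phi(t)| = omega t, direction along -z (e(t+dt) x e(t))
  omega <- 0.05
  ang <- angular_increments(uniform_rotation_series(omega))
  mag <- sqrt(ang$phi[, 1, 1]^2 + ang$phi[, 1, 2]^2 + ang$phi[, 1, 3]^2)
  expect_equal(mag, omega * (seq_along(mag) - 1), tolerance = 1e-10)
  expect_equal(abs(ang$phi[10, 1, 3]), omega * 9, tolerance = 1e-10)
  expect_equal(ang$phi[10, 1, 1:2], c(0, 0), tolerance = 1e-12)
  expect_error(angular_increments(
    rod_series(1:3, array(0, c(3, 1, 3)),
               axis = array(2, c(3, 1, 3)))), "unit")
})

test_that("increments are invariant under apolar axis sign flips", {
  oc <- oracle_config(n_rods = 5, n_frames = 300, dt_frame = 0.1,
                      D_par = 0, D_perp = 0, D_rot = 0.02, seed = 61)
  ser <- generate_rod_oracle(oc)
  flipped <- ser
  set.seed(62)
  for (r in 1:5) {   # flip the sign of random tail segments
    f0 <- sample(50:250, 1)
    flipped$axis[f0:300, r, ] <- -flipped$axis[f0:300, r, ]
  }
  a1 <- angular_increments(ser)
  a2 <- angular_increments(flipped)
  expect_equal(a2$phi, a1$phi, tolerance = 1e-10)
})

test_that("MSAD of uniform rotation is exactly quadratic", {
  omega <- 0.04
  ang <- angular_increments(uniform_rotation_series(omega))
  ms <- msad(ang, lags = c(1, 5, 20, 40))
  expect_equal(ms$value, (omega * ms$lag)^2, tolerance = 1e-10)
  al <- rotational_alpha(msad(ang))
  expect_equal(al$value, rep(2, nrow(al)), tolerance = 1e-8)
  # zero rotation: MSAD identically zero
  expect_true(all(msad(angular_increments(uniform_rotation_series(0)))$value == 0))
})

test_that("rotational diffusion oracle is recovered by MSAD/4t", {
  oc <- oracle_config(n_rods = 300, n_frames = 2000, dt_frame = 0.1,
                      D_par = 0, D_perp = 0, D_rot = 0.01, seed = 63)
  ser <- generate_rod_oracle(oc)
  ms <- msad(angular_increments(ser), lags = 1:20, origin_stride = 3)
  fit <- fit_Drot(ms, window = c(0.1, 1))
  expect_equal(fit$D, 0.01, tolerance = 0.05)
})

test_that("Drot fit contracts hold", {
  lag <- seq(1, 40)
  expect_equal(fit_Drot(make_ls(lag, 4 * 0.02 * lag), c(1, 40))$D, 0.02)
  expect_error(fit_Drot(make_ls(lag, lag), c(100, 200)), "fewer than 3")
  # synthetic MSAD power law: alpha_rot exact
  al <- rotational_alpha(make_ls(10^seq(0, 2, 0.1), (10^seq(0, 2, 0.1))^0.8))
  expect_equal(al$value, rep(0.8, nrow(al)), tolerance = 1e-10)
})

test_that("rotational non-Gaussian parameter matches moment oracles", {
  nf <- 2001; R <- 60
  set.seed(64)
  # Gaussian 3D rotation-vector increments: alpha2_rot ~ 0
  phi <- array(0, c(nf, R, 3))
  phi[-1, , ] <- apply(array(rnorm((nf - 1) * R * 3, sd = 0.05),
                             c(nf - 1, R, 3)), c(2, 3), cumsum)
  ang <- structure(list(times = seq_len(nf) - 1, dt_frame = 1, phi = phi),
                   class = "angular_series")
  a2 <- rotational_non_gaussian(ang, lags = c(1, 4), origin_stride = 2)
  expect_lt(max(abs(a2$value)), 0.05)
  # fixed-magnitude increments: 3/5 - 1 = -0.4 at the one-step lag
  u <- matrix(rnorm(3 * (nf - 1) * R), ncol = 3)
  u <- 0.1 * u / sqrt(rowSums(u^2))
  phi2 <- array(0, c(nf, R, 3))
  phi2[-1, , ] <- apply(array(u, c(nf - 1, R, 3)), c(2, 3), cumsum)
  ang2 <- structure(list(times = seq_len(nf) - 1, dt_frame = 1, phi = phi2),
                    class = "angular_series")
  a2f <- rotational_non_gaussian(ang2, lags = 1)
  expect_equal(a2f$value, -0.4, tolerance = 1e-10)
  # two-population (fast/slow) rotation: positive alpha2_rot
  oc_f <- oracle_config(n_rods = 50, n_frames = 500, dt_frame = 0.1,
                        D_par = 0, D_perp = 0, D_rot = 0.1, seed = 65)
  oc_s <- oracle_config(n_rods = 50, n_frames = 500, dt_frame = 0.1,
                        D_par = 0, D_perp = 0, D_rot = 0.001, seed = 66)
  mix_axis <- array(0, c(500, 100, 3))
  mix_axis[, 1:50, ] <- generate_rod_oracle(oc_f)$axis
  mix_axis[, 51:100, ] <- generate_rod_oracle(oc_s)$axis
  ser <- rod_series((0:499) * 0.1, array(0, c(500, 100, 3)), axis = mix_axis)
  a2mix <- rotational_non_gaussian(angular_increments(ser), lags = c(5, 20))
  expect_gt(min(a2mix$value), 0.2)
})

test_that("aliased rotation strides are refused", {
  # ~60 degrees per frame: acos aliasing territory
  expect_error(angular_increments(uniform_rotation_series(1.05)),
               "pi/4")
  expect_warning(angular_increments(uniform_rotation_series(0.3)),
                 "0.2 rad")
})
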