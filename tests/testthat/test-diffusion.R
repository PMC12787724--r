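static_series <- function(n_rods = 3, n_frames = 50) {
  com <- array(rep(seq_len(n_rods), each = n_frames), c(n_frames, n_rods, 3))
  rod_series(seq_len(n_frames) - 1, com)
}

test_that("MSD of limiting motions is exact", {
  expect_true(all(msd(static_series())$value == 0))
  # ballistic drift r = v t gives MSD = v^2 t^2 at every lag
  v <- c(0.3, -0.2, 0.1)
  nf <- 100
  com <- array(0, c(nf, 2, 3))
  for (k in 1:3) com[, , k] <- outer((seq_len(nf) - 1), c(1, 1)) * v[k]
  m <- msd(rod_series(seq_len(nf) - 1, com))
  expect_equal(m$value, sum(v^2) * m$lag^2, tolerance = 1e-12)
  # lags beyond the series are dropped, not padded
  expect_true(all(msd(static_series(n_frames = 10), lags = c(2, 50))$lag < 10))
})

test_that("MSD slope/6 recovers D for Brownian walkers", {
  ser <- brownian_series(1000, 500, D = 0.5, seed = 21)
  fit <- fit_D(msd(ser, origin_stride = 3), window = c(20, 100), d = 3)
  expect_equal(fit$D, 0.5, tolerance = 0.05)
})

test_that("axis decomposition is exact per sample and recovers anisotropy", {
  # exact orthonormal identity on arbitrary trajectories
  oc <- oracle_config(n_rods = 20, n_frames = 300, dt_frame = 0.05,
                      D_par = 0.3, D_perp = 0.05, D_rot = 0.05, seed = 31)
  ser <- generate_rod_oracle(oc)
  dec <- msd_decomposed(ser)
  expect_equal(dec$parallel$value + dec$perp1$value + dec$perp2$value,
               dec$total$value, tolerance = 1e-10)
  expect_equal(dec$perp_plane$value, dec$perp1$value + dec$perp2$value,
               tolerance = 1e-12)
  # purely axial displacement: perpendicular components vanish
  oc2 <- oracle_config(n_rods = 10, n_frames = 200, dt_frame = 0.05,
                       D_par = 0.3, D_perp = 0, D_rot = 0, seed = 32)
  dec2 <- msd_decomposed(generate_rod_oracle(oc2))
  expect_lt(max(dec2$perp_plane$value), 1e-20)
  # body-frame diffusivity recovery (frozen axes)
  oc3 <- oracle_config(n_rods = 400, n_frames = 3000, dt_frame = 0.05,
                       D_par = 0.4, D_perp = 0.1, D_rot = 0, seed = 33)
  dec3 <- msd_decomposed(generate_rod_oracle(oc3), lags = 1:20,
                         origin_stride = 3)
  expect_equal(fit_D(dec3$parallel, c(0.05, 1), d = 1)$D, 0.4, tolerance = 0.05)
  expect_equal(fit_D(dec3$perp_plane, c(0.05, 1), d = 2)$D, 0.1, tolerance = 0.05)
})

test_that("anisotropy parameter hits its limiting values", {
  # axial-only motion: A = 2 identically
  oc <- oracle_config(n_rods = 10, n_frames = 200, dt_frame = 0.05,
                      D_par = 0.3, D_perp = 0, D_rot = 0, seed = 41)
  dec <- msd_decomposed(generate_rod_oracle(oc))
  A <- anisotropy(dec$parallel, dec$total)
  expect_equal(A$value, rep(2, nrow(A)), tolerance = 1e-10)
  # isotropic motion: A = 0 within statistical error
  oc2 <- oracle_config(n_rods = 400, n_frames = 1000, dt_frame = 0.05,
                       D_par = 0.2, D_perp = 0.2, D_rot = 0.02, seed = 42)
  dec2 <- msd_decomposed(generate_rod_oracle(oc2), origin_stride = 2)
  A2 <- anisotropy(dec2$parallel, dec2$total)
  expect_lt(max(abs(A2$value)), 0.06)
  # perpendicular-only motion: A = -1
  oc3 <- oracle_config(n_rods = 10, n_frames = 200, dt_frame = 0.05,
                       D_par = 0, D_perp = 0.2, D_rot = 0, seed = 43)
  dec3 <- msd_decomposed(generate_rod_oracle(oc3))
  A3 <- anisotropy(dec3$parallel, dec3$total)
  expect_equal(A3$value, rep(-1, nrow(A3)), tolerance = 1e-10)
  expect_true(all(A$value <= 2 + 1e-9 & A3$value >= -1 - 1e-9))
})

test_that("local log-log slope estimator is exact on power laws", {
  lag <- 10^seq(-1, 2, by = 0.1)
  for (a in c(1, 2, 0.65)) {
    al <- anomalous_exponent(make_ls(lag, 3 * lag^a))
    expect_equal(al$value, rep(a, nrow(al)), tolerance = 1e-10)
  }
  expect_error(anomalous_exponent(make_ls(lag[1:3], lag[1:3])), "window_pts")
})

test_that("diffusion-coefficient fits divide the slope by 2d", {
  lag <- seq(1, 50)
  expect_equal(fit_D(make_ls(lag, 6 * 0.25 * lag), c(1, 50), d = 3)$D, 0.25)
  expect_equal(fit_D(make_ls(lag, 4 * 0.1 * lag), c(1, 50), d = 2)$D, 0.1)
  expect_equal(fit_D(make_ls(lag, 2 * 0.7 * lag), c(1, 50), d = 1)$D, 0.7)
  expect_error(fit_D(make_ls(lag, lag), c(100, 200)), "fewer than 3")
  # automatic window is recorded and lies inside the lag range
  fit <- fit_D(make_ls(lag, 6 * lag + 2))
  expect_true(fit$window[1] >= 1 && fit$window[2] <= 50)
})

test_that("non-Gaussian parameter matches moment oracles", {
  nf <- 2001; R <- 100
  # Gaussian steps: alpha2 consistent with 0 at the one-step lag
  set.seed(51)
  com <- array(0, c(nf, R, 3))
  com[-1, , ] <- apply(array(rnorm((nf - 1) * R * 3), c(nf - 1, R, 3)),
                       c(2, 3), cumsum)
  ser <- rod_series(seq_len(nf) - 1, com)
  a2 <- non_gaussian(ser, "total", lags = c(1, 2, 5), origin_stride = 2)
  expect_lt(max(abs(a2$value)), 0.05)     # ~1e5 pooled samples per lag
  # fixed-magnitude random-direction steps: alpha2(1) = 1/(1+2/3) - 1 = -0.4
  u <- matrix(rnorm(3 * R * (nf - 1)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  com2 <- array(0, c(nf, R, 3))
  com2[-1, , ] <- apply(array(u, c(nf - 1, R, 3)), c(2, 3), cumsum)
  ser2 <- rod_series(seq_len(nf) - 1, com2)
  a2f <- non_gaussian(ser2, "total", lags = 1)
  expect_equal(a2f$value, -0.4, tolerance = 1e-10)
  # 50/50 mixture of 1d Gaussian widths (1, 9): alpha2 = 123/75 - 1 = 0.64
  sd_mix <- sample(c(1, 3), (nf - 1) * R, replace = TRUE)
  ax <- array(0, c(nf, R, 3)); ax[, , 1] <- 1   # axis fixed along x
  com3 <- array(0, c(nf, R, 3))
  com3[-1, , 1] <- apply(matrix(rnorm((nf - 1) * R, sd = sd_mix), nf - 1, R),
                         2, cumsum)
  ser3 <- rod_series(seq_len(nf) - 1, com3, axis = ax)
  a2m <- non_gaussian(ser3, "parallel", lags = 1)
  mix_expected <- (3 * (0.5 * 1 + 0.5 * 81)) / (3 * (0.5 * 1 + 0.5 * 9)^2) - 1
  expect_equal(mix_expected, 0.64)        # analytic mixture moments
  expect_equal(a2m$value, 0.64, tolerance = 0.05)
})

test_that("perpendicular alpha2 uses the d = 2 normalization", {
  nf <- 2001; R <- 50
  set.seed(52)
  ax <- array(0, c(nf, R, 3)); ax[, , 1] <- 1
  com <- array(0, c(nf, R, 3))
  # Gaussian in-plane steps (y, z): alpha2_perp ~ 0
  com[-1, , 2] <- apply(matrix(rnorm((nf - 1) * R), nf - 1, R), 2, cumsum)
  com[-1, , 3] <- apply(matrix(rnorm((nf - 1) * R), nf - 1, R), 2, cumsum)
  ser <- rod_series(seq_len(nf) - 1, com, axis = ax)
  a2 <- non_gaussian(ser, "perpendicular", lags = c(1, 3))
  expect_lt(max(abs(a2$value)), 0.05)
  # fixed-magnitude in-plane steps: <r^4> = <r^2>^2, alpha2 = 1/2 - 1 = -0.5
  th <- runif((nf - 1) * R) * 2 * pi
  com2 <- array(0, c(nf, R, 3))
  com2[-1, , 2] <- apply(matrix(cos(th), nf - 1, R), 2, cumsum)
  com2[-1, , 3] <- apply(matrix(sin(th), nf - 1, R), 2, cumsum)
  ser2 <- rod_series(seq_len(nf) - 1, com2, axis = ax)
  a2f <- non_gaussian(ser2, "perpendicular", lags = 1)
  expect_equal(a2f$value, -0.5, tolerance = 1e-10)
})

test_that("power-law scaling fits recover exponents", {
  x <- c(10, 15, 20, 25)
  fit <- fit_scaling(x, 7 * x^(-1.5))
  expect_equal(fit$exponent, -1.5, tolerance = 1e-12)
  expect_equal(fit$prefactor, 7, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  # two points: exact interpolation slope
  fit2 <- fit_scaling(c(2, 8), c(5, 40))
  expect_equal(fit2$exponent, log(8) / log(4), tolerance = 1e-12)
  expect_error(fit_scaling(c(1, -2), c(1, 2)), "positive")
  # noisy power law: mean exponent unbiased within the Monte-Carlo CI
  set.seed(53)
  est <- replicate(60, fit_scaling(x, 7 * x^(-1.5) *
                                     exp(rnorm(4, sd = 0.1)))$exponent)
  expect_lt(abs(mean(est) + 1.5), 3 * sd(est) / sqrt(length(est)) + 0.02)
})
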