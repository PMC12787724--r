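test_that("truncated-shifted LJ matches direct evaluation", {
  # beyond the cutoff: identically zero
  out <- lj_pair(c(2.5, 3, 10), eps = 0.1, sigma = 1)
  expect_equal(out$energy, c(0, 0, 0))
  expect_equal(out$force, c(0, 0, 0))
  # at r = sigma the unshifted energy vanishes, leaving minus the shift
  at1 <- lj_pair(1, eps = 0.1, sigma = 1)
  expect_equal(at1$energy, -4 * 0.1 * ((1 / 2.5)^12 - (1 / 2.5)^6))
  expect_equal(at1$energy, 0.0016317, tolerance = 1e-4)
  # at the minimum the force vanishes and the energy is -eps + shift
  atm <- lj_pair(2^(1 / 6), eps = 0.1, sigma = 1)
  expect_equal(atm$force, 0, tolerance = 1e-12)
  expect_equal(atm$energy, -0.1 + 0.016317 * 0.1, tolerance = 1e-6)
  expect_error(lj_pair(0), "r must be")
})

test_that("harmonic bond carries no 1/2 prefactor and is symmetric", {
  expect_equal(bond_potential(1, 25, 1)$energy, 0)
  expect_equal(bond_potential(1, 25, 1)$force, 0)
  expect_equal(bond_potential(1.2, 25, 1)$energy, 1.0)
  expect_equal(bond_potential(0.8, 25, 1)$energy,
               bond_potential(1.2, 25, 1)$energy)
})

test_that("angle potential matches direct evaluation and its gradient", {
  # equilibrium: straight triple, zero energy and forces
  ap <- angle_potential(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), ka = 250)
  expect_equal(ap$energy, 0)
  expect_equal(max(abs(ap$forces)), 0, tolerance = 1e-10)
  # 170 degrees at ka = 250: 250*(10*pi/180)^2
  th <- 170 * pi / 180
  ap <- angle_potential(c(cos(th), sin(th), 0), c(0, 0, 0), c(1, 0, 0), ka = 250)
  expect_equal(ap$theta, th)
  expect_equal(ap$energy, 250 * (pi / 18)^2)
  expect_equal(ap$energy, 7.615, tolerance = 1e-3)
  # finite-difference gradient check at random geometries
  set.seed(4)
  for (rep in 1:5) {
    x <- matrix(rnorm(9), 3, 3)
    ap <- angle_potential(x[1, ], x[2, ], x[3, ], ka = 25)
    fmat <- unname(ap$forces)
    h <- 1e-6
    for (bead in 1:3) for (k in 1:3) {
      xp <- x; xp[bead, k] <- xp[bead, k] + h
      xm <- x; xm[bead, k] <- xm[bead, k] - h
      num <- -(angle_potential(xp[1, ], xp[2, ], xp[3, ], ka = 25)$energy -
               angle_potential(xm[1, ], xm[2, ], xm[3, ], ka = 25)$energy) / (2 * h)
      expect_equal(fmat[bead, k], num, tolerance = 1e-5)
    }
    # zero net force and net torque about the origin
    expect_equal(colSums(fmat), c(0, 0, 0), tolerance = 1e-10)
    torque <- colSums(t(vapply(1:3, function(b)
      c(x[b, 2] * fmat[b, 3] - x[b, 3] * fmat[b, 2],
        x[b, 3] * fmat[b, 1] - x[b, 1] * fmat[b, 3],
        x[b, 1] * fmat[b, 2] - x[b, 2] * fmat[b, 1]), numeric(3))))
    expect_equal(torque, c(0, 0, 0), tolerance = 1e-8)
  }
  expect_error(angle_potential(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("tether spring is quadratic in the displacement", {
  expect_equal(tether_potential(c(1, 2, 3), c(1, 2, 3))$energy, 0)
  expect_equal(tether_potential(c(1, 0, 0), c(0, 0, 0), k = 1)$energy, 1)
  expect_equal(tether_potential(c(2, 0, 0), c(0, 0, 0), k = 1)$energy, 4)
  expect_equal(tether_potential(c(1, 0, 0), c(0, 0, 0), k = 1)$force,
               c(-2, 0, 0))
})

test_that("assembled system energies match hand assembly", {
  ff <- force_field("thin", 250)
  # bonded dimer at rest length: bond zero, LJ excluded
  sys <- manual_system(rbind(c(5, 5, 5), c(6, 5, 5)),
                       bonds = rbind(c(1L, 2L)))
  tf <- total_forces(sys, ff)
  expect_equal(tf$energy, 0, tolerance = 1e-14)
  expect_equal(max(abs(tf$forces)), 0, tolerance = 1e-12)
  # straight 3-bead rod: only the 1-3 LJ pair (at 2 sigma) contributes
  sys <- manual_system(rbind(c(5, 5, 5), c(6, 5, 5), c(7, 5, 5)),
                       bonds = rbind(c(1L, 2L), c(2L, 3L)),
                       angles = rbind(c(1L, 2L, 3L)))
  tf <- total_forces(sys, ff)
  expect_equal(tf$energy, lj_pair(2, 0.1, 1, 2.5)$energy, tolerance = 1e-14)
})

test_that("neighbour-list forces equal the all-pairs oracle", {
  ff <- force_field("thin", 25)
  set.seed(11)
  for (rep in 1:3) {
    # random mixed-species gas with a few bonds/angles/tethers
    n <- 60
    pos <- matrix(runif(3 * n) * 10, n, 3)
    sp <- sample(c("network", "rod_thin"), n, replace = TRUE)
    mol <- ifelse(sp == "network", 0L, 1L)
    sys <- manual_system(pos, box = rep(10, 3), species = sp,
                         bonds = rbind(c(1L, 2L), c(3L, 4L)),
                         angles = rbind(c(1L, 2L, 3L)),
                         tether_idx = c(5L, 6L),
                         tether_anchor = pos[5:6, ] + 0.3,
                         molecule_id = mol)
    got <- total_forces(sys, ff)
    want <- ref_total_forces(sys, ff)
    expect_equal(got$energy, want$energy, tolerance = 1e-10)
    expect_equal(got$forces, want$forces, tolerance = 1e-10)
  }
})

test_that("translational invariance and Newton's third law hold", {
  ff <- force_field("thin", 250)
  cfg <- build_config(box_lengths = c(12, 12, 12), n_rods = 2, rod_N = 6,
                      seed = 9)
  sys <- build_system(cfg)
  sys$tether_idx <- integer()            # tethers break both properties
  sys$tether_anchor <- matrix(0, 0, 3)
  tf <- total_forces(sys, ff)
  expect_equal(colSums(tf$forces), c(0, 0, 0), tolerance = 1e-10)
  shifted <- sys
  shifted$positions <- sys$positions + 1.2345   # rigid shift (unwrapped)
  tf2 <- total_forces(shifted, ff)
  expect_equal(tf2$energy, tf$energy, tolerance = 1e-10)
  # overlapping beads are rejected
  bad <- manual_system(rbind(c(1, 1, 1), c(1, 1, 1 + 1e-9)))
  expect_error(total_forces(bad, ff), "overlap")
})

test_that("pair table renders as LAMMPS pair_coeff lines", {
  pc <- lammps_pair_coeffs(force_field("thin", 250))
  expect_length(pc, 6)
  expect_true(any(grepl("^pair_coeff 1 2 0.1 2 5$", pc)))
  expect_true(any(grepl("^pair_coeff 1 1 0.1 1 2.5$", pc)))
  pc_thick <- lammps_pair_coeffs(force_field("thick", 25))
  expect_true(any(grepl("^pair_coeff 1 3 0.1 2.62 6.55$", pc_thick)))
})
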