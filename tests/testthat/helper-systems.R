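# Shared fixtures and independent oracles, all built in code.

# A bare particle_system with no topology: n free beads (each its own
# "molecule" so the analysis stack can treat them as point tracers).
free_system <- function(n, box = 50, seed = 1, species = "rod_thin") {
  pos <- netrod:::with_seed(seed, matrix(runif(3 * n) * box, n, 3))
  structure(list(box_lengths = rep(box, 3), positions = pos,
                 image_counts = matrix(0, n, 3), species = rep(species, n),
                 molecule_id = seq_len(n), bonds = matrix(0L, 0, 2),
                 angles = matrix(0L, 0, 3), tether_idx = integer(),
                 tether_anchor = matrix(0, 0, 3), masses = rep(1, n),
                 velocities = NULL), class = "particle_system")
}

# Hand-assembled small system with explicit topology.
manual_system <- function(pos, box = rep(20, 3), species = NULL,
                          bonds = matrix(0L, 0, 2), angles = matrix(0L, 0, 3),
                          tether_idx = integer(),
                          tether_anchor = matrix(0, 0, 3),
                          molecule_id = NULL, velocities = NULL) {
  n <- nrow(pos)
  if (is.null(species)) species <- rep("network", n)
  if (is.null(molecule_id)) molecule_id <- rep(0L, n)
  structure(list(box_lengths = box, positions = pos,
                 image_counts = matrix(0, n, 3), species = species,
                 molecule_id = molecule_id, bonds = bonds, angles = angles,
                 tether_idx = tether_idx, tether_anchor = tether_anchor,
                 masses = rep(1, n), velocities = velocities),
            class = "particle_system")
}

# Independent all-pairs force/energy oracle in plain R (no neighbour list),
# assembled from the exported per-term potentials.
ref_total_forces <- function(sys, params) {
  pos <- sys$positions + sweep(sys$image_counts, 2, sys$box_lengths, "*")
  n <- nrow(pos)
  box <- sys$box_lengths
  ty <- match(sys$species, c("network", "rod_thin", "rod_thick"))
  F <- matrix(0, n, 3)
  E <- 0
  mi <- function(d) d - box * round(d / box)
  excl <- if (nrow(sys$bonds)) paste(pmin(sys$bonds[, 1], sys$bonds[, 2]),
                                     pmax(sys$bonds[, 1], sys$bonds[, 2])) else character()
  if (params$epsilon != 0 && n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (paste(i, j) %in% excl) next
      d <- mi(pos[i, ] - pos[j, ])
      r <- sqrt(sum(d^2))
      sig <- params$sigma_table[ty[i], ty[j]]
      rc <- params$rcut_factor * sig
      if (r >= rc) next
      lj <- lj_pair(r, params$epsilon, sig, rc)
      E <- E + lj$energy
      fv <- lj$force * d / r
      F[i, ] <- F[i, ] + fv
      F[j, ] <- F[j, ] - fv
    }
  }
  if (nrow(sys$bonds)) for (b in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds[b, 1]; j <- sys$bonds[b, 2]
    d <- mi(pos[i, ] - pos[j, ])
    r <- sqrt(sum(d^2))
    bp <- bond_potential(r, params$kb, params$r0)
    E <- E + bp$energy
    fv <- bp$force * d / r
    F[i, ] <- F[i, ] + fv
    F[j, ] <- F[j, ] - fv
  }
  if (nrow(sys$angles)) {
    ka <- ifelse(sys$molecule_id[sys$angles[, 2]] == 0L, params$ka_network,
                 params$rod_ka)
    for (a in seq_len(nrow(sys$angles))) {
      i <- sys$angles[a, 1]; j <- sys$angles[a, 2]; k <- sys$angles[a, 3]
      rij <- pos[j, ] + mi(pos[i, ] - pos[j, ])
      rkj <- pos[j, ] + mi(pos[k, ] - pos[j, ])
      ap <- angle_potential(rij, pos[j, ], rkj, ka[a], params$theta0)
      E <- E + ap$energy
      F[i, ] <- F[i, ] + ap$forces["i", ]
      F[j, ] <- F[j, ] + ap$forces["j", ]
      F[k, ] <- F[k, ] + ap$forces["k", ]
    }
  }
  if (length(sys$tether_idx)) for (t in seq_along(sys$tether_idx)) {
    i <- sys$tether_idx[t]
    tp <- tether_potential(pos[i, ], sys$tether_anchor[t, ], params$k_tether)
    E <- E + tp$energy
    F[i, ] <- F[i, ] + tp$force
  }
  list(energy = E, forces = F)
}

# lag_statistic constructor for synthetic curves (class is plain S3 on a
# data.frame, so tests may build one directly)
make_ls <- function(lag, value, n = 1) {
  structure(data.frame(lag = lag, value = value, n = n),
            observable = "synthetic", class = c("lag_statistic", "data.frame"))
}

# plain Brownian walkers as a rod_series (independent of the oracle module)
brownian_series <- function(n_walkers, n_frames, D, dt = 1, seed = 1) {
  com <- netrod:::with_seed(seed, {
    steps <- array(rnorm(n_frames * n_walkers * 3, sd = sqrt(2 * D * dt)),
                   c(n_frames, n_walkers, 3))
    steps[1, , ] <- 0
    apply(steps, c(2, 3), cumsum)
  })
  rod_series(times = (seq_len(n_frames) - 1) * dt, com = com)
}
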