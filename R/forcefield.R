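# Species indexing used throughout: 1 = network, 2 = rod_thin, 3 = rod_thick.
SPECIES_LEVELS <- c("network", "rod_thin", "rod_thick")

species_index <- function(species) {
  idx <- match(species, SPECIES_LEVELS)
  if (anyNA(idx)) stop("unknown species: ",
                       paste(unique(species[is.na(idx)]), collapse = ", "))
  idx
}

sigma_lookup <- function(rod_class, sigma_cn = NULL) {
  if (is.null(sigma_cn)) sigma_cn <- if (rod_class == "thin") 2 else 2.62
  c(nn = 1, cc = 1, cn = sigma_cn)
}

#' Force-field parameter set
#'
#' All interactions use the coarse-grained parameterization: a purely weak
#' (eps = 0.1 kBT) truncated-shifted LJ pair potential between all beads, with
#' species-pair diameters sigma_cc = sigma_nn = 1 sigma and a rod-network
#' diameter sigma_cn of 2 sigma (thin rods, effective rod diameter 3 sigma) or
#' 2.62 sigma (thick rods, doubled effective cross-sectional area); harmonic
#' bonds U = kb (r - r0)^2 with kb = 25 kBT/sigma^2, r0 = 1 sigma; harmonic
#' angles U = ka (theta - pi)^2 with ka = 250 kBT/rad^2 along network strands
#' and ka = 250, 25 or 2.5 for rods; and junction tethers with spring constant
#' 1 kBT/sigma^2. Bonded (1-2) pairs are excluded from the LJ sum. The
#' quadratic potentials carry no 1/2 prefactor.
#'
#' @param rod_class `"thin"` or `"thick"`; sets the default `sigma_cn`.
#' @param rod_ka rod bending stiffness (kBT/rad^2).
#' @param epsilon LJ well depth for all pairs (kBT).
#' @param sigma_cn override for the rod-network LJ diameter (sigma).
#' @param rcut_factor cutoff in units of the pair sigma (LJ truncated and
#'   shifted to zero there).
#' @param kb,r0 bond spring constant (kBT/sigma^2) and rest length (sigma).
#' @param ka_network network-strand bending stiffness (kBT/rad^2).
#' @param theta0 equilibrium angle (radians); straight chains.
#' @param k_tether junction self-spring constant (kBT/sigma^2).
#' @return an object of class `force_field` holding the per-species-pair sigma
#'   table and all constants.
#' @export
force_field <- function(rod_class = c("thin", "thick"), rod_ka = 250,
                        epsilon = 0.1, sigma_cn = NULL, rcut_factor = 2.5,
                        kb = 25, r0 = 1, ka_network = 250, theta0 = pi,
                        k_tether = 1) {
  rod_class <- match.arg(rod_class)
  sig <- sigma_lookup(rod_class, sigma_cn)
  # explicit pair table over (network, rod_thin, rod_thick); rod-rod pairs use
  # sigma_nn = 1 for both classes, only rod-network pairs are enlarged
  st <- matrix(1, 3, 3, dimnames = list(SPECIES_LEVELS, SPECIES_LEVELS))
  st["network", "rod_thin"] <- st["rod_thin", "network"] <- if (rod_class == "thin") sig["cn"] else 2
  st["network", "rod_thick"] <- st["rod_thick", "network"] <- if (rod_class == "thick") sig["cn"] else 2.62
  structure(list(epsilon = epsilon, sigma_table = st,
                 rcut_factor = rcut_factor, kb = kb, r0 = r0,
                 ka_network = ka_network, rod_ka = rod_ka, theta0 = theta0,
                 k_tether = k_tether, rod_class = rod_class),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("<force_field> eps =", x$epsilon, "kBT, rcut =", x$rcut_factor, "sigma_ij\n")
  cat("  sigma_cn:", x$sigma_table["network", paste0("rod_", x$rod_class)],
      sprintf("sigma (%s rods)\n", x$rod_class))
  cat("  kb =", x$kb, " r0 =", x$r0, " ka(network) =", x$ka_network,
      " ka(rod) =", x$rod_ka, " k_tether =", x$k_tether, "\n")
  invisible(x)
}

#' Truncated-shifted Lennard-Jones pair potential
#'
#' U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6), truncated at `rcut` and shifted
#' so the energy is zero there; the force is that of the unshifted form.
#' Vectorized over `r`.
#'
#' @param r pair distance(s), sigma; must be positive.
#' @param eps well depth (kBT).
#' @param sigma pair diameter (sigma).
#' @param rcut cutoff distance (default 2.5 sigma).
#' @return list with `energy` and `force` (magnitude of -dU/dr; positive =
#'   repulsive), each the length of `r`.
#' @export
lj_pair <- function(r, eps = 0.1, sigma = 1, rcut = 2.5 * sigma) {
  if (any(r <= 0)) stop("lj_pair: r must be > 0")
  sr6 <- (sigma / r)^6
  shift <- local({ s6 <- (sigma / rcut)^6; 4 * eps * (s6^2 - s6) })
  e <- ifelse(r < rcut, 4 * eps * (sr6^2 - sr6) - shift, 0)
  f <- ifelse(r < rcut, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  list(energy = e, force = f)
}

#' Harmonic bond potential
#'
#' U(r) = kb (r - r0)^2 (no 1/2 prefactor, matching LAMMPS `bond_style
#' harmonic`). Vectorized over `r`.
#'
#' @param r bond length(s), sigma.
#' @param kb spring constant (kBT/sigma^2).
#' @param r0 rest length (sigma).
#' @return list with `energy` and `force` (restoring force magnitude
#'   -dU/dr).
#' @export
bond_potential <- function(r, kb = 25, r0 = 1) {
  if (any(r <= 0)) stop("bond_potential: r must be > 0")
  list(energy = kb * (r - r0)^2, force = -2 * kb * (r - r0))
}

#' Harmonic angle potential with per-bead forces
#'
#' U(theta) = ka (theta - theta0)^2 for the angle at bead `j` of the triple
#' (i, j, k). Returns the energy and the analytic forces on the three beads
#' (which sum to zero and exert zero net torque).
#'
#' @param ri,rj,rk positions of the three beads (3-vectors); `rj` is the
#'   centre bead.
#' @param ka bending stiffness (kBT/rad^2).
#' @param theta0 equilibrium angle (radians; pi for straight chains).
#' @return list with `energy`, `theta`, and `forces` (3 x 3 matrix, one row
#'   per bead in i, j, k order).
#' @export
angle_potential <- function(ri, rj, rk, ka = 250, theta0 = pi) {
  d1 <- ri - rj
  d2 <- rk - rj
  r1 <- sqrt(sum(d1^2)); r2 <- sqrt(sum(d2^2))
  if (r1 < 1e-10 || r2 < 1e-10) stop("angle_potential: degenerate bond vector")
  cth <- max(-1, min(1, sum(d1 * d2) / (r1 * r2)))
  sth <- max(sqrt(1 - cth^2), 1e-8)
  theta <- acos(cth)
  e <- ka * (theta - theta0)^2
  a <- -2 * ka * (theta - theta0) / sth
  fi <- (a * cth / r1^2) * d1 + (-a / (r1 * r2)) * d2
  fk <- (a * cth / r2^2) * d2 + (-a / (r1 * r2)) * d1
  list(energy = e, theta = theta,
       forces = rbind(i = fi, j = -(fi + fk), k = fk))
}

#' Junction tether potential
#'
#' Self-spring restraining a network junction to its anchor point:
#' U = k |pos - anchor|^2, force -2 k (pos - anchor).
#'
#' @param pos current bead position (3-vector).
#' @param anchor anchor point (3-vector).
#' @param k spring constant (kBT/sigma^2).
#' @return list with `energy` and `force` (3-vector).
#' @export
tether_potential <- function(pos, anchor, k = 1) {
  d <- pos - anchor
  list(energy = k * sum(d^2), force = -2 * k * d)
}

# per-angle ka vector: network angles first (molecule 0), rods after
angle_ka_vector <- function(sys, params) {
  centre_mol <- sys$molecule_id[sys$angles[, 2]]
  ifelse(centre_mol == 0L, params$ka_network, params$rod_ka)
}

#' Total potential energy and forces of a system
#'
#' Assembles the LJ pair sum (Verlet neighbour list, minimum image, 1-2
#' exclusions), harmonic bonds, harmonic angles and junction tethers for a
#' full `particle_system`.
#'
#' @param sys a `particle_system`.
#' @param params a [force_field()].
#' @return list with `energy` (kBT) and `forces` (n x 3 matrix, kBT/sigma).
#' @export
total_forces <- function(sys, params) {
  pos <- unwrapped_positions(sys)
  ka <- angle_ka_vector(sys, params)
  res <- cpp_forces(pos, sys$box_lengths, species_index(sys$species),
                    params$sigma_table, params$epsilon, params$rcut_factor,
                    bonds_matrix(sys), angles_matrix(sys), ka,
                    as.integer(sys$tether_idx), tether_anchor_matrix(sys),
                    params$kb, params$r0, params$theta0, params$k_tether)
  res
}

bonds_matrix <- function(sys) {
  if (nrow(sys$bonds) == 0) matrix(0L, 0, 2) else
    matrix(as.integer(sys$bonds), ncol = 2)
}
angles_matrix <- function(sys) {
  if (nrow(sys$angles) == 0) matrix(0L, 0, 3) else
    matrix(as.integer(sys$angles), ncol = 3)
}
tether_anchor_matrix <- function(sys) {
  if (length(sys$tether_idx) == 0) matrix(0, 0, 3) else
    matrix(as.numeric(sys$tether_anchor), ncol = 3)
}

#' LAMMPS pair_coeff lines for the force field
#'
#' Renders the species-pair LJ table as `pair_coeff` commands (types
#' network = 1, rod_thin = 2, rod_thick = 3) for cross-checking the
#' parameterization against an external engine running
#' `pair_style lj/cut` with shifted energies.
#'
#' @param params a [force_field()].
#' @return character vector of `pair_coeff i j eps sigma rcut` lines.
#' @export
lammps_pair_coeffs <- function(params) {
  stopifnot(inherits(params, "force_field"))
  out <- character()
  for (i in 1:3) for (j in i:3) {
    sig <- params$sigma_table[i, j]
    out <- c(out, sprintf("pair_coeff %d %d %.10g %.10g %.10g", i, j,
                          params$epsilon, sig, params$rcut_factor * sig))
  }
  out
}
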