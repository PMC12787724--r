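#' Build configuration for a network + nanorod system
#'
#' Collects and validates the geometric parameters of the simulated system:
#' the periodic box, the cubic network mesh, and the nanorod population.
#' Defaults correspond to a desk-scale box of 24 x 30 x 24 sigma with the
#' standard 6-sigma mesh; the production-scale box is 48 x 54 x 48 sigma.
#'
#' @param box_lengths numeric length-3, box edge lengths (sigma). Each must be
#'   an integer multiple of `mesh`.
#' @param mesh cubic network mesh size (sigma); an integer multiple of
#'   `bead_spacing`.
#' @param bead_spacing spacing of beads along network strands and rods (sigma).
#' @param n_rods number of nanorods to insert; `NULL` uses
#'   [default_rod_count()] scaled by the ratio of the box volume to the
#'   production box volume (so the rod volume fraction matches).
#' @param rod_N beads per nanorod (>= 3).
#' @param rod_class `"thin"` or `"thick"` (sets the rod-network LJ diameter).
#' @param rod_ka rod bending stiffness (kBT/rad^2); 250, 25 and 2.5 denote
#'   rigid, semiflexible and soft rods.
#' @param seed integer seed controlling rod insertion.
#' @param min_insert_gap minimal allowed distance between a newly inserted rod
#'   bead and any existing bead (sigma). `NULL` uses 0.9 times the pair LJ
#'   diameter of the relevant species pair.
#' @return an object of class `build_config`.
#' @export
build_config <- function(box_lengths = c(24, 30, 24), mesh = 6,
                         bead_spacing = 1, n_rods = NULL, rod_N = 10,
                         rod_class = c("thin", "thick"), rod_ka = 250,
                         seed = 1, min_insert_gap = NULL) {
  rod_class <- match.arg(rod_class)
  box_lengths <- as.numeric(box_lengths)
  stopifnot(length(box_lengths) == 3, all(box_lengths > 0),
            mesh > 0, bead_spacing > 0, rod_N >= 3)
  if (any(abs(box_lengths / mesh - round(box_lengths / mesh)) > 1e-9))
    stop("box_lengths must be integer multiples of the mesh size (got box ",
         paste(box_lengths, collapse = "x"), ", mesh ", mesh, ")")
  if (abs(mesh / bead_spacing - round(mesh / bead_spacing)) > 1e-9)
    stop("mesh must be an integer multiple of bead_spacing")
  if (is.null(n_rods)) {
    budget <- default_rod_count(rod_N, rod_class) * rod_N
    frac <- prod(box_lengths) / prod(c(48, 54, 48))
    n_rods <- max(1L, round(budget * frac / rod_N))
  }
  structure(list(box_lengths = box_lengths, mesh = mesh,
                 bead_spacing = bead_spacing, n_rods = as.integer(n_rods),
                 rod_N = as.integer(rod_N), rod_class = rod_class,
                 rod_ka = rod_ka, seed = as.integer(seed),
                 min_insert_gap = min_insert_gap),
            class = "build_config")
}

#' Standard nanorod count at fixed total rod-bead budget
#'
#' The number of rods is chosen so the total number of rod beads stays at
#' roughly 800 (thin) or 400 (thick) in the production 48 x 54 x 48 sigma box,
#' keeping the rod volume fraction constant across rod lengths.
#'
#' @param rod_N beads per rod.
#' @param rod_class `"thin"` or `"thick"`.
#' @return integer rod count, `round(budget / rod_N)`.
#' @export
#' @examples
#' default_rod_count(10, "thin")   # 80
#' default_rod_count(25, "thick")  # 16
default_rod_count <- function(rod_N, rod_class = c("thin", "thick")) {
  rod_class <- match.arg(rod_class)
  budget <- if (rod_class == "thin") 800 else 400
  as.integer(round(budget / rod_N))
}

new_particle_system <- function(box_lengths, positions, image_counts, species,
                                molecule_id, bonds, angles, tether_idx,
                                tether_anchor, masses) {
  structure(list(box_lengths = box_lengths, positions = positions,
                 image_counts = image_counts, species = species,
                 molecule_id = molecule_id, bonds = bonds, angles = angles,
                 tether_idx = tether_idx, tether_anchor = tether_anchor,
                 masses = masses, velocities = NULL),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("<particle_system>\n")
  cat(sprintf("  box: %s sigma (periodic)\n", paste(x$box_lengths, collapse = " x ")))
  tab <- table(x$species)
  cat(sprintf("  beads: %d (%s)\n", nrow(x$positions),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("  bonds: %d  angles: %d  tethered junctions: %d\n",
              nrow(x$bonds), nrow(x$angles), length(x$tether_idx)))
  n_rods <- max(x$molecule_id)
  if (n_rods > 0) cat(sprintf("  rods: %d\n", n_rods))
  invisible(x)
}

wrap_positions <- function(pos, box) {
  img <- floor(sweep(pos, 2, box, "/"))
  list(wrapped = pos - sweep(img, 2, box, "*"), image = img)
}

# Unwrapped coordinates of a system (wrapped + image * box).
unwrapped_positions <- function(sys) {
  sys$positions + sweep(sys$image_counts, 2, sys$box_lengths, "*")
}

#' Construct the cross-linked network
#'
#' Places junction beads on every node of a periodic cubic lattice of the
#' configured mesh and connects each node to its +x, +y and +z neighbours by a
#' straight strand of `mesh/bead_spacing - 1` interior beads. Bonds chain
#' node-interior-...-node; angle potentials run along every straight triple of
#' each strand (angles centred on junction beads are omitted: junction
#' geometry is maintained by tethers). Every junction bead is tethered to its
#' own initial position by a harmonic self-spring.
#'
#' @param cfg a [build_config()].
#' @return a `particle_system` containing only network beads.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "build_config"))
  box <- cfg$box_lengths
  n_cells <- as.integer(round(box / cfg$mesh))
  s <- as.integer(round(cfg$mesh / cfg$bead_spacing)) - 1L  # interior beads/strand
  n_nodes <- as.integer(prod(n_cells))
  n_strands <- 3L * n_nodes

  # nodes on the lattice, index (i,j,k) zero-based, column-major id
  grid <- as.matrix(expand.grid(i = seq_len(n_cells[1]) - 1L,
                                j = seq_len(n_cells[2]) - 1L,
                                k = seq_len(n_cells[3]) - 1L))
  node_pos <- sweep(grid, 2, rep(cfg$mesh, 3), "*")
  node_id <- function(i, j, k) {  # periodic
    i <- i %% n_cells[1]; j <- j %% n_cells[2]; k <- k %% n_cells[3]
    1L + i + n_cells[1] * (j + n_cells[2] * k)
  }

  n_beads <- n_nodes + n_strands * s
  pos <- matrix(0, n_beads, 3)
  pos[seq_len(n_nodes), ] <- node_pos
  bonds <- matrix(0L, n_strands * (s + 1L), 2)
  angles <- matrix(0L, n_strands * max(s, 0L), 3)
  bead_ptr <- n_nodes  # integer: keeps bond/angle storage integer
  bond_ptr <- 0L
  ang_ptr <- 0L
  dirs <- diag(3)
  for (a in seq_len(n_nodes)) {
    ijk <- grid[a, ]
    for (d in 1:3) {
      step <- c(0L, 0L, 0L); step[d] <- 1L
      b <- node_id(ijk[1] + step[1], ijk[2] + step[2], ijk[3] + step[3])
      chain <- integer(s + 2L)
      chain[1] <- a
      if (s > 0) {
        idx <- bead_ptr + seq_len(s)
        for (q in seq_len(s))
          pos[idx[q], ] <- node_pos[a, ] + q * cfg$bead_spacing * dirs[d, ]
        chain[2:(s + 1L)] <- idx
        bead_ptr <- bead_ptr + s
      }
      chain[s + 2L] <- b
      for (q in seq_len(s + 1L)) {
        bond_ptr <- bond_ptr + 1L
        bonds[bond_ptr, ] <- c(chain[q], chain[q + 1L])
      }
      if (s > 0) for (q in seq_len(s)) {  # triples centred on interior beads
        ang_ptr <- ang_ptr + 1L
        angles[ang_ptr, ] <- chain[q:(q + 2L)]
      }
    }
  }
  angles <- angles[seq_len(ang_ptr), , drop = FALSE]

  w <- wrap_positions(pos, box)
  new_particle_system(
    box_lengths = box, positions = w$wrapped, image_counts = w$image,
    species = rep("network", n_beads), molecule_id = rep(0L, n_beads),
    bonds = bonds, angles = angles, tether_idx = seq_len(n_nodes),
    tether_anchor = pos[seq_len(n_nodes), , drop = FALSE],
    masses = rep(1, n_beads))
}

#' Insert straight nanorods into a network system
#'
#' Inserts `cfg$n_rods` straight chains of `cfg$rod_N` beads at random
#' positions and orientations (seeded by `cfg$seed`), rejecting any placement
#' in which a new rod bead falls closer than the insertion gap to an existing
#' bead under the minimum-image metric. The gap defaults to 0.9 times the LJ
#' diameter of the species pair involved, which keeps initial forces modest.
#'
#' @param net a network `particle_system` from [build_network()].
#' @param cfg the [build_config()] used to build `net`.
#' @param max_attempts attempts allowed per rod before giving up.
#' @return the combined `particle_system`; rod beads are labelled
#'   `rod_thin`/`rod_thick` with `molecule_id` 1..n_rods.
#' @export
insert_rods <- function(net, cfg, max_attempts = 1e5) {
  stopifnot(inherits(net, "particle_system"), inherits(cfg, "build_config"))
  if (cfg$n_rods == 0L) return(net)
  box <- net$box_lengths
  rod_len <- (cfg$rod_N - 1) * cfg$bead_spacing
  if (rod_len > min(box) - 2)
    stop("rod length ", rod_len, " sigma does not fit the periodic box (min ",
         "edge ", min(box), " sigma): a rod would overlap its own image")
  rod_species <- paste0("rod_", cfg$rod_class)
  sig <- sigma_lookup(cfg$rod_class)
  gap_net <- if (is.null(cfg$min_insert_gap)) 0.9 * sig["cn"] else cfg$min_insert_gap
  gap_rod <- if (is.null(cfg$min_insert_gap)) 0.9 * sig["nn"] else cfg$min_insert_gap
  N <- cfg$rod_N
  offsets <- (seq_len(N) - (N + 1) / 2) * cfg$bead_spacing

  existing <- unwrapped_positions(net)
  is_net <- rep(TRUE, nrow(existing))
  rods <- vector("list", cfg$n_rods)

  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_rods)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        centre <- runif(3) * box
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        beads <- outer(offsets, u) + rep(centre, each = N)
        gaps <- ifelse(is_net, gap_net, gap_rod)
        if (min_dist_ok(beads, existing, box, gaps)) {
          rods[[r]] <- beads
          existing <- rbind(existing, beads)
          is_net <- c(is_net, rep(FALSE, N))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("failed to insert rod ", r, " after ", max_attempts, " attempts")
    }
  })

  n0 <- nrow(net$positions)
  rod_pos <- do.call(rbind, rods)
  rod_bonds <- do.call(rbind, lapply(seq_len(cfg$n_rods), function(r) {
    base <- n0 + (r - 1L) * N
    cbind(base + seq_len(N - 1L), base + seq_len(N - 1L) + 1L)
  }))
  rod_angles <- if (N >= 3) do.call(rbind, lapply(seq_len(cfg$n_rods), function(r) {
    base <- n0 + (r - 1L) * N
    cbind(base + seq_len(N - 2L), base + seq_len(N - 2L) + 1L,
          base + seq_len(N - 2L) + 2L)
  })) else matrix(0L, 0, 3)

  w <- wrap_positions(rod_pos, box)
  out <- net
  out$positions <- rbind(net$positions, w$wrapped)
  out$image_counts <- rbind(net$image_counts, w$image)
  out$species <- c(net$species, rep(rod_species, cfg$n_rods * N))
  out$molecule_id <- c(net$molecule_id, rep(seq_len(cfg$n_rods), each = N))
  out$bonds <- rbind(net$bonds, rod_bonds)
  out$angles <- rbind(net$angles, rod_angles)
  out$masses <- c(net$masses, rep(1, cfg$n_rods * N))
  out
}

# TRUE if every candidate bead is at least gap[j] away from existing bead j
# (minimum image).  gaps is per-existing-bead.
min_dist_ok <- function(beads, existing, box, gaps) {
  for (q in seq_len(nrow(beads))) {
    d <- sweep(existing, 2, beads[q, ], "-")
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    if (any(rowSums(d^2) < gaps^2)) return(FALSE)
  }
  TRUE
}

#' Build a complete network + rod system in one call
#'
#' Convenience wrapper: [build_network()] followed by [insert_rods()].
#'
#' @inheritParams insert_rods
#' @return a `particle_system`.
#' @export
build_system <- function(cfg, max_attempts = 1e5) {
  insert_rods(build_network(cfg), cfg, max_attempts = max_attempts)
}
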