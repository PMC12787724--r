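# Extended XYZ -------------------------------------------------------------

#' Write a trajectory or system snapshot as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying the periodic box
#' (`Lattice=...`), the column layout (`Properties=species:S:1:pos:R:3:mol:I:1`)
#' and the frame time, then one line per bead. Coordinates are written
#' unwrapped at full double precision.
#'
#' @param x a `trajectory` or a `particle_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "particle_system")) {
    frames <- array(unwrapped_positions(x), c(1, nrow(x$positions), 3))
    times <- 0; box <- x$box_lengths; sp <- x$species; mol <- x$molecule_id
  } else {
    stopifnot(inherits(x, "trajectory"))
    frames <- x$frames; times <- x$times; box <- x$box_lengths
    sp <- x$species; mol <- x$molecule_id
  }
  nb <- dim(frames)[2]
  lattice <- sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g"', box[1], box[2], box[3])
  for (f in seq_len(dim(frames)[1])) {
    writeLines(as.character(nb), con)
    writeLines(sprintf('%s Properties=species:S:1:pos:R:3:mol:I:1 Time=%.10g',
                       lattice, times[f]), con)
    writeLines(sprintf("%s %.17g %.17g %.17g %d", sp,
                       frames[f, , 1], frames[f, , 2], frames[f, , 3], mol), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_xyz()]; returns a `trajectory` (analysis-ready but with
#' no energy series or final state).
#'
#' @param path file written by [write_xyz()] or compatible.
#' @return a `trajectory`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(); box <- NULL; sp <- NULL; mol <- NULL
  i <- 1L
  while (i <= length(lines)) {
    nb <- as.integer(lines[i])
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    if (!is.na(lat)) {
      lv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
      box <- lv[c(1, 5, 9)]
    }
    tm <- regmatches(comment, regexec("Time=([0-9.eE+-]+)", comment))[[1]][2]
    times <- c(times, if (is.na(tm)) length(times) else as.numeric(tm))
    block <- strsplit(lines[i + 1L + seq_len(nb)], "\\s+")
    sp <- vapply(block, `[`, "", 1)
    xyz <- t(vapply(block, function(b) as.numeric(b[2:4]), numeric(3)))
    mol <- vapply(block, function(b)
      if (length(b) >= 5) as.integer(b[5]) else 0L, integer(1))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nb
  }
  nf <- length(frames); nb <- nrow(frames[[1]])
  arr <- array(0, c(nf, nb, 3))
  for (f in seq_len(nf)) arr[f, , ] <- frames[[f]]
  dt <- if (nf > 1) times[2] - times[1] else 1
  structure(list(times = times, frames = arr, box_lengths = box, species = sp,
                 molecule_id = mol, dt_frame = dt, ke_series = NULL,
                 pe_series = NULL, ke_mean_per_bead = NA_real_,
                 n_beads_total = nb, seed = NA_integer_, config = NULL,
                 final_system = NULL), class = "trajectory")
}

# LAMMPS data --------------------------------------------------------------

#' Export a system as a LAMMPS data file (atom_style angle)
#'
#' Writes Masses, Atoms (id mol type x y z ix iy iz), Bonds and Angles
#' sections for cross-validation against an external engine. Atom types
#' follow the species order network=1, rod_thin=2, rod_thick=3; angle type 1
#' is a network strand angle, type 2 a rod angle. Junction tethers have no
#' LAMMPS section; on re-import junctions are re-anchored at their stored
#' positions (exact for freshly built systems).
#'
#' @param sys a `particle_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(sys, path) {
  stopifnot(inherits(sys, "particle_system"))
  con <- file(path, "w")
  on.exit(close(con))
  ty <- species_index(sys$species)
  n <- nrow(sys$positions)
  ang_type <- if (nrow(sys$angles)) ifelse(sys$molecule_id[sys$angles[, 2]] == 0L, 1L, 2L) else integer()
  writeLines(c(
    sprintf("LAMMPS data file via netrod (rod_class=%s, tethered_junctions=%d)",
            if (any(ty == 3)) "thick" else "thin", length(sys$tether_idx)),
    "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nrow(sys$bonds)),
    sprintf("%d angles", nrow(sys$angles)),
    "",
    "3 atom types", "1 bond types", "2 angle types", "",
    sprintf("0 %.17g xlo xhi", sys$box_lengths[1]),
    sprintf("0 %.17g ylo yhi", sys$box_lengths[2]),
    sprintf("0 %.17g zlo zhi", sys$box_lengths[3]),
    "", "Masses", "", "1 1", "2 1", "3 1", "", "Atoms # angle", ""), con)
  writeLines(sprintf("%d %d %d %.17g %.17g %.17g %d %d %d",
                     seq_len(n), sys$molecule_id, ty, sys$positions[, 1],
                     sys$positions[, 2], sys$positions[, 3],
                     sys$image_counts[, 1], sys$image_counts[, 2],
                     sys$image_counts[, 3]), con)
  if (nrow(sys$bonds)) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(sprintf("%d 1 %d %d", seq_len(nrow(sys$bonds)),
                       sys$bonds[, 1], sys$bonds[, 2]), con)
  }
  if (nrow(sys$angles)) {
    writeLines(c("", "Angles", ""), con)
    writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(sys$angles)), ang_type,
                       sys$angles[, 1], sys$angles[, 2], sys$angles[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS data file written by [write_lammps_data()]
#'
#' @param path data file.
#' @return a `particle_system`.
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  rod_class <- if (grepl("rod_class=thick", header)) "thick" else "thin"
  num <- function(pat) as.numeric(sub(paste0("\\s*", pat, ".*"), "",
                                      grep(pat, lines, value = TRUE)[1]))
  n <- num("atoms"); nbond <- num("bonds"); nang <- num("angles")
  bx <- function(pat) {
    l <- grep(pat, lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:2])
  }
  box <- c(diff(bx("xlo xhi")), diff(bx("ylo yhi")), diff(bx("zlo zhi")))
  section <- function(name, nrows) {
    start <- grep(paste0("^", name), lines)[1]
    body <- lines[(start + 2):(start + 1 + nrows)]
    do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  }
  at <- section("Atoms", n)
  at <- at[order(at[, 1]), , drop = FALSE]
  pos <- at[, 4:6, drop = FALSE]
  img <- if (ncol(at) >= 9) at[, 7:9, drop = FALSE] else matrix(0, n, 3)
  species <- SPECIES_LEVELS[at[, 3]]
  mol <- as.integer(at[, 2])
  bonds <- if (nbond > 0) {
    b <- section("Bonds", nbond); matrix(as.integer(b[order(b[, 1]), 3:4]), ncol = 2)
  } else matrix(0L, 0, 2)
  angles <- if (nang > 0) {
    a <- section("Angles", nang); matrix(as.integer(a[order(a[, 1]), 3:5]), ncol = 3)
  } else matrix(0L, 0, 3)
  junction <- which(mol == 0L & tabulate(c(bonds), nbins = n)[seq_len(n)] > 2)
  unwrapped <- pos + sweep(img, 2, box, "*")
  new_particle_system(box_lengths = box, positions = pos, image_counts = img,
                      species = species, molecule_id = mol, bonds = bonds,
                      angles = angles, tether_idx = junction,
                      tether_anchor = unwrapped[junction, , drop = FALSE],
                      masses = rep(1, n))
}

#' Read a LAMMPS dump trajectory
#'
#' Parses `dump custom` output with columns `id type xu yu zu` (optionally a
#' `mol` column) into a `trajectory` of unwrapped coordinates, for
#' cross-engine comparison.
#'
#' @param path dump file.
#' @param dt MD time step (tau) used to convert step numbers to times.
#' @return a `trajectory`.
#' @export
read_lammps_dump <- function(path, dt = 0.005) {
  lines <- readLines(path)
  hdr <- grep("^ITEM: TIMESTEP", lines)
  frames <- list(); steps <- numeric(); box <- NULL; mol <- NULL; type <- NULL
  for (h in hdr) {
    steps <- c(steps, as.numeric(lines[h + 1]))
    nb <- as.integer(lines[grep("^ITEM: NUMBER OF ATOMS", lines[h:length(lines)])[1] + h])
    bidx <- grep("^ITEM: BOX BOUNDS", lines[h:length(lines)])[1] + h - 1
    box <- vapply(1:3, function(k) {
      v <- as.numeric(strsplit(trimws(lines[bidx + k]), "\\s+")[[1]])
      v[2] - v[1]
    }, numeric(1))
    aidx <- grep("^ITEM: ATOMS", lines[h:length(lines)])[1] + h - 1
    cols <- strsplit(sub("^ITEM: ATOMS\\s+", "", lines[aidx]), "\\s+")[[1]]
    body <- do.call(rbind, lapply(strsplit(trimws(lines[aidx + seq_len(nb)]), "\\s+"),
                                  as.numeric))
    body <- body[order(body[, match("id", cols)]), , drop = FALSE]
    xyz <- body[, match(c("xu", "yu", "zu"), cols), drop = FALSE]
    if ("mol" %in% cols) mol <- as.integer(body[, match("mol", cols)])
    if ("type" %in% cols) type <- as.integer(body[, match("type", cols)])
    frames[[length(frames) + 1L]] <- xyz
  }
  nf <- length(frames); nb <- nrow(frames[[1]])
  arr <- array(0, c(nf, nb, 3))
  for (f in seq_len(nf)) arr[f, , ] <- frames[[f]]
  if (is.null(mol)) mol <- rep(0L, nb)
  sp <- if (is.null(type)) rep("network", nb) else SPECIES_LEVELS[type]
  dtf <- if (nf > 1) (steps[2] - steps[1]) * dt else dt
  structure(list(times = steps * dt, frames = arr, box_lengths = box,
                 species = sp, molecule_id = mol, dt_frame = dtf,
                 ke_series = NULL, pe_series = NULL,
                 ke_mean_per_bead = NA_real_, n_beads_total = nb,
                 seed = NA_integer_, config = NULL, final_system = NULL),
            class = "trajectory")
}

# Run configuration ---------------------------------------------------------

CONFIG_DEFAULTS <- list(
  box_lengths = c(24, 30, 24), mesh = 6, bead_spacing = 1, n_rods = NULL,
  rod_N = 10, rod_class = "thin", rod_ka = 250, seed = 1,
  min_insert_gap = NULL,
  epsilon = 0.1, sigma_cn = NULL, rcut_factor = 2.5, kb = 25, r0 = 1,
  ka_network = 250, theta0 = pi, k_tether = 1,
  dt = 0.005, zeta = 1.0, temperature = 1.0, n_steps = 2e6,
  save_stride = 200, equilibration = 2e5, thermostat_off = FALSE, mass = 1,
  skin = 0.4)

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON-as-YAML) run configuration, applies the standard
#' defaults (eps = 0.1 kBT, T = 1, zeta = 1, dt = 0.005 tau, mesh = 6 sigma,
#' kb = 25, theta0 = pi, tether k = 1, desk-scale 24 x 30 x 24 box) and
#' rejects unknown keys. An empty file yields the full default set.
#'
#' @param path YAML file; keys are the argument names of [build_config()],
#'   [force_field()] and [integrator_config()]. Two templates ship with the
#'   package: `system.file("extdata", "config-desk.yaml", package = "netrod")`
#'   (desk scale) and `config-production.yaml` (the full-scale campaign box
#'   and step count; cluster scale).
#' @return list with validated `build`, `forcefield` and `integrator`
#'   configurations plus the merged `values`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  vals <- modifyList(CONFIG_DEFAULTS, user)
  if (vals$dt <= 0) stop("configuration key dt must be positive")
  if (vals$zeta < 0) stop("configuration key zeta must be non-negative")
  build <- build_config(box_lengths = vals$box_lengths, mesh = vals$mesh,
                        bead_spacing = vals$bead_spacing, n_rods = vals$n_rods,
                        rod_N = vals$rod_N, rod_class = vals$rod_class,
                        rod_ka = vals$rod_ka, seed = vals$seed,
                        min_insert_gap = vals$min_insert_gap)
  ff <- force_field(rod_class = vals$rod_class, rod_ka = vals$rod_ka,
                    epsilon = vals$epsilon, sigma_cn = vals$sigma_cn,
                    rcut_factor = vals$rcut_factor, kb = vals$kb, r0 = vals$r0,
                    ka_network = vals$ka_network, theta0 = vals$theta0,
                    k_tether = vals$k_tether)
  icfg <- integrator_config(dt = vals$dt, zeta = vals$zeta,
                            temperature = vals$temperature,
                            n_steps = vals$n_steps,
                            save_stride = vals$save_stride, seed = vals$seed,
                            equilibration = vals$equilibration,
                            thermostat_off = vals$thermostat_off,
                            mass = vals$mass, skin = vals$skin)
  list(build = build, forcefield = ff, integrator = icfg, values = vals)
}
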