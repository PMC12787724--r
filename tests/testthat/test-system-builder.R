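# Combinatorial oracle for a periodic cubic lattice: n nodes, 3n strands,
# each strand carrying (mesh/spacing - 1) interior beads.
lattice_counts <- function(cells, s) {
  nodes <- prod(cells)
  strands <- 3 * nodes
  list(nodes = nodes, strands = strands, beads = nodes + strands * s,
       bonds = strands * (s + 1), angles = strands * s)
}

test_that("network bead/bond/angle/tether counts match the lattice oracle", {
  for (box in list(c(12, 12, 12), c(12, 18, 12), c(48, 54, 48))) {
    cfg <- build_config(box_lengths = box, n_rods = 0)
    net <- build_network(cfg)
    want <- lattice_counts(box / 6, 5)
    expect_equal(nrow(net$positions), want$beads)
    expect_equal(nrow(net$bonds), want$bonds)
    expect_equal(nrow(net$angles), want$angles)
    expect_equal(length(net$tether_idx), want$nodes)
  }
  # the 2x2x2-cell box explicitly: 8 nodes, 24 strands, 128 beads
  net <- build_network(build_config(box_lengths = c(12, 12, 12), n_rods = 0))
  expect_equal(nrow(net$positions), 128)
  # the production box: 576 nodes, 1728 strands, 9216 beads
  net <- build_network(build_config(box_lengths = c(48, 54, 48), n_rods = 0))
  expect_equal(nrow(net$positions), 9216)
})

test_that("network geometry invariants hold", {
  cfg <- build_config(box_lengths = c(12, 18, 12), n_rods = 0)
  net <- build_network(cfg)
  # wrapped positions in [0, box)
  for (k in 1:3) {
    expect_true(all(net$positions[, k] >= 0 & net$positions[, k] < net$box_lengths[k]))
  }
  # every interior strand bead has exactly 2 bonds; junctions have 6
  deg <- tabulate(c(net$bonds), nbins = nrow(net$positions))
  junction <- seq_along(net$tether_idx)
  expect_true(all(deg[junction] == 6))
  expect_true(all(deg[-junction] == 2))
  # no duplicate bonds
  key <- paste(pmin(net$bonds[, 1], net$bonds[, 2]),
               pmax(net$bonds[, 1], net$bonds[, 2]))
  expect_equal(anyDuplicated(key), 0L)
  # tethers anchor junctions at their own initial positions
  expect_equal(unname(net$tether_anchor),
               unname(net$positions[net$tether_idx, ] +
                      sweep(net$image_counts[net$tether_idx, , drop = FALSE],
                            2, net$box_lengths, "*")))
})

test_that("non-commensurate box or mesh is rejected", {
  expect_error(build_config(box_lengths = c(13, 12, 12)), "multiple")
  expect_error(build_config(mesh = 2.5), "multiple")
})

test_that("rod insertion appends the right beads, bonds and angles", {
  cfg <- build_config(box_lengths = c(48, 54, 48), n_rods = 80, rod_N = 10,
                      rod_class = "thin", seed = 7)
  net <- build_network(cfg)
  sys <- insert_rods(net, cfg)
  expect_equal(sum(sys$species == "rod_thin"), 800)
  expect_equal(nrow(sys$bonds) - nrow(net$bonds), 80 * 9)
  expect_equal(nrow(sys$angles) - nrow(net$angles), 80 * 8)
  expect_equal(max(sys$molecule_id), 80)
  # each rod is a contiguous chain of N beads
  expect_equal(as.integer(table(sys$molecule_id[sys$molecule_id > 0])),
               rep(10L, 80))
})

test_that("insertion respects the minimum gap and is seeded-deterministic", {
  cfg <- build_config(box_lengths = c(12, 12, 12), n_rods = 2, rod_N = 5,
                      seed = 3)
  s1 <- build_system(cfg)
  s2 <- build_system(cfg)
  expect_identical(s1$positions, s2$positions)
  # min-image pair distances: rod-network >= 0.9*sigma_cn, rod-rod >= 0.9
  pos <- s1$positions + sweep(s1$image_counts, 2, s1$box_lengths, "*")
  rod <- which(s1$molecule_id > 0)
  net <- which(s1$molecule_id == 0)
  mi <- function(d) d - s1$box_lengths * round(d / s1$box_lengths)
  for (q in rod) {
    dn <- t(apply(pos[net, ], 1, function(p) mi(pos[q, ] - p)))
    expect_gte(min(sqrt(rowSums(dn^2))), 0.9 * 2)
    other <- setdiff(rod, which(s1$molecule_id == s1$molecule_id[q]))
    if (length(other)) {
      dr <- t(apply(pos[other, , drop = FALSE], 1, function(p) mi(pos[q, ] - p)))
      expect_gte(min(sqrt(rowSums(dr^2))), 0.9)
    }
  }
})

test_that("zero rods is the identity and translation+rewrap is idempotent", {
  cfg <- build_config(box_lengths = c(12, 12, 12), n_rods = 0)
  net <- build_network(cfg)
  expect_identical(insert_rods(net, cfg), net)
  shifted <- net
  shifted$positions <- sweep(net$positions, 2, net$box_lengths, "+")
  w <- netrod:::wrap_positions(shifted$positions, net$box_lengths)
  expect_equal(w$wrapped, net$positions, tolerance = 1e-12)
})

test_that("standard rod counts follow the fixed bead budget", {
  expect_equal(default_rod_count(10, "thin"), 80L)
  expect_equal(default_rod_count(25, "thick"), 16L)
  expect_equal(default_rod_count(15, "thin"), 53L)
  expect_equal(default_rod_count(20, "thick"), 20L)
})
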