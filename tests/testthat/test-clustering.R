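two_state_traj <- function(pattern, jitter = 0, seed = 9) {
  fr <- two_basin_frames()
  set.seed(seed)
  F <- length(pattern)
  n <- nrow(fr$A)
  coords <- array(0, c(F, n, 3))
  for (f in seq_len(F)) {
    base <- if (pattern[f] == 1) fr$A else fr$B
    coords[f, , ] <- base + jitter * matrix(rnorm(3 * n), n, 3)
  }
  trajectory(coords, dt = 0.1)
}

test_that("identical frames collapse to a single full-occupancy cluster", {
  tr <- two_state_traj(rep(1, 12))
  net <- leader_cluster(tr, cutoff = 1.5)
  expect_length(net$leaders, 1)
  expect_equal(net$occupancy, 12L)
  expect_equal(unname(transition_matrix(net)), matrix(1, 1, 1))
})

test_that("alternating two-basin trajectory yields two leaders with hand-counted transitions", {
  pattern <- rep(c(1, 2), 10)       # strict alternation, 20 frames
  tr <- two_state_traj(pattern)
  net <- leader_cluster(tr, cutoff = 1.5)
  expect_length(net$leaders, 2)
  expect_equal(net$assignment, rep(c(1L, 2L), 10))
  # hand count: 1->2 ten times, 2->1 nine times, no self transitions
  expect_equal(net$counts, matrix(c(0L, 9L, 10L, 0L), 2, 2))
  P <- transition_matrix(net)
  expect_equal(P, matrix(c(0, 1, 1, 0), 2, 2))
  # a cutoff above the max pairwise RMSD collapses everything
  net1 <- leader_cluster(tr, cutoff = 10)
  expect_length(net1$leaders, 1)
})

test_that("network invariants hold on a dwelling trajectory", {
  pattern <- c(rep(1, 15), rep(2, 15), rep(1, 10), rep(2, 10))
  tr <- two_state_traj(pattern, jitter = 0.1)
  net <- leader_cluster(tr, cutoff = 1.5)
  expect_equal(sum(net$occupancy), 50L)
  expect_equal(length(net$assignment), 50L)
  # row sums of counts equal occupancy minus trajectory-end correction
  last <- net$assignment[50]
  expected <- net$occupancy
  expected[last] <- expected[last] - 1L
  expect_equal(rowSums(net$counts), as.numeric(expected))
})

test_that("leader count is non-increasing in the cutoff", {
  tt <- tiny_tetramer()
  U <- orthogonalize_modes(
    localized_modes(tt$system$natoms, list(tt$loopA), matrix(c(1, 0, 0), 1)),
    tt$reference)
  bd <- simulate_rigid_bd(tt$system,
                          rigid_tensors(diag(1e-9, 3), diag(1e-9, 3)),
                          400, 0.05, seed = 3)
  tr <- remove_rototranslation(add_internal_ou(bd, U, 4, 0.5, seed = 3))
  counts <- vapply(c(0.05, 0.15, 0.3, 0.6, 1.2),
                   function(cu) length(leader_cluster(tr, cutoff = cu)$leaders),
                   0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(leader_cluster(tr, cutoff = -1), "positive")
})

test_that("MCL identifies communicating blocks exactly on a 6-state chain", {
  # two 3-state blocks, hand-built row-stochastic matrix; within-block
  # mixing dominates the self-transitions so the kinetic basins (not the
  # individual states) are the attracting structures
  P <- matrix(0, 6, 6)
  blockA <- matrix(c(0.4, 0.3, 0.3, 0.3, 0.4, 0.3, 0.3, 0.3, 0.4), 3, 3,
                   byrow = TRUE)
  P[1:3, 1:3] <- blockA
  P[4:6, 4:6] <- blockA
  lab <- markov_cluster(P)
  expect_length(unique(lab), 2)
  expect_length(unique(lab[1:3]), 1)
  expect_length(unique(lab[4:6]), 1)
  expect_false(lab[1] == lab[4])
  # identity matrix: every state its own macrostate
  expect_equal(markov_cluster(diag(5)), 1:5)
  # fully uniform matrix: one macrostate
  expect_length(unique(markov_cluster(matrix(1 / 4, 4, 4))), 1)
  # input validation
  expect_error(markov_cluster(matrix(c(1, 1, 0, 1), 2, 2)), "row-stochastic")
  expect_error(markov_cluster(diag(4), expansion = 1), "expansion")
  expect_error(markov_cluster(diag(4), inflation = 1), "inflation")
})

test_that("cluster count increases across a synthetic temperature ladder", {
  tt <- tiny_tetramer()
  loop_sets <- lapply(c("A", "B", "C", "D"), function(ch)
    select_atoms(tt$system, chains = ch, resno_range = tt$loop_range))
  U <- orthogonalize_modes(localized_modes(tt$system$natoms, loop_sets),
                           tt$reference)
  # amplitude ladder set from target independent-frame RMSD levels
  # bracketing the 1.5 A cutoff: with 4 orthonormal modes over N atoms the
  # expected pair RMSD is sigma * sqrt(8/N)
  sigmas <- c(0.6, 1.5, 3.0) * sqrt(tt$system$natoms / 8)
  counts <- vapply(seq_along(sigmas), function(i) {
    bd <- simulate_rigid_bd(tt$system,
                            rigid_tensors(diag(1e-9, 3), diag(1e-9, 3)),
                            1200, 0.05, seed = 20)
    tr <- add_internal_ou(bd, U, rep(sigmas[i]^2, 4), rep(1, 4),
                          seed = 21)
    length(leader_cluster(remove_rototranslation(tr), cutoff = 1.5)$leaders)
  }, 0L)
  expect_true(all(diff(counts) > 0))
})

test_that("networks export to GraphML and GEXF and round-trip", {
  pattern <- c(rep(1, 10), rep(2, 10), rep(1, 5))
  tr <- two_state_traj(pattern)
  net <- kinetic_network(leader_cluster(tr, cutoff = 1.5))
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), sum(net$counts > 0))
  expect_equal(sort(igraph::V(g)$occupancy), sort(net$occupancy))
  gexf <- tempfile(fileext = ".gexf")
  export_network(net, gexf, "gexf")
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), 2)
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), sum(net$counts > 0))
  empty <- net
  empty$leaders <- integer(0)
  expect_error(export_network(empty, tempfile(), "gexf"), "empty")
})

test_that("assignment CSV records frame, leader and macrostate", {
  tr <- two_state_traj(rep(c(1, 2), 6))
  net <- kinetic_network(leader_cluster(tr, cutoff = 1.5))
  f <- tempfile(fileext = ".csv")
  write_assignment_csv(net, f)
  df <- read.csv(f)
  expect_named(df, c("frame", "leader", "macrostate"))
  expect_equal(nrow(df), 12)
})
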