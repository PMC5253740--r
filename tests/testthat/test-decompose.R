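test_that("removing translation from a uniformly translating rigid body leaves it static", {
  set.seed(1)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  F <- 20
  coords <- array(0, c(F, 10, 3))
  for (f in 1:F) coords[f, , ] <- base + (f - 1) * c(1, -2, 0.5)[col(base)]
  tr <- trajectory(coords, dt = 0.1)
  out <- remove_translation(tr)
  expect_equal(out$kind, "translation_removed")
  for (f in 2:F) expect_equal(out$coords[f, , ], out$coords[1, , ],
                              tolerance = 1e-12)
  # already-centered input is unchanged
  centered <- remove_translation(out)
  expect_equal(centered$coords, out$coords, tolerance = 1e-12)
})

test_that("superposition recovers a rigid roto-translation exactly, with proper rotations only", {
  set.seed(2)
  ref <- matrix(rnorm(36, sd = 6), 12, 3)
  F <- 8
  coords <- array(0, c(F, 12, 3))
  for (f in 1:F) {
    R <- random_rotation(f)
    coords[f, , ] <- sweep(ref %*% t(R), 2, c(f, 2 * f, -f), "+")
  }
  tr <- trajectory(coords, dt = 0.1)
  out <- remove_rototranslation(tr, reference = ref)
  for (f in 1:F)
    expect_lt(kabsch(matrix(out$coords[f, , ], ncol = 3), ref)$rmsd, 1e-9)
  # mirror image cannot be superposed by a proper rotation
  mir <- ref %*% diag(c(-1, 1, 1))
  k <- kabsch(mir, ref)
  expect_equal(det(k$R), 1, tolerance = 1e-9)
  expect_gt(k$rmsd, 0.5)
  # collinear selections make the rotation ill-defined
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line * 2, line), "degenerate|ill-defined")
})

test_that("roto-translation removal is idempotent and never increases the RMSD", {
  tt <- tiny_tetramer()
  tens <- tiny_tensors(tt)
  tr <- simulate_rigid_bd(tt$system, tens, 200, 0.05, seed = 5)
  f1 <- remove_rototranslation(tr)
  f2 <- remove_rototranslation(f1)
  expect_lt(max(abs(f2$coords - f1$coords)), 1e-8)
  # superposition optimality: per-frame RMSD to the reference never grows
  ref <- matrix(colMeans(matrix(f1$coords, nrow = f1$nframes)), ncol = 1)
  refm <- apply(f1$coords, c(2, 3), mean)
  for (f in c(1, 50, 150)) {
    before <- sqrt(mean(rowSums((matrix(tr$coords[f, , ], ncol = 3) - refm)^2)))
    after <- sqrt(mean(rowSums((matrix(f1$coords[f, , ], ncol = 3) - refm)^2)))
    expect_lte(after, before + 1e-9)
  }
})

test_that("rotation-only BD matches the rigid formula with zeroed translation", {
  tt <- tiny_tetramer()
  tens <- tiny_tensors(tt)
  tens$D_T <- diag(1e-12, 3)
  tr <- simulate_rigid_bd(tt$system, tens, 3e4, 0.05, seed = 9)
  no_t <- remove_translation(tr)
  Q <- c(0.1, 0.2)
  sp <- spectrum_with_error(no_t, tt$system, Q, "auto", n_blocks = 6,
                            n_orientations = 24, max_lag = 1.5)
  rsp <- rigid_body_spectrum(tt$system, tens, Q)
  expect_lt(max(abs(sp$D - rsp$D) / pmax(sp$se, 1e-6)), 4)
})

test_that("internal spectrum vanishes for purely rigid motion", {
  tt <- tiny_tetramer()
  tens <- tiny_tensors(tt)
  tr <- simulate_rigid_bd(tt$system, tens, 5e3, 0.05, seed = 13)
  fitted <- remove_rototranslation(tr)
  sp <- internal_spectrum(fitted, tt$system, c(0.1, 0.2),
                          fit_window = c(0, 1), n_orientations = 16,
                          max_lag = 1)
  expect_lt(max(abs(sp$D)), 1e-4)
  # and a raw trajectory is rejected
  expect_error(internal_spectrum(tr, tt$system, 0.1), "roto-translation-free")
})

test_that("internal OU mode spectrum matches the brute-force propagator oracle", {
  tt <- tiny_tetramer()
  U <- orthogonalize_modes(
    localized_modes(tt$system$natoms, list(tt$loopA), matrix(c(1, 0, 0), 1)),
    tt$reference)
  sig2 <- 4; tau <- 2
  tens0 <- rigid_tensors(diag(1e-9, 3), diag(1e-9, 3))
  bd <- simulate_rigid_bd(tt$system, tens0, 4e4, 0.05, seed = 3)
  tr <- add_internal_ou(bd, U, sig2, tau, seed = 3)
  fitted <- remove_rototranslation(tr)
  Q <- c(0.08, 0.22)
  sp <- spectrum_with_error(fitted, tt$system, Q, "auto", n_blocks = 6,
                            n_orientations = 24, max_lag = 2)
  lags <- seq(0, 2, by = 0.05)
  D_or <- vapply(Q, function(q) {
    v <- ou_isf_oracle(tt$reference, tt$system$b, U[, 1], sig2, tau, q, lags)
    cumulant_fit(isf_curve(q, lags, v / v[1]), "auto")$D_eff
  }, 0)
  expect_lt(max(abs(sp$D - D_or) / pmax(sp$se, 1e-6)), 4)
})

test_that("composition is exact bookkeeping and validates grids", {
  Q <- c(0.1, 0.2, 0.3)
  rigid <- diffusion_spectrum_obj(Q, c(5, 6, 7), component = "rigid_total")
  zero <- diffusion_spectrum_obj(Q, c(0, 0, 0), component = "internal")
  comp <- compose_total(rigid, zero)
  expect_equal(comp$D, rigid$D)
  expect_equal(attr(comp, "component"), "composed")
  intl <- diffusion_spectrum_obj(Q, c(0.2, 0.4, 0.1), component = "internal")
  expect_equal(compose_total(rigid, intl)$D, rigid$D + intl$D)
  other <- diffusion_spectrum_obj(Q + 0.01, c(0, 0, 0), component = "internal")
  expect_error(compose_total(rigid, other), "grids")
})

test_that("excision subsets trajectory and system consistently", {
  tt <- tiny_tetramer(n_res = 6, n_loop = 2)
  tens <- tiny_tensors(tt)
  tr <- simulate_rigid_bd(tt$system, tens, 50, 0.05, seed = 1)
  # removing a range that matches nothing is the identity
  same <- excise_region(tr, tt$system, c(100, 200), mode = "remove")
  expect_equal(same$traj$natoms, tr$natoms)
  expect_equal(same$system$natoms, tt$system$natoms)
  # keeping a single residue keeps its atoms on all chains
  one <- excise_region(tr, tt$system, c(1, 1), mode = "keep_only")
  expect_equal(one$system$natoms, 4)  # one bead per residue, 4 chains
  expect_equal(one$traj$natoms, 4)
  expect_equal(one$traj$kind, "excised")
  # excising the loops removes the internal signal placed on them
  U <- orthogonalize_modes(
    localized_modes(tt$system$natoms, list(tt$loopA), matrix(c(1, 0, 0), 1)),
    tt$reference)
  bd <- simulate_rigid_bd(tt$system,
                          rigid_tensors(diag(1e-9, 3), diag(1e-9, 3)),
                          8e3, 0.05, seed = 8)
  tr2 <- add_internal_ou(bd, U, 4, 2, seed = 8)
  fitted <- remove_rototranslation(tr2)
  cut <- excise_region(fitted, tt$system, tt$loop_range, mode = "remove")
  Qpk <- 0.14
  sp_full <- internal_spectrum(fitted, tt$system, Qpk, "auto",
                               n_orientations = 16, max_lag = 1.5)
  sp_cut <- internal_spectrum(cut$traj, cut$system, Qpk, "auto",
                              n_orientations = 16, max_lag = 1.5)
  expect_lt(sp_cut$D, sp_full$D)
})
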