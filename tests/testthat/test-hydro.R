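kB <- 1.380649e-23

test_that("single-bead tensors reproduce Stokes-Einstein and Stokes-Einstein-Debye", {
  a <- 20; Tk <- 298; eta <- 0.89
  bm <- build_bead_model(NULL, "user_beads", centers = matrix(0, 1, 3),
                         radii = a)
  tens <- diffusion_tensor(bm, Tk, eta)
  D_se <- kB * Tk / (6 * pi * eta * 1e-3 * a * 1e-10) * 1e11
  D_sed <- kB * Tk / (8 * pi * eta * 1e-3 * (a * 1e-10)^3) / 1e9
  expect_lt(max(abs(tens$D_T - diag(D_se, 3))) / D_se, 1e-10)
  expect_lt(max(abs(tens$D_R - diag(D_sed, 3))) / D_sed, 1e-10)
})

test_that("two well-separated beads match the Kirkwood closed form within 1%", {
  a <- 3; r <- 30; Tk <- 298; eta <- 0.89
  bm <- build_bead_model(NULL, "user_beads",
                         centers = rbind(c(0, 0, 0), c(r, 0, 0)), radii = a)
  tens <- diffusion_tensor(bm, Tk, eta)
  D_kirk <- kB * Tk / (12 * pi * eta * 1e-3) *
    (1 / (a * 1e-10) + 1 / (r * 1e-10)) * 1e11
  expect_lt(abs(mean(diag(tens$D_T)) / D_kirk - 1), 0.01)
  # ... and the Kirkwood fallback agrees with its own closed form
  expect_lt(abs(kirkwood_translational_d(bm, Tk, eta) / D_kirk - 1), 1e-10)
})

test_that("bead shells converge monotonically to the Stokes value", {
  R <- 20; Tk <- 298; eta <- 0.89
  D_stokes <- kB * Tk / (6 * pi * eta * 1e-3 * R * 1e-10) * 1e11
  Ds <- vapply(c(50, 150, 400), function(n) {
    arad <- 2 * R / sqrt(n) / 1.8
    bm <- build_bead_model(NULL, "user_beads",
                           centers = fibonacci_directions(n) * R,
                           radii = arad)
    mean(diag(diffusion_tensor(bm, Tk, eta)$D_T))
  }, 0)
  expect_true(all(diff(abs(Ds - D_stokes)) < 0))  # monotone approach
  expect_lt(abs(Ds[3] / D_stokes - 1), 0.02)
})

test_that("tensors are symmetric positive definite with symmetric coupling", {
  tt <- tiny_tetramer()
  tens <- tiny_tensors(tt)
  expect_equal(tens$D_T, t(tens$D_T))
  expect_equal(tens$D_R, t(tens$D_R))
  expect_true(all(eigen(tens$D_T, symmetric = TRUE)$values > 0))
  expect_true(all(eigen(tens$D_R, symmetric = TRUE)$values > 0))
  # at the center of diffusion the coupling block is symmetric
  expect_lt(max(abs(tens$D_C - t(tens$D_C))), 1e-8 * max(abs(tens$D_T)))
})

test_that("rescaling multiplies both tensors and records the factor", {
  tt <- tiny_tetramer()
  tens <- tiny_tensors(tt)
  same <- rescale_tensors(tens, 1)
  expect_equal(same$D_T, tens$D_T)
  up <- rescale_tensors(tens, 1.2)
  expect_equal(eigen(up$D_T)$values, 1.2 * eigen(tens$D_T)$values)
  expect_equal(eigen(up$D_R)$values, 1.2 * eigen(tens$D_R)$values)
  expect_equal(up$rescale_factor, 1.2)
  expect_error(rescale_tensors(tens, 0), "positive")
  expect_error(rescale_tensors(tens, -2), "positive")
})

test_that("bead model construction maps atoms deterministically", {
  tt <- tiny_tetramer(n_res = 5)
  bm <- build_bead_model(tt$system, "one_bead_per_residue", bead_radius = 3)
  expect_equal(nrow(bm$centers), 20)  # 4 chains x 5 residues
  expect_equal(bm$centers[1, ], tt$system$xyz[1, ])  # 1-atom residues
  expect_error(build_bead_model(NULL, "user_beads",
                                centers = matrix(0, 1, 3)), "radii")
  bad <- build_bead_model(NULL, "user_beads",
                          centers = rbind(c(0, 0, 0), c(0, 0, 0)), radii = 2)
  expect_error(diffusion_tensor(bad, 298, 1), "coincident beads 1 and 2")
})

test_that("uniform-b sphere of beads reproduces the analytic sphere form factor", {
  R <- 15
  set.seed(3)
  pts <- matrix(rnorm(3 * 4000), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * R * runif(4000)^(1/3)
  sys <- scattering_system(pts, b = 1)
  Q <- c(0.05, 0.1, 0.15)
  ff <- form_factor(sys, Q, n_orientations = 64) / 4000^2
  sphere <- (3 * (sin(Q * R) - Q * R * cos(Q * R)) / (Q * R)^3)^2
  expect_lt(max(abs(ff - sphere)), 0.02)
})

test_that("rigid-body spectrum limits: point scatterer and b-centroid at origin", {
  tens <- rigid_tensors(diag(c(6, 8, 10)), diag(c(0.01, 0.02, 0.03)))
  one <- scattering_system(matrix(0, 1, 3), b = 1)
  sp <- rigid_body_spectrum(one, tens, c(0.05, 0.1, 0.3))
  expect_equal(sp$D, rep(8, 3), tolerance = 1e-3)  # trace(D_T)/3, rotation absent
  # centered dumbbell at Q -> 0: rotational term vanishes by symmetry
  db <- scattering_system(rbind(c(12, 0, 0), c(-12, 0, 0)), b = 1)
  sp2 <- rigid_body_spectrum(db, tens, c(1e-4, 0.3))
  expect_equal(sp2$D[1], 8, tolerance = 1e-3)
  expect_gt(sp2$D[2], sp2$D[1])   # rotation adds at finite Q
})

test_that("rigid-body spectrum stays within tensor eigenvalue bounds", {
  tt <- tiny_tetramer()
  tens <- tiny_tensors(tt)
  Q <- seq(0.02, 0.4, length.out = 12)
  sp <- rigid_body_spectrum(tt$system, tens, Q, n_orientations = 256)
  expect_true(all(is.finite(sp$D)))
  expect_true(all(sp$D >= min(eigen(tens$D_T)$values) - 1e-9))
  rmax2 <- max(rowSums(sweep(tt$system$xyz, 2, tens$center)^2))
  ceiling_D <- max(eigen(tens$D_T)$values) +
    rmax2 * max(eigen(tens$D_R)$values)
  expect_true(all(sp$D <= ceiling_D))
})

test_that("spherical bead shell has an exactly flat translational component", {
  bm_centers <- fibonacci_directions(80) * 18
  sys <- scattering_system(bm_centers, b = 1)
  tens <- diffusion_tensor(build_bead_model(NULL, "user_beads",
                                            centers = bm_centers, radii = 2),
                           298, 0.89)
  sp <- rigid_body_spectrum(sys, tens, seq(0.05, 0.3, length.out = 6),
                            n_orientations = 256, components = TRUE)
  spread <- diff(range(sp$translation$D)) / mean(sp$translation$D)
  expect_lt(spread, 5e-3)
})

test_that("tensors serialize to JSON with units", {
  tens <- rigid_tensors(diag(5, 3), diag(0.01, 3))
  f <- tempfile(fileext = ".json")
  write_tensors_json(tens, f)
  js <- jsonlite::read_json(f)
  expect_equal(unlist(js$D_T[[1]])[1], 5)
  expect_equal(js$units$D_T, "A^2/ns")
})
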