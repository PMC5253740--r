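test_that("loop CV of single-atom loops is the plain interatomic distance", {
  sys <- scattering_system(rbind(c(0, 0, 0), c(10, 0, 0)), b = 1,
                           chain = c("A", "B"), resno = c(1, 1))
  coords <- array(0, c(5, 2, 3))
  for (f in 1:5) coords[f, 2, 1] <- 10 + f
  tr <- trajectory(coords, dt = 0.1)
  cv <- loop_cv(tr, sys, c(1, 1), "A", "B")
  expect_equal(cv$values, 11:15)
  # sum convention scales by the pair count (here 1: identical)
  expect_equal(loop_cv(tr, sys, c(1, 1), "A", "B", reduce = "sum")$values,
               cv$values)
})

test_that("static toy tetramer loop CVs sit at the constructed centroid distances", {
  tt <- tiny_tetramer()
  # constructed centroids are exact
  cd <- as.matrix(dist(tt$loop_centroids))
  expect_equal(sort(unique(round(cd[cd > 0], 6))), c(45, 60, 75))
  coords <- array(rep(tt$reference, each = 3), c(3, tt$system$natoms, 3))
  tr <- trajectory(coords, dt = 0.1)
  pairs <- list(c("A", "B"), c("A", "C"), c("A", "D"))
  d <- vapply(pairs, function(p)
    loop_cv(tr, tt$system, tt$loop_range, p[1], p[2])$values[1], 0)
  # the mean-over-pairs CV deviates from the centroid distance only by the
  # O(spread^2/d) curvature of the loop bead clouds
  expect_equal(d, c(45, 60, 75), tolerance = 0.01)
  # static trace is constant; its ACF is undefined
  cv <- loop_cv(tr, tt$system, tt$loop_range, "A", "B")
  expect_error(autocorrelation(cv), "zero variance")
  expect_error(harmonic_diffusivity(cv), "zero variance")
})

test_that("autocorrelation is flat for white noise and exponential for OU", {
  set.seed(31)
  wn <- cv_trace(50 + rnorm(20000), dt = 0.1)
  ac <- autocorrelation(wn, max_lag = 50)
  expect_equal(ac$acf[1], 1)
  expect_lt(max(abs(ac$acf[-1])), 0.05)
  # OU trace, tau = 2 ns
  tau <- 2; dt <- 0.05; F <- 60000
  phi <- exp(-dt / tau)
  set.seed(32)
  x <- as.numeric(stats::filter(c(rnorm(1), sqrt(1 - phi^2) * rnorm(F - 1)),
                                phi, method = "recursive"))
  ou <- cv_trace(50 + 2 * x, dt = dt)
  ac2 <- autocorrelation(ou, max_lag = 100)
  expect_lt(max(abs(ac2$acf - exp(-ac2$t / tau))), 0.06)
})

test_that("harmonic diffusivity inverts the OU identity var = D * tau", {
  tau <- 2; sig2 <- 4; dt <- 0.05; F <- 50000
  phi <- exp(-dt / tau)
  set.seed(33)
  x <- as.numeric(stats::filter(c(rnorm(1), sqrt(1 - phi^2) * rnorm(F - 1)),
                                phi, method = "recursive"))
  tr <- cv_trace(60 + sqrt(sig2) * x, dt = dt)
  hd <- harmonic_diffusivity(tr)
  expect_equal(hd$variance, sig2, tolerance = 0.15)
  expect_equal(hd$tau, tau, tolerance = 0.15)
  expect_equal(hd$D, sig2 / tau, tolerance = 0.3)
  expect_equal(hd$D, hd$variance / hd$tau)   # exact identity
  # relabeling the timestep: tau doubles, D halves
  tr2 <- cv_trace(tr$values, dt = 2 * dt)
  hd2 <- harmonic_diffusivity(tr2)
  expect_equal(hd2$tau, 2 * hd$tau, tolerance = 1e-10)
  expect_equal(hd2$D, hd$D / 2, tolerance = 1e-10)
  expect_equal(hd2$variance, hd$variance)
  # a decorrelation time the trace cannot support is refused
  # (a two-level step correlates over a third of the trace)
  step <- cv_trace(c(rep(10, 50), rep(12, 50)), dt = 0.05)
  expect_error(harmonic_diffusivity(step), "longer trace")
})

test_that("harmonic diffusivity is unbiased over seeds on OU ground truth", {
  tau <- 1.5; sig2 <- 3; dt <- 0.05; F <- round(150 * tau / dt)
  phi <- exp(-dt / tau)
  est <- t(vapply(1:20, function(s) {
    set.seed(200 + s)
    x <- as.numeric(stats::filter(c(rnorm(1), sqrt(1 - phi^2) * rnorm(F - 1)),
                                  phi, method = "recursive"))
    hd <- harmonic_diffusivity(cv_trace(40 + sqrt(sig2) * x, dt = dt))
    c(hd$variance, hd$tau, hd$D)
  }, numeric(3)))
  mu <- colMeans(est)
  se <- apply(est, 2, sd) / sqrt(20)
  # D = var/tau: the O(tau/T) finite-trace biases of numerator and
  # denominator cancel, so D is unbiased within 2 SE
  expect_lt(abs(mu[3] - sig2 / tau) / se[3], 2)
  # var and tau individually carry a small O(tau/T) downward bias; their
  # means stay within 10% of truth at this trace length
  expect_lt(abs(mu[1] - sig2) / sig2, 0.1)
  expect_lt(abs(mu[2] - tau) / tau, 0.1)
})

test_that("active-site classification follows the decision list on built frames", {
  # minimal geometry: arg tip (1), arg base (2), asp (3), his (4), pocket (5)
  base <- rbind(c(0, 0, 0),      # arg guanidinium (tip, atom 1)
                c(-3, 0, 0),     # arg CB-like base (atom 2)
                c(10, 0, 0),     # asp carboxylate (atom 3)
                c(10, 8, 0),     # his (atom 4)
                c(4, 0, 0))      # pocket center marker (atom 5)
  crit <- list(arg_atoms = 1, asp_atoms = 3, his_atoms = 4,
               arg_vec_atoms = c(2, 1), pocket_atoms = 5,
               saltbridge_cutoff = 4, contact_cutoff = 4)
  mk <- function(...) {
    frames <- list(...)
    coords <- array(0, c(length(frames), 5, 3))
    for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
    trajectory(coords, dt = 0.1)
  }
  ip <- base; ip[1, ] <- c(10 - 2.8, 0, 0)       # ion pair at 2.8 A
  r_state <- base; r_state[4, ] <- c(10, 3.5, 0)  # asp-his contact
  t_out <- base; t_out[1, ] <- c(-8, 0, 0)        # arg points out of pocket
  res <- classify_active_site(mk(ip, r_state, t_out), NULL, crit)
  expect_equal(as.character(res$states), c("T_IP", "R", "T_out"))
  expect_equal(unname(res$occupancy), rep(1 / 3, 3))
  expect_equal(res$n_ambiguous, 0)
  # labels are invariant under rigid roto-translation of the frames
  R <- random_rotation(5)
  rot <- mk(sweep(ip %*% t(R), 2, c(3, -2, 7), "+"),
            sweep(r_state %*% t(R), 2, c(3, -2, 7), "+"),
            sweep(t_out %*% t(R), 2, c(3, -2, 7), "+"))
  res2 <- classify_active_site(rot, NULL, crit)
  expect_equal(res2$states, res$states)
  expect_error(classify_active_site(mk(base, base), NULL,
                                    list(arg_atoms = 1)),
               "missing fields")
})
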