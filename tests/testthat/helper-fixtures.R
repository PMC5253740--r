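# Shared fixtures: all built in code, deterministic seeds.

tiny_tetramer <- function(n_res = 10, n_loop = 3, seed = 2) {
  tt <- toy_tetramer(n_res, loop_spec = list(n_loop = n_loop,
                                             distances = c(45, 60, 75)),
                     seed = seed)
  tt$loopA <- select_atoms(tt$system, chains = "A",
                           resno_range = tt$loop_range)
  tt$loopB <- select_atoms(tt$system, chains = "B",
                           resno_range = tt$loop_range)
  tt
}

tiny_tensors <- function(tt, temperature = 298) {
  beads <- build_bead_model(tt$system, "one_bead_per_residue")
  diffusion_tensor(beads, temperature, d2o_viscosity(temperature))
}

# brute-force coherent ISF of a single body-frame OU mode on a static
# structure: Gaussian pair propagator, averaged over the same Fibonacci
# direction set as the implementation
ou_isf_oracle <- function(ref, b, u, sig2, tau, Q, lags, n_orient = 24) {
  dirs <- fibonacci_directions(n_orient)
  um <- matrix(u, ncol = 3, byrow = TRUE)
  vals <- vapply(lags, function(t) {
    rho <- exp(-t / tau)
    tot <- 0
    for (m in seq_len(n_orient)) {
      q <- Q * dirs[m, ]
      a <- as.numeric(um %*% q)
      ph <- as.numeric(ref %*% q)
      G <- exp(-sig2 / 2 * (outer(a^2, a^2, "+") - 2 * rho * outer(a, a)))
      tot <- tot + sum((b %o% b) * cos(outer(ph, ph, "-")) * G)
    }
    tot / n_orient
  }, 0)
  vals / vals[1]
}

# linearized gain of the A-B loop CV with respect to a mode amplitude
cv_gain <- function(tt, U, eps = 1e-4) {
  ref <- tt$reference
  d_at <- function(xyz) {
    vapply(seq_along(tt$loopA), function(i)
      sqrt(sum((xyz[tt$loopA[i], ] - xyz[tt$loopB[i], ])^2)), 0)
  }
  refp <- ref + eps * matrix(U[, 1], ncol = 3, byrow = TRUE)
  mean(d_at(refp) - d_at(ref)) / eps
}

# a structure pair with a purely internal displacement of given RMSD
two_basin_frames <- function(n = 20, rmsd = 3, seed = 4) {
  set.seed(seed)
  A <- matrix(rnorm(3 * n, sd = 6), n, 3)
  u <- orthogonalize_modes(matrix(rnorm(3 * n), 3 * n, 1), A)
  B <- A + rmsd * sqrt(n) * matrix(u, ncol = 3, byrow = TRUE)
  list(A = A, B = B)
}

# F x 3n atom-major (x1,y1,z1,...) view of an F x n x 3 array
flatten_lab <- function(arr) {
  F <- dim(arr)[1]; n <- dim(arr)[2]
  M <- matrix(arr, nrow = F)                       # coordinate-major
  M[, as.vector(t(matrix(seq_len(3 * n), n, 3))), drop = FALSE]
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
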