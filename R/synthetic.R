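# independent per-stream seeds derived from one user seed (keeps the
# rigid-body noise stream unchanged when internal modes are added)
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + tag * 7919 + 12345) %% 2147483647)
}

#' Rigid-body Brownian dynamics trajectory
#'
#' Euler-Maruyama propagation of an anisotropic rigid body: per step, a
#' body-frame translational displacement with covariance \eqn{2 D^T dt}
#' rotated to the lab frame, and a rotational kick by a random rotation
#' vector with covariance \eqn{2 D^R dt} composed onto the current
#' orientation (re-orthonormalized every step). Translation and rotation
#' noises come from independent seed streams derived from `seed`, so other
#' generator stages never perturb them.
#'
#' @param system a [scattering_system()] giving the body-frame structure.
#' @param tensors a `rigid_tensors` ground truth; coordinates are taken
#'   relative to `tensors$center`.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing in ns; must satisfy
#'   `dt * max(eigen(D_R)) < 0.01` so rotational steps stay small.
#' @param seed integer seed (reproducible: same seed, same trajectory).
#' @return A `traj` (kind `"raw"`) carrying the orientation history in
#'   `$rotations` and the ground truth in `attr(, "ground_truth")`.
#' @export
simulate_rigid_bd <- function(system, tensors, n_frames, dt, seed = 1) {
  stopifnot(inherits(system, "scat_system"), inherits(tensors, "rigid_tensors"))
  max_dr <- max(eigen(tensors$D_R, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (dt * max_dr >= 0.01)
    stop(sprintf("dt too large: dt * max eig(D_R) = %.3g >= 0.01 rad^2",
                 dt * max_dr))
  r0 <- sweep(system$xyz, 2, tensors$center)
  chol_lower <- function(M) {
    ev <- eigen(M, symmetric = TRUE)
    if (all(ev$values > 1e-14 * max(ev$values, 1))) t(chol(M)) else {
      # semi-definite tensors (e.g. zeroed D_T) handled via eigen square root
      ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3) %*% t(ev$vectors)
    }
  }
  Bt <- chol_lower(2 * tensors$D_T * dt)
  Br <- chol_lower(2 * tensors$D_R * dt)
  set.seed(derive_seed(seed, 1L))
  zt <- matrix(rnorm(3 * (n_frames - 1)), n_frames - 1, 3)
  set.seed(derive_seed(seed, 2L))
  zr <- matrix(rnorm(3 * (n_frames - 1)), n_frames - 1, 3)
  res <- cpp_rigid_bd(r0, Bt, Br, zt, zr)
  out <- trajectory(res$coords, dt = dt, kind = "raw",
                    provenance = sprintf("rigid-body BD, seed %d", seed),
                    rotations = res$rotations)
  attr(out, "ground_truth") <- list(tensors = tensors, dt = dt, seed = seed)
  out
}

#' Superimpose Ornstein-Uhlenbeck internal modes on a rigid trajectory
#'
#' Adds independent OU processes along orthonormalized 3N mode directions in
#' the body frame (rotated with the body, so removal of roto-translation by
#' superposition recovers them in expectation). The OU update is exact:
#' \eqn{x(t+dt) = x e^{-dt/\tau} + N(0, \sigma^2 (1 - e^{-2 dt/\tau}))},
#' giving stationary variance \eqn{\sigma^2} and relaxation time \eqn{\tau}.
#' Each mode has its own seed stream.
#'
#' @param traj a trajectory from [simulate_rigid_bd()] (its orientation
#'   history is required; a plain trajectory is treated as unrotated).
#' @param mode_directions 3N x K matrix of mode directions (atom-major
#'   x1,y1,z1,...; orthonormalized internally).
#' @param variances stationary variances \eqn{\sigma_i^2} (A^2), length K.
#' @param taus relaxation times (ns), length K.
#' @param seed integer seed.
#' @return A `traj` like the input with internal motion added; ground truth
#'   in `attr(, "ground_truth")$modes`.
#' @export
add_internal_ou <- function(traj, mode_directions, variances, taus, seed = 1) {
  stopifnot(inherits(traj, "traj"))
  U <- as.matrix(mode_directions)
  K <- ncol(U)
  if (nrow(U) != 3 * traj$natoms)
    stop("mode_directions must have 3 * natoms rows")
  stopifnot(length(variances) == K, length(taus) == K)
  if (any(variances < 0) || any(taus <= 0))
    stop("variances must be >= 0 and taus > 0")
  U <- qr.Q(qr(U))[, seq_len(K), drop = FALSE]
  F <- traj$nframes
  X <- matrix(0, F, K)
  for (k in seq_len(K)) {
    if (variances[k] == 0) next
    s2 <- variances[k]
    phi <- exp(-traj$dt / taus[k])
    set.seed(derive_seed(seed, 100L + k))
    z <- rnorm(F)
    innov <- c(sqrt(s2) * z[1], sqrt(s2 * (1 - phi^2)) * z[-1])
    X[, k] <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  rot <- traj$rotations
  if (is.null(rot))
    rot <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = F), F, 9)
  coords <- cpp_add_modes(traj$coords, rot, U, X)
  out <- trajectory(coords, dt = traj$dt, kind = traj$kind,
                    provenance = paste0(traj$provenance,
                                        sprintf(" | +%d OU modes", K)),
                    rotations = traj$rotations)
  gt <- attr(traj, "ground_truth")
  gt$modes <- list(directions = U, variances = variances, taus = taus,
                   seed = seed)
  attr(out, "ground_truth") <- gt
  out
}

#' Toy tetramer with tagged catalytic loops
#'
#' Builds a four-subunit bead structure with D2-like symmetry: one compact
#' Gaussian bead cloud per subunit (one bead per "residue"), replicated by
#' the three two-fold rotations, with a designated loop residue stretch per
#' subunit whose centroids sit at exactly the requested pairwise distances
#' (defaults 45/60/75 A, the rectangle that spans the 36-75 A loop-distance
#' range typical of an LDH-sized tetramer). Deterministic given the seed.
#' This is a synthetic stand-in geometry, not a crystal structure.
#'
#' @param n_residues_per_subunit beads per subunit (loop included).
#' @param loop_spec list: `n_loop` (residues in the loop, default 5) and
#'   `distances` (the three distinct loop-centroid distances
#'   `c(d12, d13, d14)` under D2 symmetry, default `c(45, 60, 75)`).
#' @param seed integer seed for the subunit cloud.
#' @param subunit_radius spatial spread of a subunit (A, default 12).
#' @return List: `system` (a `scat_system`, chains A-D, uniform b),
#'   `reference` (N x 3 coordinates), `loop_range` (residue-number range of
#'   the loop), `loop_centroids` (4 x 3).
#' @export
toy_tetramer <- function(n_residues_per_subunit = 25,
                         loop_spec = list(n_loop = 5,
                                          distances = c(45, 60, 75)),
                         seed = 1, subunit_radius = 12) {
  n_loop <- loop_spec$n_loop %||% 5
  d <- loop_spec$distances %||% c(45, 60, 75)
  stopifnot(n_loop >= 1, n_loop < n_residues_per_subunit, length(d) == 3)
  s <- sum(d^2) / 8
  abc2 <- s - d^2 / 4
  if (any(abc2 < -1e-9))
    stop("requested loop distances are not realizable under D2 symmetry")
  abc <- sqrt(pmax(abc2, 0))
  p1 <- abc                                  # loop centroid of subunit A
  rots <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
               diag(c(-1, -1, 1)))
  centroids <- t(vapply(rots, function(R) as.numeric(R %*% p1), numeric(3)))
  set.seed(derive_seed(seed, 7L))
  n_core <- n_residues_per_subunit - n_loop
  core <- matrix(rnorm(3 * n_core, sd = subunit_radius / 2), n_core, 3)
  core <- sweep(core, 2, colMeans(core))
  core <- sweep(core, 2, 0.7 * p1, "+")      # subunit body inside the loop
  loop <- matrix(rnorm(3 * n_loop, sd = 1.5), n_loop, 3)
  loop <- sweep(loop, 2, colMeans(loop))
  loop <- sweep(loop, 2, p1, "+")            # loop centroid exactly at p1
  sub1 <- rbind(core, loop)
  xyz <- do.call(rbind, lapply(rots, function(R) sub1 %*% t(R)))
  chains <- rep(c("A", "B", "C", "D"), each = n_residues_per_subunit)
  resno <- rep(seq_len(n_residues_per_subunit), times = 4)
  sys <- scattering_system(xyz, b = 1, element = "C", chain = chains,
                           resno = resno, resid = "GLY")
  list(system = sys, reference = xyz,
       loop_range = c(n_core + 1L, n_residues_per_subunit),
       loop_centroids = centroids)
}

#' Mode directions localized on given atoms
#'
#' Convenience builder of 3N mode-direction vectors that displace a set of
#' atoms along a common direction (one mode per entry), e.g. to place all
#' internal variance on the loop residues of a [toy_tetramer()].
#'
#' @param natoms total atom count.
#' @param atom_sets list of atom index vectors, one mode each.
#' @param directions K x 3 matrix of displacement directions (default: x,
#'   y, z cycled).
#' @return 3N x K matrix (atom-major) suitable for [add_internal_ou()].
#' @export
localized_modes <- function(natoms, atom_sets, directions = NULL) {
  K <- length(atom_sets)
  if (is.null(directions))
    directions <- diag(3)[rep(1:3, length.out = K), , drop = FALSE]
  U <- matrix(0, 3 * natoms, K)
  for (k in seq_len(K)) {
    for (j in atom_sets[[k]]) U[(3 * j - 2):(3 * j), k] <- directions[k, ]
  }
  U
}

#' Project mode directions onto the internal subspace
#'
#' Removes the rigid-body (3 translation + 3 rotation) components of a set
#' of 3N mode-direction vectors about a reference structure, then
#' orthonormalizes. Modes built this way carry no net roto-translation, so
#' frame-wise superposition removes none of their variance (to first order
#' in the amplitude) and a PCA of the fitted trajectory recovers the
#' imposed variances directly.
#'
#' @param U 3N x K matrix of raw mode directions (atom-major).
#' @param reference N x 3 reference coordinates.
#' @return 3N x K orthonormal matrix of purely internal directions.
#' @export
orthogonalize_modes <- function(U, reference) {
  n <- nrow(reference)
  stopifnot(nrow(U) == 3 * n)
  ctr <- sweep(reference, 2, colMeans(reference))
  rigid <- matrix(0, 3 * n, 6)
  for (k in 1:3) rigid[seq(k, 3 * n, by = 3), k] <- 1
  for (j in seq_len(n)) {
    r <- ctr[j, ]
    rigid[(3 * j - 2):(3 * j), 4] <- c(0, r[3], -r[2])
    rigid[(3 * j - 2):(3 * j), 5] <- c(-r[3], 0, r[1])
    rigid[(3 * j - 2):(3 * j), 6] <- c(r[2], -r[1], 0)
  }
  Rq <- qr.Q(qr(rigid))
  Uproj <- U - Rq %*% (t(Rq) %*% U)
  if (any(colSums(Uproj^2) < 1e-12))
    stop("a mode direction is entirely rigid-body; nothing internal remains")
  qr.Q(qr(Uproj))[, seq_len(ncol(U)), drop = FALSE]
}

#' Synthetic SAXS concentration series
#'
#' Generates \eqn{I(Q, C) = C F(Q) (1 - \alpha C e^{-(Q/Q_0)^2})} plus
#' optional Gaussian noise; the imposed structure factor
#' \eqn{S(Q; C) = 1 - \alpha C e^{-(Q/Q_0)^2}} is recorded as ground truth.
#'
#' @param form_factor function of Q returning F(Q) (> 0), or a single
#'   radius R (A) selecting the uniform-sphere form factor.
#' @param alpha interaction strength per concentration (1/(mg/ml)).
#' @param Q0 width of the low-Q suppression (1/Angstrom).
#' @param concentrations positive concentrations (mg/ml).
#' @param Q_grid Q grid (1/Angstrom).
#' @param noise relative Gaussian noise level (default 0).
#' @param seed integer seed.
#' @return A [saxs_series()] with attribute `ground_truth_S` (function of
#'   Q and C).
#' @export
synthetic_saxs_series <- function(form_factor, alpha, Q0, concentrations,
                                  Q_grid = seq(0.01, 0.3, length.out = 60),
                                  noise = 0, seed = 1) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  ff <- if (is.function(form_factor)) form_factor else {
    R <- form_factor
    function(Q) (3 * (sin(Q * R) - Q * R * cos(Q * R)) / (Q * R)^3)^2
  }
  Fq <- ff(Q_grid)
  S_true <- function(Q, C) 1 - alpha * C * exp(-(Q / Q0)^2)
  set.seed(derive_seed(seed, 3L))
  curves <- lapply(concentrations, function(C) {
    I <- C * Fq * S_true(Q_grid, C)
    if (noise > 0) I <- I * (1 + noise * rnorm(length(I)))
    data.frame(Q = Q_grid, I = pmax(I, 0))
  })
  names(curves) <- concentrations
  out <- saxs_series(curves)
  attr(out, "ground_truth_S") <- S_true
  out
}

#' Ideal single-exponential NSE curves
#'
#' \eqn{I(Q,t)/I(Q,0) = e^{-D(Q) Q^2 t}} plus optional Gaussian noise on the
#' t > 0 points — fixtures with known cumulants for the fitting stage.
#'
#' @param D_profile function of Q giving D (A^2/ns), or a vector matching
#'   `Q_list`.
#' @param Q_list Q moduli (1/Angstrom).
#' @param lags time lags in ns; must start at 0.
#' @param noise absolute Gaussian noise sd (default 0).
#' @param seed integer seed.
#' @return List of [isf_curve()].
#' @export
ideal_nse_curves <- function(D_profile, Q_list, lags, noise = 0, seed = 1) {
  if (lags[1] != 0) stop("lags must start at 0")
  D <- if (is.function(D_profile)) D_profile(Q_list) else
    rep_len(D_profile, length(Q_list))
  set.seed(derive_seed(seed, 4L))
  lapply(seq_along(Q_list), function(k) {
    v <- exp(-D[k] * Q_list[k]^2 * lags)
    if (noise > 0) v[-1] <- v[-1] + noise * rnorm(length(v) - 1)
    isf_curve(Q_list[k], lags, v)
  })
}

#' Write a scattering system as a PDB file
#'
#' One CA pseudo-atom per bead; for inspection of synthetic structures.
#'
#' @param system a `scat_system`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_system_pdb <- function(system, file) {
  n <- system$natoms
  bio3d::write.pdb(file = file, xyz = as.numeric(t(system$xyz)),
                   type = rep("ATOM", n), resno = system$atom$resno,
                   resid = system$atom$resid, elety = rep("CA", n),
                   chain = system$atom$chain)
  invisible(file)
}
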