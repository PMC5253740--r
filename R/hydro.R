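skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Build a bead model from a scattering system
#'
#' Maps atoms to hydrodynamic beads. The default mode places one bead at
#' each residue centroid with an effective residue radius, the style used by
#' shell/bead hydrodynamic programs for proteins.
#'
#' @param system a [scattering_system()].
#' @param mode `"one_bead_per_residue"`, `"one_bead_per_atom_heavy"`, or
#'   `"user_beads"`.
#' @param bead_radius bead radius in Angstrom (default 2.9, an effective
#'   per-residue radius; for per-atom mode a smaller value is sensible).
#' @param centers,radii for `mode = "user_beads"`: explicit bead centers
#'   (M x 3) and radii.
#' @return Object of class `bead_model` with `centers`, `radii`, `mapping`
#'   (list of atom index vectors per bead).
#' @export
build_bead_model <- function(system,
                             mode = c("one_bead_per_residue",
                                      "one_bead_per_atom_heavy",
                                      "user_beads"),
                             bead_radius = 2.9, centers = NULL, radii = NULL) {
  mode <- match.arg(mode)
  if (mode == "user_beads") {
    centers <- as.matrix(centers)
    if (is.null(radii)) stop("user_beads mode needs radii")
    radii <- rep_len(as.numeric(radii), nrow(centers))
    mapping <- vector("list", nrow(centers))
  } else {
    stopifnot(inherits(system, "scat_system"))
    if (system$natoms == 0L) stop("empty structure")
    if (mode == "one_bead_per_residue") {
      key <- paste(system$atom$chain, system$atom$resno, sep = "_")
      groups <- split(seq_len(system$natoms), factor(key, levels = unique(key)))
    } else {
      heavy <- which(system$atom$element != "H")
      if (length(heavy) == 0L) stop("no heavy atoms in structure")
      groups <- as.list(heavy)
    }
    centers <- t(vapply(groups, function(ix)
      colMeans(system$xyz[ix, , drop = FALSE]), numeric(3)))
    radii <- rep(bead_radius, length(groups))
    mapping <- groups
  }
  if (any(radii <= 0)) stop("bead radii must be positive")
  structure(list(centers = centers, radii = radii, mapping = mapping),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("Bead model: %d beads, radii in [%g, %g] A\n",
              nrow(x$centers), min(x$radii), max(x$radii)))
  invisible(x)
}

# bead-level translational diffusion supermatrix kT*mu (A^2/ns),
# Rotne-Prager-Yamakawa with the overlap correction for equal radii
rpy_supermatrix <- function(centers, radii, temperature, viscosity) {
  n <- nrow(centers)
  # kT/(pi*eta) in A^3/ns: J/(Pa s) = m^3/s = 1e21 A^3/ns
  C <- .kB * temperature / (pi * viscosity * 1e-3) * 1e21
  M <- matrix(0, 3 * n, 3 * n)
  I3 <- diag(3)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    M[ii, ii] <- C / (6 * radii[i]) * I3
    if (i < n) for (j in (i + 1):n) {
      jj <- (3 * j - 2):(3 * j)
      rij <- centers[j, ] - centers[i, ]
      r <- sqrt(sum(rij^2))
      if (r < 1e-6)
        stop(sprintf("coincident beads %d and %d (separation %.2g A)", i, j, r))
      e <- rij / r
      ee <- tcrossprod(e)
      a2 <- radii[i]^2 + radii[j]^2
      if (r >= radii[i] + radii[j]) {
        B <- C / (8 * r) * ((1 + a2 / (3 * r^2)) * I3 + (1 - a2 / r^2) * ee)
      } else {
        if (abs(radii[i] - radii[j]) > 1e-9)
          stop(sprintf("overlapping beads %d and %d with unequal radii", i, j))
        a <- radii[i]
        B <- C / (6 * a) * ((1 - 9 * r / (32 * a)) * I3 + 3 * r / (32 * a) * ee)
      }
      M[ii, jj] <- B
      M[jj, ii] <- B
    }
  }
  M
}

# 6x6 rigid-body friction (inverse-diffusion units) about a given origin
rigid_friction6 <- function(zeta, centers, radii, origin, temperature,
                            viscosity) {
  n <- nrow(centers)
  C <- .kB * temperature / (pi * viscosity * 1e-3) * 1e21
  Xtt <- matrix(0, 3, 3); Xtw <- matrix(0, 3, 3); Xww <- matrix(0, 3, 3)
  A <- lapply(seq_len(n), function(i) skew3(centers[i, ] - origin))
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    for (j in seq_len(n)) {
      jj <- (3 * j - 2):(3 * j)
      z <- zeta[ii, jj]
      Xtt <- Xtt + z
      Xtw <- Xtw - z %*% A[[j]]
      Xww <- Xww - A[[i]] %*% z %*% A[[j]]
    }
  }
  Xwt <- t(Xtw)
  # bead spin friction 8*pi*eta*a^3 (keeps a single bead's rotation finite)
  Xww <- Xww + diag(3) * sum(8 * radii^3 / C)
  rbind(cbind(Xtt, Xtw), cbind(Xwt, Xww))
}

#' Rigid-body diffusion tensors from a bead model
#'
#' Assembles the pairwise Rotne-Prager-Yamakawa mobility supermatrix
#' (overlap-corrected), inverts it to a friction supermatrix, contracts to a
#' 6x6 rigid-body friction matrix, inverts, and reports translational and
#' rotational diffusion tensors at the center of diffusion (the origin where
#' the translation-rotation coupling block is symmetric). A per-bead spin
#' friction \eqn{8\pi\eta a^3} keeps the rotational block finite for sparse
#' models and reproduces the Stokes-Einstein-Debye law for a single bead.
#'
#' @param beads a [build_bead_model()] result.
#' @param temperature temperature in K.
#' @param viscosity solvent viscosity in cP.
#' @return Object of class `rigid_tensors`: `D_T` (A^2/ns), `D_R` (rad^2/ns),
#'   `D_C` coupling block (A rad/ns, diagnostic), `center` (A),
#'   `temperature`, `viscosity`, `rescale_factor` (1).
#' @export
diffusion_tensor <- function(beads, temperature = 298, viscosity = 0.89) {
  stopifnot(inherits(beads, "bead_model"))
  if (temperature <= 0 || viscosity <= 0)
    stop("temperature and viscosity must be positive")
  mu <- rpy_supermatrix(beads$centers, beads$radii, temperature, viscosity)
  zeta <- tryCatch(solve(mu), error = function(e)
    stop("singular mobility supermatrix: ", conditionMessage(e)))
  o0 <- colMeans(beads$centers)
  X <- rigid_friction6(zeta, beads$centers, beads$radii, o0, temperature,
                       viscosity)
  D6 <- solve(X)
  Drr <- D6[4:6, 4:6]
  Dwt <- D6[4:6, 1:3]
  # shift s so that antisym(Dwt + Drr %*% skew3(s)) vanishes
  anti_vec <- function(M) c(M[3, 2] - M[2, 3], M[1, 3] - M[3, 1],
                            M[2, 1] - M[1, 2])
  L <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- 1
    anti_vec(Drr %*% skew3(e))
  }, numeric(3))
  s <- solve(L, -anti_vec(Dwt))
  center <- o0 + s
  X <- rigid_friction6(zeta, beads$centers, beads$radii, center, temperature,
                       viscosity)
  D6 <- solve(X)
  D6 <- (D6 + t(D6)) / 2
  D_T <- D6[1:3, 1:3]
  D_R <- D6[4:6, 4:6]
  D_C <- D6[1:3, 4:6]
  for (M in list(D_T, D_R)) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (any(!is.finite(ev)) || any(ev <= 0))
      stop("diffusion tensor is not positive definite")
  }
  structure(list(D_T = D_T, D_R = D_R, D_C = D_C, center = center,
                 temperature = temperature, viscosity = viscosity,
                 rescale_factor = 1, n_beads = nrow(beads$centers)),
            class = "rigid_tensors")
}

#' @export
print.rigid_tensors <- function(x, ...) {
  cat(sprintf("Rigid-body tensors (%d beads, T = %g K, eta = %g cP, rescale = %g)\n",
              x$n_beads, x$temperature, x$viscosity, x$rescale_factor))
  cat(sprintf("  tr(D_T)/3 = %.4g A^2/ns, tr(D_R)/3 = %.4g rad^2/ns\n",
              mean(diag(x$D_T)), mean(diag(x$D_R))))
  cat(sprintf("  coupling magnitude |D_C| = %.3g\n", sqrt(sum(x$D_C^2))))
  invisible(x)
}

#' Construct rigid-body tensors directly
#'
#' For synthetic ground truth: wraps user-supplied tensors in the
#' `rigid_tensors` container (center defaults to the origin).
#'
#' @param D_T 3x3 translational tensor (A^2/ns), symmetric positive
#'   semi-definite.
#' @param D_R 3x3 rotational tensor (rad^2/ns).
#' @param center center of diffusion (default origin).
#' @param temperature,viscosity labels (K, cP).
#' @return A `rigid_tensors`.
#' @export
rigid_tensors <- function(D_T, D_R, center = c(0, 0, 0), temperature = 298,
                          viscosity = 0.89) {
  D_T <- (D_T + t(D_T)) / 2
  D_R <- (D_R + t(D_R)) / 2
  if (any(eigen(D_T, symmetric = TRUE, only.values = TRUE)$values < 0) ||
      any(eigen(D_R, symmetric = TRUE, only.values = TRUE)$values < 0))
    stop("tensors must be positive semi-definite")
  structure(list(D_T = D_T, D_R = D_R, D_C = matrix(0, 3, 3), center = center,
                 temperature = temperature, viscosity = viscosity,
                 rescale_factor = 1, n_beads = NA_integer_),
            class = "rigid_tensors")
}

#' Rescale rigid-body tensors
#'
#' Multiplies the translational and rotational diffusion tensors by a common
#' factor, the calibration used to anchor bead-model hydrodynamics to a
#' measured translational diffusion constant (e.g. the factor 1.2 between
#' bead-model and DLS values for the LDH tetramer).
#'
#' @param tensors a `rigid_tensors`.
#' @param factor positive scale factor.
#' @return Rescaled `rigid_tensors` with `rescale_factor` updated.
#' @export
rescale_tensors <- function(tensors, factor) {
  stopifnot(inherits(tensors, "rigid_tensors"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("rescale factor must be a positive scalar")
  tensors$D_T <- tensors$D_T * factor
  tensors$D_R <- tensors$D_R * factor
  tensors$D_C <- tensors$D_C * factor
  tensors$rescale_factor <- tensors$rescale_factor * factor
  tensors
}

#' Kirkwood estimate of the translational diffusion coefficient
#'
#' Cheap double-sum approximation
#' \eqn{D_t = (kT/N^2) \sum_{ij} \mathrm{tr}(\mu_{ij})/3}, the classical
#' fallback to the full supermatrix inversion.
#'
#' @inheritParams diffusion_tensor
#' @return Scalar translational diffusion coefficient (A^2/ns).
#' @export
kirkwood_translational_d <- function(beads, temperature = 298,
                                     viscosity = 0.89) {
  mu <- rpy_supermatrix(beads$centers, beads$radii, temperature, viscosity)
  n <- nrow(beads$centers)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- tot + sum(diag(mu[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)])) / 3
  }
  tot / n^2
}

#' Orientation-averaged form factor
#'
#' \eqn{F(Q) = \sum_{j,k} b_j b_k \langle e^{i\mathbf{Q}\cdot(\mathbf{r}_j -
#' \mathbf{r}_k)} \rangle_{\hat{Q}}}, evaluated on the package's Fibonacci
#' direction set.
#'
#' @param system a [scattering_system()].
#' @param Q_list Q moduli (1/Angstrom).
#' @param n_orientations direction count (default 64).
#' @return Numeric vector of F(Q) values (units of b^2).
#' @export
form_factor <- function(system, Q_list, n_orientations = 64) {
  stopifnot(inherits(system, "scat_system"))
  dirs <- fibonacci_directions(n_orientations)
  P <- system$xyz %*% t(dirs)
  vapply(Q_list, function(Q) {
    A <- colSums(system$b * exp(1i * Q * P))
    mean(Mod(A)^2)
  }, 0)
}

#' First-cumulant rigid-body diffusion spectrum
#'
#' Evaluates the closed-form Q-dependent first-cumulant diffusion
#' coefficient of a rigid scatterer with diffusion tensors \eqn{D^T, D^R}:
#' \deqn{D(Q) = \frac{\sum_{j,k} b_j b_k \langle e^{i\mathbf{Q}\cdot
#'   (\mathbf{r}_j-\mathbf{r}_k)} (\mathbf{Q}\cdot D^T \cdot \mathbf{Q} +
#'   \mathbf{L}_j \cdot D^R \cdot \mathbf{L}_k) \rangle_{\hat{Q}}}
#'   {Q^2 \sum_{j,k} b_j b_k \langle e^{i\mathbf{Q}\cdot(\mathbf{r}_j -
#'   \mathbf{r}_k)}\rangle_{\hat{Q}}}}
#' with \eqn{\mathbf{L}_k = \mathbf{r}_k \times \mathbf{Q}} and coordinates
#' relative to the center of diffusion. The denominator is \eqn{Q^2 F(Q)}.
#' The translation-rotation coupling is excluded (its magnitude is available
#' as `tensors$D_C`); the same Fibonacci direction construction as
#' [coherent_isf()] is used. The default direction count is higher here than
#' in the trajectory route because the rotational cross term
#' \eqn{L_j \cdot D^R \cdot L_k} converges more slowly in the angular
#' average than the ISF itself; the evaluation is cheap (single structure),
#' so a dense set costs little.
#'
#' @param system a [scattering_system()].
#' @param tensors a `rigid_tensors` (its `center` is subtracted from the
#'   coordinates).
#' @param Q_list Q moduli (1/Angstrom).
#' @param n_orientations direction count (default 512).
#' @param components if `TRUE`, also return the translational and rotational
#'   parts separately.
#' @param ff_floor form-factor floor (relative to its Q = 0 value) below
#'   which a Q is flagged as a gap (`NA`).
#' @return A `diff_spectrum` (component `"rigid_total"`); when
#'   `components = TRUE`, a list of three spectra (`total`, `translation`,
#'   `rotation`).
#' @export
rigid_body_spectrum <- function(system, tensors, Q_list, n_orientations = 512,
                                components = FALSE, ff_floor = 1e-10) {
  stopifnot(inherits(system, "scat_system"), inherits(tensors, "rigid_tensors"))
  xyz <- sweep(system$xyz, 2, tensors$center)
  b <- system$b
  dirs <- fibonacci_directions(n_orientations)
  P <- xyz %*% t(dirs)                     # N x M projections
  # r x u per direction (depends on direction only)
  CX <- outer(xyz[, 2], dirs[, 3]) - outer(xyz[, 3], dirs[, 2])
  CY <- outer(xyz[, 3], dirs[, 1]) - outer(xyz[, 1], dirs[, 3])
  CZ <- outer(xyz[, 1], dirs[, 2]) - outer(xyz[, 2], dirs[, 1])
  uDTu <- rowSums((dirs %*% tensors$D_T) * dirs)   # M
  DR <- tensors$D_R
  F0 <- sum(b)^2
  o <- order(Q_list)
  Qs <- Q_list[o]
  Dtr <- Drot <- Dtot <- rep(NA_real_, length(Qs))
  for (qi in seq_along(Qs)) {
    Q <- Qs[qi]
    E <- exp(1i * Q * P)
    bE <- b * E
    A2 <- Mod(colSums(bE))^2              # M
    Bx <- colSums(bE * CX); By <- colSums(bE * CY); Bz <- colSums(bE * CZ)
    rot <- Re(Conj(Bx) * (DR[1, 1] * Bx + DR[1, 2] * By + DR[1, 3] * Bz) +
              Conj(By) * (DR[2, 1] * Bx + DR[2, 2] * By + DR[2, 3] * Bz) +
              Conj(Bz) * (DR[3, 1] * Bx + DR[3, 2] * By + DR[3, 3] * Bz))
    den <- sum(A2)
    if (!is.finite(den) || den < ff_floor * max(F0, .Machine$double.eps)) next
    Dtr[qi] <- sum(uDTu * A2) / den
    Drot[qi] <- sum(rot) / den
    Dtot[qi] <- Dtr[qi] + Drot[qi]
  }
  if (anyNA(Dtot))
    warning("form factor below floor at some Q; flagged as gaps")
  tot <- diffusion_spectrum_obj(Qs, Dtot, component = "rigid_total",
                                temperature = tensors$temperature)
  if (!components) return(tot)
  list(total = tot,
       translation = diffusion_spectrum_obj(Qs, Dtr,
                                            component = "rigid_translation",
                                            temperature = tensors$temperature),
       rotation = diffusion_spectrum_obj(Qs, Drot,
                                         component = "rigid_rotation",
                                         temperature = tensors$temperature))
}

#' Write rigid-body tensors as JSON
#' @param tensors a `rigid_tensors`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tensors_json <- function(tensors, file) {
  jsonlite::write_json(
    list(D_T = tensors$D_T, D_R = tensors$D_R, D_C = tensors$D_C,
         center = tensors$center, temperature = tensors$temperature,
         viscosity_cP = tensors$viscosity,
         rescale_factor = tensors$rescale_factor,
         units = list(D_T = "A^2/ns", D_R = "rad^2/ns", center = "A")),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Approximate D2O viscosity
#'
#' Vogel-equation fit for light water scaled by the D2O/H2O viscosity ratio
#' (about 1.23 near room temperature); adequate for the temperature range
#' 280-340 K used here and fully overridable wherever a viscosity is taken.
#'
#' @param temperature temperature in K.
#' @return Viscosity in cP.
#' @export
d2o_viscosity <- function(temperature) {
  eta_h2o <- 2.414e-2 * 10^(247.8 / (temperature - 140))
  1.23 * eta_h2o
}
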