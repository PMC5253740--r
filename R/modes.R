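# F x 3n matrix in atom-major order (x1,y1,z1,x2,...)
flatten_traj <- function(traj, selection) {
  sub <- traj$coords[, selection, , drop = FALSE]
  F <- dim(sub)[1]; n <- dim(sub)[2]
  X <- matrix(0, F, 3 * n)
  X[, seq(1, 3 * n, by = 3)] <- sub[, , 1]
  X[, seq(2, 3 * n, by = 3)] <- sub[, , 2]
  X[, seq(3, 3 * n, by = 3)] <- sub[, , 3]
  X
}

#' Principal component analysis of internal motion
#'
#' Eigendecomposition of the Cartesian covariance matrix of a
#' roto-translation-free trajectory over an atom selection. Covariances use
#' the 1/F (population) normalization so that the eigenvalue sum equals the
#' summed per-atom mean-square fluctuation exactly.
#'
#' @param traj_fitted a `traj` of kind `"rototranslation_removed"`.
#' @param selection atom indices (default all; for proteins the
#'   Calpha set is the conventional choice).
#' @return Object of class `mode_set`: `mean` (3n), `values` (eigenvalues,
#'   A^2, descending), `vectors` (3n x K orthonormal), `selection`.
#' @export
pca_modes <- function(traj_fitted, selection = NULL) {
  stopifnot(inherits(traj_fitted, "traj"))
  if (traj_fitted$kind != "rototranslation_removed")
    stop("PCA expects a roto-translation-removed trajectory (kind = ",
         traj_fitted$kind, ")")
  sel <- if (is.null(selection)) seq_len(traj_fitted$natoms) else selection
  X <- flatten_traj(traj_fitted, sel)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(mean = mu, values = vals, vectors = e$vectors,
                 selection = sel, natoms = length(sel)),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("Mode set: %d atoms, %d modes, total variance %.4g A^2\n",
              x$natoms, length(x$values), sum(x$values)))
  cat("  top eigenvalues:", paste(signif(head(x$values, 5), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project a trajectory on the leading principal modes
#'
#' Reconstructs each frame as mean + sum over the first `n_modes` modes of
#' the displacement projected on that mode; the virtual trajectory contains
#' only the motion carried by those modes. The result is restricted to the
#' mode set's atom selection.
#'
#' @param traj_fitted the fitted trajectory the modes were computed from.
#' @param modeset a [pca_modes()] result.
#' @param n_modes number of leading modes to keep (0 gives the static mean).
#' @return A `traj` of kind `"mode_projected"` over the selection atoms.
#' @export
project_on_modes <- function(traj_fitted, modeset, n_modes) {
  stopifnot(inherits(modeset, "mode_set"))
  n_modes <- as.integer(n_modes)
  if (n_modes < 0 || n_modes > length(modeset$values))
    stop("n_modes out of range")
  X <- flatten_traj(traj_fitted, modeset$selection)
  Xc <- sweep(X, 2, modeset$mean)
  rec <- if (n_modes == 0) matrix(0, nrow(X), ncol(X)) else {
    V <- modeset$vectors[, seq_len(n_modes), drop = FALSE]
    (Xc %*% V) %*% t(V)
  }
  Y <- sweep(rec, 2, modeset$mean, "+")
  n <- modeset$natoms
  coords <- array(0, c(nrow(Y), n, 3))
  coords[, , 1] <- Y[, seq(1, 3 * n, by = 3)]
  coords[, , 2] <- Y[, seq(2, 3 * n, by = 3)]
  coords[, , 3] <- Y[, seq(3, 3 * n, by = 3)]
  trajectory(coords, dt = traj_fitted$dt, kind = "mode_projected",
             provenance = sprintf("projection on first %d modes", n_modes))
}

#' Mode-resolved contribution to the internal diffusion spectrum
#'
#' Computes the internal spectrum of the trajectory projected on the first
#' `n_modes` principal modes and its fraction of the full internal spectrum
#' at each Q (both over the mode set's atom selection).
#'
#' @param traj_fitted a roto-translation-removed `traj`.
#' @param system the matching `scat_system`.
#' @param modeset a [pca_modes()] result.
#' @param n_modes number of leading modes.
#' @param Q_list,fit_window,... as in [internal_spectrum()].
#' @return List with `spectrum` (the projected `diff_spectrum`), `full`
#'   (full internal spectrum), and `fraction` (per-Q ratio projected/full).
#' @export
mode_contribution <- function(traj_fitted, system, modeset, n_modes, Q_list,
                              fit_window = c(0, 50), ...) {
  sub_sys <- subset_system(system, modeset$selection)
  proj <- project_on_modes(traj_fitted, modeset, n_modes)
  full_traj <- subset_traj(traj_fitted, modeset$selection)
  sp_proj <- internal_spectrum(proj, sub_sys, Q_list, fit_window, ...)
  sp_full <- internal_spectrum(full_traj, sub_sys, Q_list, fit_window, ...)
  list(spectrum = sp_proj, full = sp_full,
       fraction = sp_proj$D / sp_full$D)
}

#' Per-residue mean-square fluctuation profile
#'
#' Time-averaged squared displacement about the mean structure, summed over
#' x, y, z per atom and averaged over the atoms of each residue. Computed
#' on a roto-translation-free trajectory it localizes the flexible regions
#' of the structure along the sequence.
#'
#' @param traj_fitted a roto-translation-removed `traj`.
#' @param system the matching `scat_system`.
#' @param selection atom indices (default all).
#' @param group_by_residue if `FALSE`, return per-atom MSF instead.
#' @return Data frame with columns `chain`, `resno`, `msf` (A^2), or per-atom
#'   `atom`, `msf`.
#' @export
msf_profile <- function(traj_fitted, system, selection = NULL,
                        group_by_residue = TRUE) {
  stopifnot(inherits(traj_fitted, "traj"), inherits(system, "scat_system"))
  sel <- if (is.null(selection)) seq_len(traj_fitted$natoms) else selection
  X <- flatten_traj(traj_fitted, sel)
  Xc <- sweep(X, 2, colMeans(X))
  percoord <- colMeans(Xc^2)
  msf_atom <- percoord[seq(1, length(percoord), 3)] +
    percoord[seq(2, length(percoord), 3)] +
    percoord[seq(3, length(percoord), 3)]
  if (!group_by_residue)
    return(data.frame(atom = sel, msf = msf_atom))
  key <- paste(system$atom$chain[sel], system$atom$resno[sel], sep = "_")
  agg <- tapply(msf_atom, factor(key, levels = unique(key)), mean)
  first <- !duplicated(key)
  data.frame(chain = system$atom$chain[sel][first],
             resno = system$atom$resno[sel][first],
             msf = as.numeric(agg))
}
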