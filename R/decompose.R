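#' Optimal proper superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `ref`,
#' restricted to proper rotations (determinant +1; mirror images are never
#' matched by a reflection).
#'
#' @param mobile,ref N x 3 coordinate matrices.
#' @param weights optional per-atom weights (default uniform).
#' @return List with `R` (3x3 rotation), `t` (translation), `rmsd`, and
#'   `apply(x)` transforming an M x 3 matrix.
#' @export
kabsch <- function(mobile, ref, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(ref * w)
  P <- sweep(mobile, 2, cm)
  Qm <- sweep(ref, 2, cr)
  H <- crossprod(P * w, Qm)
  sv <- svd(H)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1))
    stop("degenerate selection: rotation is ill-defined (collinear atoms)")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (!is.finite(d) || d == 0)
    stop("degenerate selection: rotation is ill-defined (collinear atoms)")
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  tvec <- cr - as.numeric(R %*% cm)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Qm)^2)))
  list(R = R, t = tvec, rmsd = rmsd,
       apply = function(x) sweep(x %*% t(R), 2, tvec, "+"))
}

#' Remove center-of-selection translation from a trajectory
#'
#' Shifts each frame so the (b-weighted or uniform) center of the selection
#' sits at the origin; the output contains rotation plus internal motion
#' only.
#'
#' @param traj a [trajectory()].
#' @param system optional [scattering_system()] supplying b-weights.
#' @param selection atom indices defining the center (default all atoms).
#' @param weights `"uniform"` (default) or `"b"` (scattering-length
#'   weighted; requires `system`).
#' @return A `traj` with `kind = "translation_removed"`.
#' @export
remove_translation <- function(traj, system = NULL, selection = NULL,
                               weights = c("uniform", "b")) {
  weights <- match.arg(weights)
  stopifnot(inherits(traj, "traj"))
  sel <- if (is.null(selection)) seq_len(traj$natoms) else selection
  w <- if (weights == "b") {
    if (is.null(system)) stop("b-weighting requires a system")
    abs(system$b[sel])
  } else rep(1, length(sel))
  w <- w / sum(w)
  coords <- traj$coords
  for (k in 1:3) {
    ctr <- coords[, sel, k, drop = FALSE]
    dim(ctr) <- c(traj$nframes, length(sel))
    coords[, , k] <- coords[, , k] - as.numeric(ctr %*% w)
  }
  trajectory(coords, dt = traj$dt, kind = "translation_removed",
             provenance = paste0(traj$provenance, " | translation removed"),
             rotations = traj$rotations)
}

#' Remove roto-translation by frame-wise superposition
#'
#' Fits every frame onto a reference structure by optimal proper
#' superposition, leaving only the internal modes. The default reference is
#' the trajectory average after one pre-alignment pass onto the first
#' frame (iterated once), which minimizes leakage of rigid motion into the
#' apparent internal dynamics; an explicit reference (e.g. a crystal
#' structure) can be supplied instead.
#'
#' @param traj a [trajectory()].
#' @param reference optional N_sel x 3 reference coordinates.
#' @param selection atom indices used for the fit (default all); the fitted
#'   transform is applied to all atoms.
#' @param weights optional per-atom fit weights over the selection.
#' @return A `traj` with `kind = "rototranslation_removed"`.
#' @export
remove_rototranslation <- function(traj, reference = NULL, selection = NULL,
                                   weights = NULL) {
  stopifnot(inherits(traj, "traj"))
  sel <- if (is.null(selection)) seq_len(traj$natoms) else selection
  F <- traj$nframes
  if (is.null(reference)) {
    ref0 <- traj$coords[1, sel, ]
    dim(ref0) <- c(length(sel), 3)
    acc <- matrix(0, length(sel), 3)
    for (f in seq_len(F)) {
      fr <- matrix(traj$coords[f, sel, ], ncol = 3)
      acc <- acc + kabsch(fr, ref0, weights)$apply(fr)
    }
    reference <- acc / F
  } else {
    reference <- as.matrix(reference)
    if (nrow(reference) != length(sel))
      stop("reference atom count does not match the selection")
  }
  out <- traj$coords
  for (f in seq_len(F)) {
    fr_sel <- matrix(traj$coords[f, sel, ], ncol = 3)
    tr <- kabsch(fr_sel, reference, weights)
    out[f, , ] <- tr$apply(matrix(traj$coords[f, , ], ncol = 3))
  }
  trajectory(out, dt = traj$dt, kind = "rototranslation_removed",
             provenance = paste0(traj$provenance, " | roto-translation removed"))
}

#' Internal diffusion spectrum
#'
#' Runs the coherent-ISF/cumulant pipeline on a roto-translation-free (or
#' mode-projected / excised) trajectory; the result is the internal
#' contribution \eqn{D^{Int}(Q)} obtained from the initial decay of
#' I(Q,t)/I(Q,0).
#'
#' @param traj_fitted a `traj` of kind `"rototranslation_removed"`,
#'   `"mode_projected"`, or `"excised"`.
#' @param system the matching [scattering_system()].
#' @param Q_list Q moduli (1/Angstrom).
#' @param fit_window cumulant fit window in ns.
#' @param ... passed to [coherent_isf()].
#' @return A `diff_spectrum` with component `"internal"`.
#' @export
internal_spectrum <- function(traj_fitted, system, Q_list,
                              fit_window = c(0, 50), ...) {
  stopifnot(inherits(traj_fitted, "traj"))
  if (!traj_fitted$kind %in% c("rototranslation_removed", "mode_projected",
                               "excised"))
    stop("internal_spectrum needs a roto-translation-free trajectory (kind = ",
         traj_fitted$kind, ")")
  curves <- coherent_isf(traj_fitted, system, Q_list, ...)
  diffusion_spectrum(curves, fit_window, component = "internal")
}

#' Compose rigid-body and internal spectra
#'
#' Pointwise sum D(Q) = D_rigid(Q) + D_int(Q) on the common Q grid — the
#' additive decomposition of the total first-cumulant diffusivity into
#' rigid-body and internal contributions.
#'
#' @param rigid a `diff_spectrum` (rigid-body component).
#' @param internal a `diff_spectrum` (internal component).
#' @return A `diff_spectrum` with component `"composed"`.
#' @export
compose_total <- function(rigid, internal) {
  stopifnot(inherits(rigid, "diff_spectrum"), inherits(internal, "diff_spectrum"))
  if (nrow(rigid) != nrow(internal) ||
      any(abs(rigid$Q - internal$Q) > 1e-9))
    stop("Q grids of the two spectra do not match")
  se <- if ("se" %in% names(rigid) && "se" %in% names(internal))
    sqrt(rigid$se^2 + internal$se^2)
  else if ("se" %in% names(rigid)) rigid$se
  else if ("se" %in% names(internal)) internal$se
  else NULL
  diffusion_spectrum_obj(rigid$Q, rigid$D + internal$D, component = "composed",
                         temperature = attr(rigid, "temperature"), se = se)
}

#' Excise a residue region from trajectory and system
#'
#' Keeps or removes residue ranges consistently in both the trajectory and
#' the scattering system, e.g. to measure the spectrum with the loop
#' regions excised.
#'
#' @param traj a `traj`.
#' @param system the matching `scat_system`.
#' @param residue_ranges list of `c(lo, hi)` residue-number ranges (applied
#'   on all chains) or a single range vector.
#' @param mode `"remove"` (drop the ranges) or `"keep_only"`.
#' @return List with elements `traj` (kind `"excised"`) and `system`.
#' @export
excise_region <- function(traj, system, residue_ranges,
                          mode = c("remove", "keep_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "traj"), inherits(system, "scat_system"))
  if (is.numeric(residue_ranges)) residue_ranges <- list(residue_ranges)
  inrange <- rep(FALSE, system$natoms)
  for (rg in residue_ranges)
    inrange <- inrange | (system$atom$resno >= rg[1] &
                          system$atom$resno <= rg[2])
  keep <- if (mode == "remove") which(!inrange) else which(inrange)
  if (length(keep) == 0L) stop("excision leaves no atoms")
  list(traj = subset_traj(traj, keep, kind = "excised"),
       system = subset_system(system, keep))
}
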