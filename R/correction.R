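#' SAXS concentration series container
#'
#' Holds background-subtracted small-angle scattering curves I(Q) measured
#' at several protein concentrations, the input for the structure-factor
#' extrapolation.
#'
#' @param curves named list; names are concentrations in mg/ml (coercible to
#'   numeric), each element a data frame or list with fields `Q` and `I`.
#' @param background_subtracted logical flag recorded with the series.
#' @return Object of class `saxs_series`.
#' @export
saxs_series <- function(curves, background_subtracted = TRUE) {
  conc <- as.numeric(names(curves))
  if (anyNA(conc)) stop("curve names must be numeric concentrations (mg/ml)")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(conc) < 2L) stop("need at least 2 concentrations for extrapolation")
  curves <- lapply(curves, function(cu) {
    cu <- as.data.frame(cu)[, c("Q", "I")]
    if (any(cu$I < 0)) stop("negative intensities in SAXS curve")
    cu
  })
  structure(list(curves = curves, concentrations = conc,
                 background_subtracted = background_subtracted),
            class = "saxs_series")
}

#' Read a SAXS series from two-column files
#'
#' @param files vector of paths to whitespace- or comma-separated two-column
#'   (Q, I) files.
#' @param concentrations concentrations (mg/ml) matching `files`.
#' @param q_unit `"A^-1"` or `"nm^-1"`; nm^-1 input is converted to 1/Angstrom.
#' @return A [saxs_series()].
#' @export
read_saxs_series <- function(files, concentrations, q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  stopifnot(length(files) == length(concentrations))
  curves <- lapply(files, function(f) {
    df <- read.table(f, header = FALSE, col.names = c("Q", "I"),
                     sep = "", comment.char = "#")
    if (q_unit == "nm^-1") df$Q <- df$Q / 10
    df
  })
  names(curves) <- concentrations
  saxs_series(curves)
}

#' Structure factor from a SAXS concentration series
#'
#' Extrapolates the concentration-normalized intensity I(Q,C)/C linearly in
#' C to C = 0 at each Q; that limit is the form-factor reference (inter-
#' protein interactions vanish at infinite dilution, S(Q) -> 1). The
#' structure factor at the target concentration is then
#' \deqn{S(Q; C) = \frac{I(Q, C)/C}{\lim_{C\to 0} I(Q, C)/C}}
#' and the curve is renormalized so the mean of S over the top decile of the
#' Q range equals 1 (at high Q the curves are interaction-free and overlap;
#' the renormalization removes calibration constants).
#'
#' @param series a [saxs_series()].
#' @param target_C concentration (mg/ml) at which to evaluate S(Q); must be
#'   one of the measured concentrations or inside their hull.
#' @param order polynomial order in C for the extrapolation (default 1,
#'   the dilute-regime virial behaviour).
#' @param interpolate if `TRUE`, curves on different Q grids are linearly
#'   interpolated onto the grid of the first curve; if `FALSE`, differing
#'   grids are an error.
#' @return Object of class `structure_factor`: data frame `Q`, `S`, with
#'   attributes `target_C`, `norm_factor`, `residuals` (per-Q extrapolation
#'   residual norm).
#' @export
structure_factor_from_series <- function(series, target_C, order = 1,
                                         interpolate = FALSE) {
  stopifnot(inherits(series, "saxs_series"))
  conc <- series$concentrations
  if (target_C < min(conc) - 1e-9 || target_C > max(conc) + 1e-9)
    stop("target_C outside the measured concentration hull")
  Qref <- series$curves[[1]]$Q
  Imat <- vapply(seq_along(conc), function(i) {
    cu <- series$curves[[i]]
    if (length(cu$Q) == length(Qref) && all(abs(cu$Q - Qref) < 1e-9))
      return(cu$I)
    if (!interpolate)
      stop("SAXS curves are on different Q grids; set interpolate = TRUE")
    approx(cu$Q, cu$I, xout = Qref, rule = 2)$y
  }, numeric(length(Qref)))
  # per-Q polynomial extrapolation of I/C to C = 0
  Y <- sweep(Imat, 2, conc, "/")
  X <- outer(conc, 0:order, "^")
  beta <- solve(crossprod(X), crossprod(X, t(Y)))   # (order+1) x nQ
  F_ref <- beta[1, ]
  resid <- sqrt(colSums((t(Y) - X %*% beta)^2))
  if (any(F_ref <= 0))
    stop("non-positive extrapolated form factor; check the series")
  it <- which.min(abs(conc - target_C))
  I_target <- if (abs(conc[it] - target_C) < 1e-9) Imat[, it] else
    vapply(seq_along(Qref), function(k)
      sum(beta[, k] * target_C^(0:order)) * target_C, 0) / target_C
  S <- (I_target / target_C) / F_ref
  top <- Qref >= stats::quantile(Qref, 0.9)
  norm <- mean(S[top])
  S <- S / norm
  structure(data.frame(Q = Qref, S = S),
            target_C = target_C, norm_factor = norm, residuals = resid,
            class = c("structure_factor", "data.frame"))
}

#' @export
print.structure_factor <- function(x, ...) {
  cat(sprintf("Structure factor at C = %g mg/ml: %d Q points, S in [%.3g, %.3g]\n",
              attr(x, "target_C"), nrow(x), min(x$S), max(x$S)))
  invisible(x)
}

#' DLS anchor
#'
#' A Q-independent translational diffusion constant measured by dynamic
#' light scattering, used to fix the overall hydrodynamic scale of the
#' corrected spectrum over a Q window where the hydrodynamic function is
#' flat.
#'
#' @param D_dls translational diffusion constant (A^2/ns, > 0).
#' @param window `c(Q_lo, Q_hi)` anchor window in 1/Angstrom; the default
#'   lower edge 0.06 is where model calculations show the hydrodynamic
#'   function free of oscillatory structure.
#' @return Object of class `hydro_anchor`.
#' @export
hydro_anchor <- function(D_dls, window = c(0.06, Inf)) {
  if (!is.numeric(D_dls) || D_dls <= 0) stop("D_dls must be positive")
  structure(list(D_dls = D_dls, window = window), class = "hydro_anchor")
}

#' Correct an effective diffusion spectrum to infinite dilution
#'
#' Applies \eqn{D_0(Q) = D_{eff}(Q) \cdot S(Q) / H(Q)}. The hydrodynamic
#' function is treated as a Q-independent scalar over the anchor window:
#' with \eqn{P(Q) = D_{eff}(Q) S(Q)}, the scale is
#' \eqn{h = \mathrm{mean}_{window} P / D_{DLS}} and \eqn{D_0 = P / h}, i.e.
#' the corrected spectrum matches the DLS translational diffusion constant
#' on average over the window.
#'
#' @param spectrum a `diff_spectrum` of effective diffusion.
#' @param s a [structure_factor_from_series()] result (interpolated onto the
#'   spectrum's Q grid).
#' @param anchor a [hydro_anchor()].
#' @return A `diff_spectrum` of \eqn{D_0(Q)} with attribute `h_scale`.
#' @export
apply_solution_correction <- function(spectrum, s, anchor) {
  stopifnot(inherits(spectrum, "diff_spectrum"),
            inherits(s, "structure_factor"), inherits(anchor, "hydro_anchor"))
  Svals <- approx(s$Q, s$S, xout = spectrum$Q, rule = 2)$y
  P <- spectrum$D * Svals
  inw <- spectrum$Q >= anchor$window[1] & spectrum$Q <= anchor$window[2]
  if (!any(inw)) stop("anchor window contains no Q points of the spectrum")
  if (anyNA(P[inw])) stop("anchor window overlaps flagged gaps in the spectrum")
  h <- mean(P[inw]) / anchor$D_dls
  out <- diffusion_spectrum_obj(spectrum$Q, P / h, component = "effective",
                                temperature = attr(spectrum, "temperature"),
                                se = if ("se" %in% names(spectrum))
                                  spectrum$se * Svals / h else NULL)
  attr(out, "h_scale") <- h
  out
}

#' Write a structure factor as CSV
#' @param s a `structure_factor`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure_factor_csv <- function(s, file) {
  write.csv(as.data.frame(s), file, row.names = FALSE)
  invisible(file)
}
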