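#' Deterministic quasi-uniform directions on the unit sphere
#'
#' Spherical Fibonacci (golden-angle spiral) point set used for all
#' orientational averages in the package. Deterministic and low-discrepancy,
#' so the same direction set can be shared between the trajectory-based ISF
#' and the closed-form rigid-body spectrum, making the two routes directly
#' comparable at any direction count.
#'
#' @param n number of directions (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' ISF curve constructor
#'
#' Normalized coherent intermediate scattering function at one Q:
#' I(Q,t)/I(Q,0) on a grid of time lags.
#'
#' @param Q scattering vector modulus (1/Angstrom, > 0).
#' @param lags time lags in ns, strictly increasing from 0.
#' @param values normalized ISF values; `values[1]` must be exactly 1.
#' @param n_orientations number of directions used in the orientational
#'   average.
#' @return Object of class `isf_curve`.
#' @export
isf_curve <- function(Q, lags, values, n_orientations = NA_integer_) {
  if (Q <= 0) stop("Q must be positive")
  if (lags[1] != 0 || any(diff(lags) <= 0))
    stop("lags must increase strictly from 0")
  if (length(values) != length(lags)) stop("values/lags length mismatch")
  if (values[1] != 1) stop("ISF must be normalized: values[1] must equal 1")
  structure(list(Q = Q, lags = lags, values = values,
                 n_orientations = n_orientations),
            class = "isf_curve")
}

#' @export
print.isf_curve <- function(x, ...) {
  cat(sprintf("ISF curve: Q = %g 1/A, %d lags up to %g ns (%s orientations)\n",
              x$Q, length(x$lags), max(x$lags),
              ifelse(is.na(x$n_orientations), "?", x$n_orientations)))
  invisible(x)
}

#' Coherent intermediate scattering function from a trajectory
#'
#' Computes, for each Q, the orientation- and time-origin-averaged coherent
#' ISF
#' \deqn{I(Q,t) = \langle \sum_{j,k} b_j b_k
#'   e^{i \mathbf{Q}\cdot[\mathbf{r}_j(t_0+t) - \mathbf{r}_k(t_0)]}
#'   \rangle_{t_0,\hat{Q}}}
#' normalized by its t = 0 value. The orientational average uses the
#' deterministic [fibonacci_directions()] set (solution isotropy); the time
#' origin average runs over all origins with a configurable stride.
#'
#' @param traj a [trajectory()].
#' @param system the matching [scattering_system()] (same atom count).
#' @param Q_list positive Q moduli (1/Angstrom).
#' @param n_orientations directions in the orientational average (default 64).
#' @param max_lag largest lag in ns (default: half the trajectory length).
#' @param n_lags number of lag points (default 40, spaced evenly in frames,
#'   always including 0 and consecutive early frames).
#' @param origin_stride stride over time origins (default 1 = all origins;
#'   overlapping origins are accepted, trading bias for variance).
#' @param selection optional atom indices to restrict the calculation.
#' @return List of `isf_curve`, one per Q.
#' @export
coherent_isf <- function(traj, system, Q_list, n_orientations = 64,
                         max_lag = NULL, n_lags = 40, origin_stride = 1,
                         selection = NULL) {
  stopifnot(inherits(traj, "traj"), inherits(system, "scat_system"))
  if (traj$natoms != system$natoms)
    stop("trajectory and system atom counts differ")
  if (any(Q_list <= 0)) stop("all Q must be positive")
  if (n_orientations < 1) stop("n_orientations must be >= 1")
  coords <- traj$coords
  b <- system$b
  if (!is.null(selection)) {
    if (length(selection) == 0L) stop("selection is empty")
    coords <- coords[, selection, , drop = FALSE]
    b <- b[selection]
  }
  if (all(b == 0)) stop("all scattering lengths in the selection are zero")
  tmax_avail <- (traj$nframes - 1) * traj$dt
  if (is.null(max_lag)) max_lag <- tmax_avail / 2
  if (max_lag > tmax_avail + 1e-12)
    stop(sprintf("max_lag = %g ns exceeds the trajectory limit (%g ns)",
                 max_lag, tmax_avail))
  lag_max_fr <- floor(max_lag / traj$dt + 1e-9)
  lags_fr <- if (lag_max_fr + 1 <= n_lags) 0:lag_max_fr else
    sort(unique(c(0:min(5L, lag_max_fr),
                  round(seq(0, lag_max_fr, length.out = n_lags)))))
  dirs <- fibonacci_directions(n_orientations)
  raw <- cpp_isf(coords, b, dirs, as.numeric(Q_list),
                 as.integer(lags_fr), as.integer(origin_stride))
  lapply(seq_along(Q_list), function(k) {
    isf_curve(Q_list[k], lags_fr * traj$dt, raw[k, ] / raw[k, 1],
              n_orientations)
  })
}

#' Initial-decay fit window for a curve
#'
#' Chooses a Q-adaptive cumulant fit window ending where the curve has
#' decayed by `target_decay` in ln I (default 0.3, i.e. I about 0.74),
#' estimated from the earliest lags. The first cumulant is a t -> 0
#' property; restricting the fit to the initial decay keeps the truncation
#' bias of the two-term expansion below the sampling noise for strongly
#' decaying (high-Q) curves, while slowly decaying curves keep the full
#' window.
#'
#' @param curve an [isf_curve()].
#' @param target_decay ln I decay depth terminating the window.
#' @param min_points minimum number of lag points in the window.
#' @return `c(0, t_max)` in ns.
#' @export
auto_fit_window <- function(curve, target_decay = 0.3, min_points = 5) {
  v <- curve$values
  t <- curve$lags
  k <- which(v < exp(-target_decay))
  tmax <- if (length(k) == 0) max(t) else t[k[1]]
  tmax <- max(tmax, t[min(min_points, length(t))])
  c(0, min(tmax, max(t)))
}

#' Cumulant fit of an ISF curve
#'
#' Least-squares fit of \eqn{\ln[I(Q,t)/I(Q,0)] = -\Gamma t + (K_2/2) t^2}
#' over a time window (the first two terms of the cumulant expansion; the
#' third cumulant is not fitted). The effective diffusion coefficient is
#' \eqn{D_{eff} = \Gamma / Q^2}.
#'
#' @param curve an [isf_curve()].
#' @param fit_window `c(t_min, t_max)` in ns (default `c(0, 50)`, clipped
#'   with a warning when the curve is shorter), or the string `"auto"` for
#'   the per-curve initial-decay window of [auto_fit_window()].
#' @return Object of class `cumulant_fit` with fields `Gamma` (1/ns), `K2`
#'   (1/ns^2), `D_eff` (A^2/ns), `Q`, `fit_window`, `residual_norm`.
#' @export
cumulant_fit <- function(curve, fit_window = c(0, 50)) {
  stopifnot(inherits(curve, "isf_curve"))
  if (identical(fit_window, "auto")) fit_window <- auto_fit_window(curve)
  tmax_avail <- max(curve$lags)
  if (fit_window[2] > tmax_avail) {
    warning(sprintf("fit window clipped from %g to %g ns (curve limit)",
                    fit_window[2], tmax_avail))
    fit_window[2] <- tmax_avail
  }
  inw <- curve$lags >= fit_window[1] & curve$lags <= fit_window[2] + 1e-12
  t <- curve$lags[inw]
  v <- curve$values[inw]
  if (length(t) < 4L) stop("need at least 4 lag points inside the fit window")
  if (any(v <= 0))
    stop("non-positive ISF values in the fit window; shorten the window")
  y <- log(v)
  X <- cbind(t, t^2)
  fit <- tryCatch(lm.fit(X, y), error = function(e)
    stop("singular design matrix in cumulant fit: ", conditionMessage(e)))
  if (any(is.na(fit$coefficients)))
    stop("singular design matrix in cumulant fit")
  Gamma <- -unname(fit$coefficients[1])
  K2 <- 2 * unname(fit$coefficients[2])
  structure(list(Gamma = Gamma, K2 = K2, D_eff = Gamma / curve$Q^2,
                 Q = curve$Q, fit_window = fit_window,
                 residual_norm = sqrt(sum(fit$residuals^2))),
            class = "cumulant_fit")
}

#' @export
print.cumulant_fit <- function(x, ...) {
  cat(sprintf("Cumulant fit: Q = %g, Gamma = %g 1/ns, K2 = %g, D_eff = %g A^2/ns\n",
              x$Q, x$Gamma, x$K2, x$D_eff))
  invisible(x)
}

#' Diffusion spectrum constructor
#'
#' Q-dependent diffusion coefficients D(Q) (A^2/ns) tagged by the motion
#' component they describe.
#'
#' @param Q strictly increasing Q grid (1/Angstrom).
#' @param D diffusion values (A^2/ns); `NA` marks flagged gaps.
#' @param component one of `"effective"`, `"rigid_total"`,
#'   `"rigid_translation"`, `"rigid_rotation"`, `"internal"`, `"composed"`,
#'   `"experimental"`.
#' @param temperature temperature label in K (optional).
#' @param se optional per-Q standard errors.
#' @return Object of class `diff_spectrum` (a data frame with columns `Q`,
#'   `D`, optionally `se`, plus `component` and `temperature` attributes).
#' @export
diffusion_spectrum_obj <- function(Q, D,
                                   component = c("effective", "rigid_total",
                                                 "rigid_translation",
                                                 "rigid_rotation", "internal",
                                                 "composed", "experimental"),
                                   temperature = NA_real_, se = NULL) {
  component <- match.arg(component)
  if (any(diff(Q) <= 0)) stop("Q grid must be strictly increasing")
  df <- data.frame(Q = Q, D = D)
  if (!is.null(se)) df$se <- se
  structure(df, component = component, temperature = temperature,
            class = c("diff_spectrum", "data.frame"))
}

#' @export
print.diff_spectrum <- function(x, ...) {
  cat(sprintf("Diffusion spectrum [%s]%s: %d Q points in [%g, %g] 1/A\n",
              attr(x, "component"),
              ifelse(is.na(attr(x, "temperature")), "",
                     sprintf(" at %g K", attr(x, "temperature"))),
              nrow(x), min(x$Q), max(x$Q)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Q-dependent effective diffusion from ISF curves
#'
#' Maps [cumulant_fit()] across a list of ISF curves sharing a lag grid.
#' Per-Q fit failures are propagated as `NA` gaps (with a warning), never
#' dropped silently.
#'
#' @param curves list of [isf_curve()] on a common lag grid.
#' @param fit_window passed to [cumulant_fit()].
#' @param component component tag for the result.
#' @param temperature temperature label (K).
#' @return A `diff_spectrum`.
#' @export
diffusion_spectrum <- function(curves, fit_window = c(0, 50),
                               component = "effective",
                               temperature = NA_real_) {
  if (length(curves) == 0L) stop("empty curve list")
  Q <- vapply(curves, function(cu) cu$Q, 0)
  o <- order(Q)
  D <- rep(NA_real_, length(curves))
  for (i in o) {
    f <- tryCatch(cumulant_fit(curves[[i]], fit_window),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning(sprintf("cumulant fit failed at Q = %g; flagged as gap", Q[i]))
    } else D[i] <- f$D_eff
  }
  diffusion_spectrum_obj(Q[o], D[o], component = component,
                         temperature = temperature)
}

#' Effective diffusion spectrum with block-averaged errors
#'
#' Splits the trajectory into contiguous blocks, computes the cumulant
#' spectrum independently on each block, and reports the across-block mean
#' and standard error at each Q. This is the package's standard error
#' estimate for trajectory-derived spectra.
#'
#' @param traj,system,Q_list,n_orientations,origin_stride,selection as in
#'   [coherent_isf()].
#' @param fit_window,component,temperature as in [diffusion_spectrum()].
#' @param n_blocks number of contiguous blocks (default 8).
#' @param max_lag,n_lags per-block lag grid controls (see [coherent_isf()]).
#' @return A `diff_spectrum` with an `se` column.
#' @export
spectrum_with_error <- function(traj, system, Q_list, fit_window,
                                n_blocks = 8, n_orientations = 64,
                                max_lag = NULL, n_lags = 40,
                                origin_stride = 1, selection = NULL,
                                component = "effective",
                                temperature = NA_real_) {
  F <- traj$nframes
  bounds <- floor(seq(0, F, length.out = n_blocks + 1))
  Dmat <- matrix(NA_real_, n_blocks, length(Q_list))
  for (bkt in seq_len(n_blocks)) {
    idx <- (bounds[bkt] + 1):bounds[bkt + 1]
    sub <- trajectory(traj$coords[idx, , , drop = FALSE], dt = traj$dt,
                      kind = traj$kind)
    curves <- coherent_isf(sub, system, Q_list,
                           n_orientations = n_orientations,
                           max_lag = max_lag, n_lags = n_lags,
                           origin_stride = origin_stride,
                           selection = selection)
    sp <- suppressWarnings(diffusion_spectrum(curves, fit_window,
                                              component = component))
    Dmat[bkt, ] <- sp$D
  }
  D <- colMeans(Dmat)
  se <- apply(Dmat, 2, sd) / sqrt(n_blocks)
  o <- order(Q_list)
  diffusion_spectrum_obj(Q_list[o], D[o], component = component,
                         temperature = temperature, se = se[o])
}

#' Write ISF curves as tidy CSV
#' @param curves list of `isf_curve`.
#' @param file output path; columns `Q`, `t`, `isf`.
#' @return `file`, invisibly.
#' @export
write_isf_csv <- function(curves, file) {
  df <- do.call(rbind, lapply(curves, function(cu)
    data.frame(Q = cu$Q, t = cu$lags, isf = cu$values)))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a diffusion spectrum as tidy CSV
#' @param spectrum a `diff_spectrum`.
#' @param file output path; columns `Q`, `D`, (`se`), `component`,
#'   `temperature`.
#' @return `file`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, file) {
  df <- as.data.frame(spectrum)
  df$component <- attr(spectrum, "component")
  df$temperature <- attr(spectrum, "temperature")
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
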