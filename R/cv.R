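#' Collective loop-distance variable
#'
#' Per-frame collective distance between the catalytic loops of two
#' subunits: the mean over matched Calpha pairs of the interatomic distance
#' \eqn{|r_i^\alpha - r_i^\beta|}. The mean (rather than the raw sum) keeps
#' d in Angstrom as a physical distance; `reduce = "sum"` exposes the
#' unnormalized convention.
#'
#' @param traj a [trajectory()].
#' @param system the matching [scattering_system()].
#' @param loop_range `c(lo, hi)` residue-number range of the loop (e.g. the
#'   catalytic loop Ala95-Arg105 of muscle LDH would be `c(95, 105)`).
#' @param chain_a,chain_b chain ids of the two subunits.
#' @param reduce `"mean"` (default) or `"sum"` over the matched pairs.
#' @return Object of class `cv_trace`: `values` (A), `dt` (ns),
#'   `definition`.
#' @export
loop_cv <- function(traj, system, loop_range, chain_a, chain_b,
                    reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(traj, "traj"), inherits(system, "scat_system"))
  ia <- select_atoms(system, chains = chain_a, resno_range = loop_range)
  ib <- select_atoms(system, chains = chain_b, resno_range = loop_range)
  # match by residue number
  ra <- system$atom$resno[ia]; rb <- system$atom$resno[ib]
  common <- intersect(ra, rb)
  if (length(common) == 0L) stop("no matched residues between the two loops")
  ia <- ia[match(common, ra)]
  ib <- ib[match(common, rb)]
  dx <- traj$coords[, ia, 1, drop = FALSE] - traj$coords[, ib, 1, drop = FALSE]
  dy <- traj$coords[, ia, 2, drop = FALSE] - traj$coords[, ib, 2, drop = FALSE]
  dz <- traj$coords[, ia, 3, drop = FALSE] - traj$coords[, ib, 3, drop = FALSE]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  dim(dist) <- c(traj$nframes, length(common))
  vals <- if (reduce == "mean") rowMeans(dist) else rowSums(dist)
  cv_trace(vals, traj$dt,
           definition = sprintf("loop %d-%d, chains %s-%s (%s over %d pairs)",
                                loop_range[1], loop_range[2], chain_a,
                                chain_b, reduce, length(common)))
}

#' CV trace constructor
#' @param values positive distance values (Angstrom).
#' @param dt time step in ns.
#' @param definition free-text definition of the variable.
#' @return Object of class `cv_trace`.
#' @export
cv_trace <- function(values, dt, definition = "") {
  if (length(values) < 2L) stop("a CV trace needs at least 2 points")
  if (any(values <= 0)) stop("CV values must be positive distances")
  if (dt <= 0) stop("dt must be positive")
  structure(list(values = as.numeric(values), dt = dt,
                 definition = definition), class = "cv_trace")
}

#' @export
print.cv_trace <- function(x, ...) {
  cat(sprintf("CV trace: %d points, dt = %g ns, mean = %.3g A, sd = %.3g A\n",
              length(x$values), x$dt, mean(x$values), sd(x$values)))
  if (nzchar(x$definition)) cat("  ", x$definition, "\n")
  invisible(x)
}

#' Normalized autocorrelation of a CV trace
#'
#' Mean-subtracted time autocorrelation computed by FFT with explicit
#' zero-padding, normalized so ACF(0) = 1.
#'
#' @param trace a [cv_trace()].
#' @param max_lag maximum lag in frames (default: half the trace).
#' @return Data frame with columns `t` (ns) and `acf`.
#' @export
autocorrelation <- function(trace, max_lag = NULL) {
  stopifnot(inherits(trace, "cv_trace"))
  x <- trace$values - mean(trace$values)
  n <- length(x)
  if (var(trace$values) == 0)
    stop("constant trace: autocorrelation undefined (zero variance)")
  if (is.null(max_lag)) max_lag <- floor(n / 2)
  npad <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, rep(0, npad - n)))
  ac <- Re(fft(Mod(f)^2, inverse = TRUE))[1:(max_lag + 1)]
  ac <- ac / (n - 0:max_lag)     # unbiased lag normalization
  data.frame(t = (0:max_lag) * trace$dt, acf = ac / ac[1])
}

#' Harmonic-approximation diffusivity of a collective variable
#'
#' Estimates \eqn{D = \langle \delta d^2 \rangle / \tau}: the stationary
#' variance of the CV divided by its decorrelation time, the latter
#' obtained from a least-squares exponential fit of the initial decay of
#' the autocorrelation function (down to `fit_fraction` of its initial
#' value, default 1/e). For an Ornstein-Uhlenbeck coordinate this estimator
#' is exact in the long-trace limit.
#'
#' @param trace a [cv_trace()].
#' @param fit_fraction ACF level terminating the fitted initial decay
#'   (default `exp(-1)`).
#' @return Object of class `harmonic_diffusivity`: `variance` (A^2), `tau`
#'   (ns), `D = variance/tau` (A^2/ns), `n_fit` points used, `acf`.
#' @export
harmonic_diffusivity <- function(trace, fit_fraction = exp(-1)) {
  stopifnot(inherits(trace, "cv_trace"))
  v <- var(trace$values) * (length(trace$values) - 1) / length(trace$values)
  if (v == 0) stop("zero variance: diffusivity undefined")
  ac <- autocorrelation(trace)
  below <- which(ac$acf <= fit_fraction)
  if (length(below) == 0L)
    stop("ACF does not decay to the fit fraction within the trace; ",
         "use a longer trace")
  nfit <- max(3L, below[1])
  sel <- seq_len(nfit)
  pos <- ac$acf[sel] > 0
  fit <- lm.fit(cbind(ac$t[sel][pos]), log(ac$acf[sel][pos]))
  slope <- unname(fit$coefficients[1])
  if (!is.finite(slope) || slope >= 0)
    stop("ACF initial decay fit failed (non-decaying ACF)")
  tau <- -1 / slope
  T_trace <- length(trace$values) * trace$dt
  if (tau > T_trace / 5)
    stop(sprintf(paste("decorrelation time (%.3g ns) is comparable to the",
                       "trace length (%.3g ns); use a longer trace"),
                 tau, T_trace))
  structure(list(variance = v, tau = tau, D = v / tau, n_fit = nfit,
                 acf = ac), class = "harmonic_diffusivity")
}

#' @export
print.harmonic_diffusivity <- function(x, ...) {
  cat(sprintf("Harmonic diffusivity: var = %.4g A^2, tau = %.4g ns, D = %.4g A^2/ns\n",
              x$variance, x$tau, x$D))
  invisible(x)
}

#' Geometric classification of active-site states
#'
#' Labels every frame by a decision list over internal distances and one
#' orientation test, the three-state picture of the catalytic arginine:
#' \itemize{
#'   \item `T_IP`: inactive state with the arginine-aspartate ion pair
#'     formed (minimum heavy-atom distance below `saltbridge_cutoff`);
#'   \item `R`: active state, aspartate in contact with the catalytic
#'     histidine (minimum distance below `contact_cutoff`);
#'   \item `T_out`: inactive state with the arginine side chain pointing
#'     out of the pocket (its base-to-tip vector makes an obtuse angle with
#'     the direction to the pocket center).
#' }
#' Frames matching none of the three tests get the label of the nearest
#' criterion and are counted as ambiguous. All criteria are internal, so
#' labels are invariant under rigid roto-translation of the frame.
#'
#' @param traj a [trajectory()].
#' @param system the matching [scattering_system()].
#' @param criteria list with fields `arg_atoms`, `asp_atoms`, `his_atoms`
#'   (atom index vectors for the side-chain groups), `arg_vec_atoms`
#'   (`c(base, tip)` atom indices of the arginine side-chain vector),
#'   `pocket_atoms` (atoms whose centroid defines the pocket center),
#'   `saltbridge_cutoff` (default 4.0 A), `contact_cutoff` (default 4.0 A).
#' @return List: `states` (factor per frame with levels `T_IP`, `R`,
#'   `T_out`), `occupancy` (named fractions), `n_ambiguous`.
#' @export
classify_active_site <- function(traj, system, criteria) {
  stopifnot(inherits(traj, "traj"))
  req <- c("arg_atoms", "asp_atoms", "his_atoms", "arg_vec_atoms",
           "pocket_atoms")
  miss <- setdiff(req, names(criteria))
  if (length(miss) > 0)
    stop("criteria missing fields: ", paste(miss, collapse = ", "))
  sb_cut <- criteria$saltbridge_cutoff %||% 4.0
  ct_cut <- criteria$contact_cutoff %||% 4.0
  F <- traj$nframes
  states <- character(F)
  ambiguous <- logical(F)
  mindist <- function(fr, ia, ib) {
    da <- fr[ia, , drop = FALSE]; db <- fr[ib, , drop = FALSE]
    min(sqrt(outer(rowSums(da^2), rowSums(db^2), "+") - 2 * da %*% t(db)))
  }
  for (f in seq_len(F)) {
    fr <- matrix(traj$coords[f, , ], ncol = 3)
    d_ip <- mindist(fr, criteria$arg_atoms, criteria$asp_atoms)
    d_hc <- mindist(fr, criteria$asp_atoms, criteria$his_atoms)
    base <- fr[criteria$arg_vec_atoms[1], ]
    tip <- fr[criteria$arg_vec_atoms[2], ]
    pocket <- colMeans(fr[criteria$pocket_atoms, , drop = FALSE])
    outward <- sum((tip - base) * (pocket - base)) < 0
    if (d_ip < sb_cut) {
      states[f] <- "T_IP"
    } else if (d_hc < ct_cut) {
      states[f] <- "R"
    } else if (outward) {
      states[f] <- "T_out"
    } else {
      # nearest criterion wins; flagged ambiguous
      states[f] <- c("T_IP", "R")[which.min(c(d_ip - sb_cut, d_hc - ct_cut))]
      ambiguous[f] <- TRUE
    }
  }
  states <- factor(states, levels = c("T_IP", "R", "T_out"))
  occ <- table(states) / F
  list(states = states, occupancy = as.numeric(occ) |>
         setNames(names(occ)), n_ambiguous = sum(ambiguous))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CV trace (and optional states) as CSV
#' @param trace a `cv_trace`.
#' @param file output path.
#' @param states optional per-frame state factor of matching length.
#' @return `file`, invisibly.
#' @export
write_cv_csv <- function(trace, file, states = NULL) {
  df <- data.frame(t = (seq_along(trace$values) - 1) * trace$dt,
                   d = trace$values)
  if (!is.null(states)) df$state <- states
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
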