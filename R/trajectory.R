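#' Build a trajectory
#'
#' A `traj` wraps an F x N x 3 coordinate array (Angstrom) with a frame
#' spacing `dt` (ns) and a processing tag recording what has been removed
#' from the raw dynamics.
#'
#' @param coords F x N x 3 numeric array.
#' @param dt frame spacing in ns (> 0).
#' @param kind processing tag, one of `"raw"`, `"translation_removed"`,
#'   `"rototranslation_removed"`, `"mode_projected"`, `"excised"`.
#' @param provenance free-text note on how the trajectory was produced.
#' @param rotations optional F x 9 matrix of body-to-lab rotation matrices
#'   (column-major), carried by the synthetic rigid-body generator.
#' @return Object of class `traj`.
#' @export
trajectory <- function(coords, dt,
                       kind = c("raw", "translation_removed",
                                "rototranslation_removed", "mode_projected",
                                "excised"),
                       provenance = "", rotations = NULL) {
  kind <- match.arg(kind)
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L) stop("coords must be an F x N x 3 array")
  if (d[1] < 2L) stop("a trajectory needs at least 2 frames")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  if (anyNA(coords)) stop("non-finite coordinates in trajectory")
  structure(list(coords = coords, dt = dt, kind = kind,
                 provenance = provenance, rotations = rotations,
                 nframes = d[1], natoms = d[2]),
            class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %g ns, kind = %s\n",
              x$nframes, x$natoms, x$dt, x$kind))
  if (nzchar(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' Extract one frame as an N x 3 matrix
#' @param traj a `traj`.
#' @param i frame index.
#' @return N x 3 coordinate matrix.
#' @export
traj_frame <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L)
}

#' Read a DCD trajectory
#'
#' Thin wrapper over [bio3d::read.dcd()] returning a [trajectory()].
#'
#' @param file path to a DCD file.
#' @param dt frame spacing in ns (DCD headers are not trusted for units).
#' @param ... passed to [trajectory()] (e.g. `kind`).
#' @return A `traj`.
#' @export
read_trajectory_dcd <- function(file, dt, ...) {
  m <- bio3d::read.dcd(file, verbose = FALSE)
  n <- ncol(m) / 3L
  coords <- array(0, c(nrow(m), n, 3L))
  coords[, , 1] <- m[, seq(1L, ncol(m), by = 3L)]
  coords[, , 2] <- m[, seq(2L, ncol(m), by = 3L)]
  coords[, , 3] <- m[, seq(3L, ncol(m), by = 3L)]
  trajectory(coords, dt = dt, provenance = paste("read from", file), ...)
}

#' Write a trajectory to DCD
#'
#' Minimal single-precision CHARMM-format DCD writer (no unit cell), for
#' inspection of processed trajectories in standard viewers; readable by
#' [bio3d::read.dcd()].
#'
#' @param traj a `traj`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- traj$nframes   # NSET
  icntrl[2] <- 1L             # ISTART
  icntrl[3] <- 1L             # NSAVC
  icntrl[20] <- 24L           # CHARMM version tag
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl[1:9], con, size = 4)
    writeBin(as.numeric(traj$dt), con, size = 4)  # DELTA (float slot)
    writeBin(icntrl[11:20], con, size = 4)
  }, 84)
  title <- sprintf("%-80s", paste("nsemd trajectory, kind:", traj$kind))
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(substr(title, 1, 80), con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(traj$natoms), con, size = 4), 4)
  nb <- 4L * traj$natoms
  for (f in seq_len(traj$nframes)) for (k in 1:3)
    rec(function() writeBin(as.numeric(traj$coords[f, , k]), con, size = 4),
        nb)
  invisible(file)
}

#' Subset trajectory atoms
#' @param traj a `traj`.
#' @param indices atom indices to keep.
#' @param kind tag for the result (defaults to the input tag).
#' @return A `traj` restricted to `indices`.
#' @export
subset_traj <- function(traj, indices, kind = traj$kind) {
  trajectory(traj$coords[, indices, , drop = FALSE], dt = traj$dt,
             kind = kind, provenance = traj$provenance,
             rotations = traj$rotations)
}
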