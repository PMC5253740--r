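#' Coherent neutron scattering lengths
#'
#' Bound coherent scattering lengths b (fm) for the elements common in
#' proteins, from the standard neutron data tables (Sears). `"D"` is
#' deuterium. Only ratios of b enter normalized observables, so relative
#' units are acceptable throughout.
#'
#' @return Named numeric vector of scattering lengths in fm.
#' @export
neutron_scattering_lengths <- function() {
  c(H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803,
    S = 2.847, P = 5.13, FE = 9.45, ZN = 5.68, MG = 5.375,
    CA = 4.70, "NA" = 3.63, CL = 9.577, K = 3.67, MN = -3.73, CU = 7.718)
}

#' Build a scattering system
#'
#' A `scat_system` holds the static description of the scatterers: positions
#' \eqn{r_k} (\eqn{\mathrm{\AA}}), coherent scattering lengths \eqn{b_k}, and
#' per-atom labels used for selections. It is the single-structure input to
#' the intermediate-scattering-function and rigid-body-spectrum calculations.
#'
#' @param xyz N x 3 numeric matrix of coordinates (Angstrom).
#' @param b numeric vector of N coherent scattering lengths (fm or relative
#'   units; only ratios matter). At least one must be non-zero.
#' @param element,chain,resno,resid optional per-atom labels (element symbol,
#'   chain id, residue number, residue name); defaults are generated.
#' @return Object of class `scat_system` with fields `xyz`, `b`, `atom`
#'   (data frame of labels) and `natoms`.
#' @export
scattering_system <- function(xyz, b = NULL, element = NULL, chain = NULL,
                              resno = NULL, resid = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must be an N x 3 matrix")
  n <- nrow(xyz)
  if (n < 1L) stop("scattering system needs at least one atom")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(b)) b <- rep(1, n)
  b <- as.numeric(b)
  if (length(b) == 1L) b <- rep(b, n)
  if (length(b) != n) stop("length(b) must equal nrow(xyz)")
  if (!all(is.finite(b))) stop("non-finite scattering lengths")
  if (all(b == 0)) stop("all scattering lengths are zero")
  atom <- data.frame(
    element = if (is.null(element)) rep("X", n) else as.character(element),
    chain   = if (is.null(chain)) rep("A", n) else as.character(chain),
    resno   = if (is.null(resno)) seq_len(n) else as.integer(resno),
    resid   = if (is.null(resid)) rep("RES", n) else as.character(resid),
    stringsAsFactors = FALSE)
  structure(list(xyz = xyz, b = b, atom = atom, natoms = n),
            class = "scat_system")
}

#' @export
print.scat_system <- function(x, ...) {
  cat("Scattering system:", x$natoms, "atoms,",
      length(unique(x$atom$chain)), "chain(s),",
      length(unique(paste(x$atom$chain, x$atom$resno))), "residues\n")
  invisible(x)
}

#' Read a scattering system from a PDB file
#'
#' Builds a [scattering_system()] from a PDB structure. By default protein
#' atoms only (solvent never enters the ISF), with per-element coherent
#' neutron scattering lengths. Exchangeable hydrogens (those bound to N, O,
#' S) can be set to the deuterium length to emulate a D2O buffer; synthetic
#' or coarse-grained structures can use a uniform b.
#'
#' @param file path to a PDB file.
#' @param chains optional character vector of chain ids to keep.
#' @param selection `"protein"` (default), `"calpha"`, or `"all"`.
#' @param b_mode `"element"` for tabulated coherent lengths, `"uniform"` for
#'   b = 1 everywhere.
#' @param deuterate_exchangeables if `TRUE`, hydrogens named like amide or
#'   hydroxyl H are assigned the deuterium scattering length.
#' @return A `scat_system`.
#' @export
system_from_pdb <- function(file, chains = NULL,
                            selection = c("protein", "calpha", "all"),
                            b_mode = c("element", "uniform"),
                            deuterate_exchangeables = FALSE) {
  selection <- match.arg(selection)
  b_mode <- match.arg(b_mode)
  pdb <- bio3d::read.pdb(file)
  sel <- switch(selection,
                protein = bio3d::atom.select(pdb, "protein"),
                calpha  = bio3d::atom.select(pdb, "calpha"),
                all     = bio3d::atom.select(pdb, "all"))
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) stop("selection is empty")
  elem <- toupper(at$elesy)
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- toupper(substr(gsub("[0-9]", "", at$elety[bad]), 1, 1))
  b <- if (b_mode == "uniform") rep(1, nrow(at)) else {
    tab <- neutron_scattering_lengths()
    out <- tab[elem]
    if (any(is.na(out)))
      stop("no tabulated scattering length for element(s): ",
           paste(unique(elem[is.na(out)]), collapse = ", "))
    unname(out)
  }
  if (deuterate_exchangeables && b_mode == "element") {
    exch <- elem == "H" & grepl("^(H|HN|HT[0-9]?|HG1?|HH[0-9]*|HE|HD1|HZ[0-9]?|HO)$", at$elety)
    b[exch] <- neutron_scattering_lengths()[["D"]]
  }
  scattering_system(cbind(at$x, at$y, at$z), b = b, element = elem,
                    chain = at$chain, resno = at$resno, resid = at$resid)
}

#' Select atoms of a scattering system
#'
#' @param system a `scat_system`.
#' @param chains optional chain ids to keep.
#' @param resno_range optional `c(lo, hi)` residue number range to keep.
#' @param indices optional explicit atom indices (applied after the above).
#' @return Integer vector of atom indices into `system`.
#' @export
select_atoms <- function(system, chains = NULL, resno_range = NULL,
                         indices = NULL) {
  stopifnot(inherits(system, "scat_system"))
  keep <- rep(TRUE, system$natoms)
  if (!is.null(chains)) keep <- keep & system$atom$chain %in% chains
  if (!is.null(resno_range))
    keep <- keep & system$atom$resno >= resno_range[1] &
      system$atom$resno <= resno_range[2]
  idx <- which(keep)
  if (!is.null(indices)) idx <- intersect(idx, indices)
  if (length(idx) == 0L) stop("selection is empty")
  idx
}

#' Subset a scattering system
#'
#' @param system a `scat_system`.
#' @param indices atom indices to keep.
#' @return A `scat_system` restricted to `indices`.
#' @export
subset_system <- function(system, indices) {
  stopifnot(inherits(system, "scat_system"))
  scattering_system(system$xyz[indices, , drop = FALSE], system$b[indices],
                    element = system$atom$element[indices],
                    chain = system$atom$chain[indices],
                    resno = system$atom$resno[indices],
                    resid = system$atom$resid[indices])
}
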