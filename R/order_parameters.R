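# Per-frame scalar descriptors: the Salpha helical order parameter, radius
# of gyration, and a transparent dihedral-based helical fraction (a
# documented stand-in for secondary-structure assignment, not DSSP).

#' Single-window term of the Salpha order parameter
#'
#' The smoothed indicator (1 - x^8) / (1 - x^12) with x = rmsd / r0,
#' continuous and strictly decreasing from 1 (x = 0) through the analytic
#' limit 2/3 at the removable singularity x = 1 toward 0.
#'
#' @param rmsd window C-alpha RMSD to the ideal helix template, Angstrom.
#' @param r0 switching length, Angstrom (default 1.0).
#' @return dimensionless value in (0, 1]. Vectorized over `rmsd`.
#' @export
salpha_term <- function(rmsd, r0 = 1.0) {
  if (any(rmsd < 0)) stop("rmsd must be non-negative")
  if (r0 <= 0) stop("r0 must be positive")
  x <- rmsd / r0
  out <- ifelse(abs(x - 1) < 1e-9, 2 / 3, (1 - x^8) / (1 - x^12))
  out
}

# 7-residue ideal-helix C-alpha template (Angstrom), cached per session.
.salpha_template <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) {
      h <- build_ideal_helix(7)
      ca <- select_atoms(h, atom_names = "CA")
      tmpl <<- get_frame(h, 1)[ca, , drop = FALSE] / .ANG2NM
    }
    tmpl
  }
})

#' Salpha helical order parameter
#'
#' Sum over all consecutive seven-residue C-alpha windows of the
#' [salpha_term()] evaluated on the window's RMSD to an ideal helical
#' template (phi = -57, psi = -47) after optimal superposition. A fully
#' helical n-residue chain scores close to n - 6; a chain with no helical
#' content scores close to 0.
#'
#' @param ens an `Ensemble` (protein atoms are used; a ligand is ignored).
#' @param frames frame indices (default all).
#' @param r0 switching length in Angstrom (default 1.0).
#' @return numeric vector of per-frame Salpha values.
#' @export
salpha <- function(ens, frames = NULL, r0 = 1.0) {
  ca <- select_atoms(ens, atom_names = "CA", ligand = FALSE)
  if (length(ca) < 7) stop("Salpha needs at least 7 residues with CA atoms")
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  tmpl <- .salpha_template()
  vapply(frames, function(f) {
    .cpp_salpha(get_frame(ens, f)[ca, , drop = FALSE] / .ANG2NM, tmpl, r0)
  }, numeric(1))
}

#' Radius of gyration
#'
#' Mass-weighted Rg over the selected atoms (default: all heavy atoms).
#' Set `ca_only = TRUE` for an unweighted C-alpha-only convention.
#'
#' @param ens an `Ensemble`.
#' @param frames frame indices (default all).
#' @param atoms optional atom-id selection; default all heavy atoms.
#' @param ca_only use C-alpha atoms with unit masses.
#' @return numeric vector of per-frame Rg in nm.
#' @export
radius_of_gyration <- function(ens, frames = NULL, atoms = NULL,
                               ca_only = FALSE) {
  a <- ens$topology$atoms
  if (ca_only) {
    atoms <- select_atoms(ens, atom_names = "CA", ligand = FALSE)
    mass <- rep(1, length(atoms))
  } else {
    if (is.null(atoms)) atoms <- select_atoms(ens, heavy_only = TRUE)
    mass <- element_mass(a$element[atoms])
  }
  if (length(atoms) < 2) stop("Rg needs at least 2 selected atoms")
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  vapply(frames, function(f) {
    .cpp_rg(get_frame(ens, f)[atoms, , drop = FALSE], mass)
  }, numeric(1))
}

#' Dihedral-based helical fraction
#'
#' A residue is counted helical iff phi in (-100, -30) deg, psi in
#' (-77, -17) deg, and it belongs to a run of at least `min_run`
#' consecutive such residues. Chain termini without complete dihedrals are
#' excluded from the denominator. This is a transparent dihedral criterion,
#' not DSSP.
#'
#' @param ens an `Ensemble`.
#' @param frames frame indices (default all).
#' @param min_run minimum helical run length (default 4).
#' @return list with `fraction` (per-frame helical fraction) and
#'   `indicators` (frames x residues 0/1 matrix, NA at termini).
#' @export
helical_fraction <- function(ens, frames = NULL, min_run = 4) {
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  prot <- ens$topology$atoms[!ens$topology$atoms$ligand, ]
  n <- max(prot$res_index)
  ind <- matrix(NA_real_, length(frames), n)
  frac <- numeric(length(frames))
  for (k in seq_along(frames)) {
    pp <- backbone_dihedrals(ens, frames[k])
    ok <- !is.na(pp[, 1]) & !is.na(pp[, 2])
    hel <- ok & pp[, 1] > -100 & pp[, 1] < -30 & pp[, 2] > -77 & pp[, 2] < -17
    hel[is.na(hel)] <- FALSE
    runs <- rle(hel)
    runs$values <- runs$values & runs$lengths >= min_run
    hel_run <- inverse.rle(runs)
    ind[k, ok] <- as.numeric(hel_run[ok])
    frac[k] <- if (any(ok)) sum(hel_run[ok]) / sum(ok) else NA_real_
  }
  list(fraction = frac, indicators = ind)
}

#' Per-frame descriptor table
#'
#' @param ens an `Ensemble`.
#' @param frames frame indices (default all).
#' @return data.frame (frame, salpha, rg, helix_fraction) with the
#'   per-residue helicity indicator matrix in attribute `indicators`.
#' @export
frame_descriptors <- function(ens, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  hf <- helical_fraction(ens, frames)
  out <- data.frame(frame = frames,
                    salpha = salpha(ens, frames),
                    rg = radius_of_gyration(ens, frames),
                    helix_fraction = hf$fraction)
  attr(out, "indicators") <- hf$indicators
  out
}
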