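# Core data model: Topology, Ensemble, ObservableTable.

#' Construct a molecular topology
#'
#' A topology names the residues and atoms of a system and carries the
#' chemical annotations that Cartesian coordinates cannot supply: element,
#' heavy-atom flag, hydrogen-bond donor/acceptor status, hydrophobic flag
#' (carbon, and chlorine on ligands), aromatic ring groups, and which atoms
#' belong to a ligand. Donors are N/O/S atoms with at least one attached
#' hydrogen; acceptors are N/O/S atoms.
#'
#' @param atoms data.frame with columns `id` (integer, 1..n), `res_index`
#'   (1-based internal residue index), `res_number` (author-facing residue
#'   number), `res_name`, `atom_name`, `element`, `heavy`, `donor`,
#'   `acceptor`, `hydrophobic`, `ligand` (logicals).
#' @param attached_h named list mapping donor atom id (as character) to the
#'   integer ids of its attached hydrogens.
#' @param ring_groups named list of integer atom-id vectors (>= 3 heavy
#'   atoms each) defining aromatic rings.
#' @return object of class `Topology`.
#' @export
topology <- function(atoms, attached_h = list(), ring_groups = list()) {
  req <- c("id", "res_index", "res_number", "res_name", "atom_name",
           "element", "heavy", "donor", "acceptor", "hydrophobic", "ligand")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("topology atoms missing column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, req]
  top <- structure(list(atoms = atoms, attached_h = attached_h,
                        ring_groups = ring_groups), class = "Topology")
  validate_topology(top)
  top
}

#' Validate a Topology
#' @param top a `Topology`.
#' @return invisibly `top`; stops on violation.
#' @export
validate_topology <- function(top) {
  a <- top$atoms
  if (!identical(a$id, seq_len(nrow(a)))) stop("atom ids must be 1..n in order")
  if (any(a$res_index < 1)) stop("invalid residue indices")
  pol <- toupper(a$element) %in% c("N", "O", "S")
  if (any(a$donor & !pol)) stop("donor atoms must be N, O or S")
  if (any(a$acceptor & !pol)) stop("acceptor atoms must be N, O or S")
  for (id in which(a$donor)) {
    h <- top$attached_h[[as.character(id)]]
    if (is.null(h) || !length(h))
      stop("donor atom ", id, " (", a$atom_name[id], ") has no attached hydrogen")
    if (any(toupper(a$element[h]) != "H"))
      stop("attached_h of atom ", id, " lists non-hydrogen atoms")
  }
  for (nm in names(top$ring_groups)) {
    g <- top$ring_groups[[nm]]
    if (length(g) < 3) stop("ring group '", nm, "' has fewer than 3 atoms")
    if (!all(a$heavy[g])) stop("ring group '", nm, "' contains hydrogens")
  }
  invisible(top)
}

#' @export
print.Topology <- function(x, ...) {
  a <- x$atoms
  cat("Topology:", max(a$res_index), "residues,", nrow(a), "atoms",
      sprintf("(%d ligand)", sum(a$ligand)), "\n")
  cat("  donors:", sum(a$donor), " acceptors:", sum(a$acceptor),
      " hydrophobic:", sum(a$hydrophobic),
      " ring groups:", length(x$ring_groups), "\n")
  invisible(x)
}

#' Construct a conformational ensemble
#'
#' @param topology a `Topology`.
#' @param coords numeric array of dimension (frames, atoms, 3), in nm.
#' @param weights optional non-negative per-frame weights; normalized to
#'   sum to 1. Default uniform.
#' @param provenance free-text label.
#' @return object of class `Ensemble`.
#' @export
ensemble <- function(topology, coords, weights = NULL, provenance = "") {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be a (frames x atoms x 3) array")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("coordinate block has ", dim(coords)[2], " atoms; topology has ",
         nrow(topology$atoms))
  nf <- dim(coords)[1]
  if (is.null(weights)) weights <- rep(1 / nf, nf)
  if (length(weights) != nf) stop("weights length must equal frame count")
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  structure(list(topology = topology, coords = coords, weights = weights / s,
                 provenance = provenance), class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", n_frames(x), "frames x", dim(x$coords)[2], "atoms")
  if (nzchar(x$provenance)) cat("  [", x$provenance, "]", sep = "")
  cat("\n")
  print(x$topology)
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an `Ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' Extract one frame's coordinates
#' @param ens an `Ensemble`.
#' @param i frame index.
#' @return (atoms x 3) coordinate matrix in nm.
#' @export
get_frame <- function(ens, i) {
  if (i < 1 || i > n_frames(ens)) stop("frame index out of range")
  matrix(ens$coords[i, , ], ncol = 3)
}

#' Select atoms by residue range, atom name, heaviness, and ligand status
#'
#' Returns a stable, ordered, deduplicated atom-id list. An empty result is
#' signalled with a warning of class `empty_selection` so callers can decide
#' severity.
#'
#' @param ens an `Ensemble` (or a `Topology`).
#' @param residues optional integer vector of internal residue indices.
#' @param atom_names optional character vector of atom names (e.g. "CA").
#' @param heavy_only if TRUE, exclude hydrogens.
#' @param ligand NULL (no filter), TRUE (ligand atoms only) or FALSE
#'   (protein atoms only).
#' @return integer vector of atom ids.
#' @export
select_atoms <- function(ens, residues = NULL, atom_names = NULL,
                         heavy_only = FALSE, ligand = NULL) {
  a <- if (inherits(ens, "Topology")) ens$atoms else ens$topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(residues)) keep <- keep & a$res_index %in% residues
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  if (heavy_only) keep <- keep & a$heavy
  if (!is.null(ligand)) keep <- keep & (a$ligand == ligand)
  ids <- a$id[keep]
  if (!length(ids))
    warning(warningCondition("atom selection is empty",
                             class = c("empty_selection", "warning")))
  ids
}

#' Construct a per-frame observable table
#'
#' Holds per-frame predicted observables (e.g. chemical shifts from an
#' upstream predictor), one column per observable, together with the
#' experimental target value and uncertainty for each observable.
#'
#' @param values numeric matrix, frames x observables.
#' @param targets numeric vector of experimental targets, one per column.
#' @param uncertainties positive numeric vector, one per column.
#' @param labels optional observable names; default taken from colnames.
#' @return object of class `ObservableTable`.
#' @export
observable_table <- function(values, targets, uncertainties, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("obs", seq_len(ncol(values)))
  if (length(targets) != ncol(values) || length(uncertainties) != ncol(values))
    stop("targets/uncertainties must have one entry per observable column")
  if (any(uncertainties <= 0)) stop("uncertainties must be positive")
  colnames(values) <- labels
  structure(list(values = values, targets = setNames(as.numeric(targets), labels),
                 uncertainties = setNames(as.numeric(uncertainties), labels),
                 labels = labels), class = "ObservableTable")
}

#' @export
print.ObservableTable <- function(x, ...) {
  cat("ObservableTable:", nrow(x$values), "frames x", ncol(x$values),
      "observables\n")
  invisible(x)
}
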