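# Backbone construction from dihedrals. Geometry is ideal (fixed bond
# lengths/angles, Engh-Huber-like values); phi/psi are the only degrees of
# freedom, omega is fixed trans. Sufficient for every downstream geometric
# analysis without a force field.

# Atoms emitted per residue, in order.
.BB_ATOMS <- c("N", "H", "CA", "C", "O")
.BB_ELEMENTS <- c("N", "H", "C", "C", "O")

#' Backbone topology for a synthetic chain
#'
#' Five atoms per residue (N, H, CA, C, O). Backbone amide N atoms are
#' hydrogen-bond donors (explicit amide H) and, like carbonyl O, acceptors;
#' carbons are flagged hydrophobic.
#'
#' @param n_residues chain length.
#' @param first_resid author-facing number of the first residue (reports
#'   print these numbers, internal indices are 1-based).
#' @param res_name residue name used in PDB output.
#' @return a `Topology`.
#' @export
backbone_topology <- function(n_residues, first_resid = 1, res_name = "ALA") {
  n <- n_residues
  atoms <- data.frame(
    id = seq_len(5 * n),
    res_index = rep(seq_len(n), each = 5),
    res_number = rep(first_resid + seq_len(n) - 1, each = 5),
    res_name = res_name,
    atom_name = rep(.BB_ATOMS, n),
    element = rep(.BB_ELEMENTS, n),
    stringsAsFactors = FALSE)
  atoms$heavy <- atoms$element != "H"
  atoms$donor <- atoms$atom_name == "N"
  atoms$acceptor <- atoms$element %in% c("N", "O")
  atoms$hydrophobic <- atoms$element == "C"
  atoms$ligand <- FALSE
  ah <- as.list(setNames(which(atoms$atom_name == "H"),
                         which(atoms$atom_name == "N")))
  topology(atoms, attached_h = ah)
}

# Build one frame from dihedrals (degrees); returns coords in nm.
.build_frame <- function(phi, psi) {
  .cpp_build_backbone(phi, psi) * .ANG2NM
}

.single_frame_ensemble <- function(phi, psi, first_resid = 1, label = "") {
  n <- length(phi)
  xyz <- .build_frame(phi, psi)
  coords <- array(0, dim = c(1, nrow(xyz), 3))
  coords[1, , ] <- xyz
  ensemble(backbone_topology(n, first_resid), coords, provenance = label)
}

#' Build an ideal alpha-helical backbone
#'
#' All phi = -57 deg, psi = -47 deg, omega = 180 deg, ideal covalent
#' geometry. Deterministic.
#'
#' @param n_residues chain length (>= 7: shorter chains have no complete
#'   seven-residue window).
#' @param first_resid author-facing first residue number.
#' @return a single-frame `Ensemble`.
#' @export
build_ideal_helix <- function(n_residues, first_resid = 1) {
  if (n_residues < 7) stop("n_residues must be >= 7 (no complete 7-residue window)")
  .single_frame_ensemble(rep(-57, n_residues), rep(-47, n_residues),
                         first_resid, "ideal helix")
}

#' Build a fully extended backbone
#'
#' All phi = -120 deg, psi = 120 deg: an extended chain with no helical
#' content. Deterministic.
#'
#' @inheritParams build_ideal_helix
#' @return a single-frame `Ensemble`.
#' @export
build_extended_chain <- function(n_residues, first_resid = 1) {
  if (n_residues < 7) stop("n_residues must be >= 7 (no complete 7-residue window)")
  .single_frame_ensemble(rep(-120, n_residues), rep(120, n_residues),
                         first_resid, "extended chain")
}

#' Minimal RMSD between two coordinate sets after optimal superposition
#'
#' Kabsch algorithm (proper rotations only, no reflection).
#'
#' @param a,b (m x 3) coordinate matrices in the same units.
#' @return RMSD in the input units.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have equal dimensions")
  .cpp_kabsch_rmsd(a, b)
}

#' Dihedral angle defined by four points
#' @param p1,p2,p3,p4 length-3 numeric vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  .cpp_dihedral(as.numeric(p1), as.numeric(p2), as.numeric(p3), as.numeric(p4))
}

#' Backbone phi/psi dihedrals of an ensemble
#'
#' @param ens an `Ensemble` whose protein part follows the 5-atom backbone
#'   layout of [backbone_topology()].
#' @param frame frame index.
#' @return matrix (residues x 2) of phi, psi in degrees; NA where undefined
#'   (phi of residue 1, psi of the last residue).
#' @export
backbone_dihedrals <- function(ens, frame = 1) {
  prot <- ens$topology$atoms[!ens$topology$atoms$ligand, ]
  n <- max(prot$res_index)
  xyz <- get_frame(ens, frame)[prot$id, , drop = FALSE]
  out <- .cpp_backbone_phipsi(xyz, n)
  colnames(out) <- c("phi", "psi")
  out
}
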