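# Geometric interaction classification: contacts, hydrophobic contacts,
# hydrogen bonds, and aromatic stacking, aggregated into per-residue
# population profiles. All distance cutoffs are inclusive (<=): "within"
# is read inclusively, and the boundary tests document it.

#' Default interaction cutoffs
#'
#' Contact 6.0 A heavy-heavy; hydrophobic 4.0 A C-C / C-Cl; hydrogen bond
#' 3.5 A hydrogen-to-acceptor with donor-hydrogen-acceptor angle > 150 deg;
#' parallel stacking R < 6.5 A, theta < 60 deg, phi < 45 deg; T-stacking
#' R < 7.5 A, theta > 75 deg, phi < 45 deg. Stored in nm internally.
#'
#' @return named list of cutoffs (lengths in nm, angles in degrees).
#' @export
interaction_cutoffs <- function() {
  list(contact = 6.0 * .ANG2NM, hydrophobic = 4.0 * .ANG2NM,
       hbond_dist = 3.5 * .ANG2NM, hbond_angle = 150,
       parallel_r = 6.5 * .ANG2NM, parallel_theta = 60, parallel_phi = 45,
       tstack_r = 7.5 * .ANG2NM, tstack_theta = 75, tstack_phi = 45)
}

.cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Heavy-atom contact between a residue and a partner atom set
#'
#' TRUE iff any heavy-heavy atom pair between the residue and the partner
#' set lies within the cutoff (inclusive).
#'
#' @param ens an `Ensemble`.
#' @param frame frame index.
#' @param residue internal residue index.
#' @param partner_atoms integer atom ids of the partner group (filtered to
#'   heavy atoms).
#' @param cutoff distance cutoff in nm (default 0.6).
#' @return logical.
#' @export
residue_contact <- function(ens, frame, residue, partner_atoms,
                            cutoff = interaction_cutoffs()$contact) {
  a <- ens$topology$atoms
  res_atoms <- a$id[a$res_index == residue & a$heavy & !a$ligand]
  partner_atoms <- partner_atoms[a$heavy[partner_atoms]]
  if (!length(res_atoms) || !length(partner_atoms))
    stop("residue_contact requires non-empty heavy-atom sets")
  xyz <- get_frame(ens, frame)
  min(.cross_dist(xyz[res_atoms, , drop = FALSE],
                  xyz[partner_atoms, , drop = FALSE])) <= cutoff
}

#' Bound-frame flag and bound fraction
#'
#' A frame is bound iff at least one protein/ligand heavy-atom pair lies
#' within 6.0 A. `bound_fraction()` is the weighted share of bound frames.
#'
#' @param ens an `Ensemble` with ligand atoms in its topology.
#' @param frames frame indices (default all).
#' @param cutoff distance cutoff in nm.
#' @return `bound_frames()`: logical vector; `bound_fraction()`: scalar.
#' @export
bound_frames <- function(ens, frames = NULL,
                         cutoff = interaction_cutoffs()$contact) {
  a <- ens$topology$atoms
  lig <- a$id[a$ligand & a$heavy]
  if (!length(lig)) stop("ensemble has no ligand heavy atoms")
  prot <- a$id[!a$ligand & a$heavy]
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  vapply(frames, function(f) {
    xyz <- get_frame(ens, f)
    min(.cross_dist(xyz[prot, , drop = FALSE], xyz[lig, , drop = FALSE])) <= cutoff
  }, logical(1))
}

#' @rdname bound_frames
#' @export
bound_fraction <- function(ens, frames = NULL,
                           cutoff = interaction_cutoffs()$contact) {
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  b <- bound_frames(ens, frames, cutoff)
  w <- ens$weights[frames]
  sum(w * b) / sum(w)
}

#' Hydrophobic contact between a residue and the ligand
#'
#' TRUE iff any protein-carbon to ligand-carbon, or protein-carbon to
#' ligand-chlorine, pair lies within 4.0 A (inclusive).
#'
#' @inheritParams residue_contact
#' @param ligand_atoms ligand atom ids (default: all ligand atoms).
#' @return logical.
#' @export
hydrophobic_contact <- function(ens, frame, residue, ligand_atoms = NULL,
                                cutoff = interaction_cutoffs()$hydrophobic) {
  a <- ens$topology$atoms
  if (is.null(ligand_atoms)) ligand_atoms <- a$id[a$ligand]
  pc <- a$id[a$res_index == residue & !a$ligand & toupper(a$element) == "C"]
  lc <- ligand_atoms[toupper(a$element[ligand_atoms]) %in% c("C", "CL")]
  if (!length(pc) || !length(lc)) return(FALSE)
  xyz <- get_frame(ens, frame)
  min(.cross_dist(xyz[pc, , drop = FALSE], xyz[lc, , drop = FALSE])) <= cutoff
}

#' Hydrogen bonds in a frame
#'
#' Donors are N/O/S atoms with explicit attached hydrogens; acceptors are
#' N/O/S atoms. A bond requires hydrogen-acceptor distance <= 3.5 A and
#' donor-hydrogen-acceptor angle > 150 deg; donor and acceptor in the same
#' residue are excluded.
#'
#' @param ens an `Ensemble`.
#' @param frame frame index.
#' @param donors optional donor atom ids (default all flagged donors).
#' @param acceptors optional acceptor atom ids (default all flagged).
#' @param dist_cutoff hydrogen-acceptor distance cutoff, nm.
#' @param angle_cutoff minimum D-H-A angle, degrees.
#' @return data.frame with columns donor, hydrogen, acceptor.
#' @export
hydrogen_bonds <- function(ens, frame, donors = NULL, acceptors = NULL,
                           dist_cutoff = interaction_cutoffs()$hbond_dist,
                           angle_cutoff = interaction_cutoffs()$hbond_angle) {
  a <- ens$topology$atoms
  if (is.null(donors)) donors <- a$id[a$donor]
  if (is.null(acceptors)) acceptors <- a$id[a$acceptor]
  xyz <- get_frame(ens, frame)
  out <- list()
  for (d in donors) {
    hs <- ens$topology$attached_h[[as.character(d)]]
    if (is.null(hs) || !length(hs))
      stop("donor atom ", d, " has no attached hydrogen in the topology")
    acc <- acceptors[a$res_index[acceptors] != a$res_index[d]]
    if (!length(acc)) next
    for (h in hs) {
      dv <- .cross_dist(xyz[h, , drop = FALSE], xyz[acc, , drop = FALSE])[1, ]
      cand <- acc[dv <= dist_cutoff]
      for (ac in cand) {
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[ac, ] - xyz[h, ]
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        if (ang > angle_cutoff)
          out[[length(out) + 1]] <- data.frame(donor = d, hydrogen = h,
                                               acceptor = ac)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  do.call(rbind, out)
}

#' Ring-pair geometry for aromatic stacking
#'
#' Centroid and best-fit plane normal (smallest principal axis of the
#' centered ring coordinates, robust to puckering) for each ring; R is the
#' centroid separation, theta the inter-normal angle and phi the angle
#' between the first ring's normal and the inter-centroid unit vector.
#' Normal sign is arbitrary, so theta and phi are folded to [0, 90] deg via
#' absolute dot products.
#'
#' @param ens an `Ensemble`.
#' @param frame frame index.
#' @param ring_a,ring_b integer atom-id vectors (>= 3 non-collinear atoms);
#'   `ring_a` plays the "protein ring" role in the phi definition.
#' @return list with centroids, normals, `R` (nm), `theta`, `phi` (deg).
#' @export
ring_geometry <- function(ens, frame, ring_a, ring_b) {
  xyz <- get_frame(ens, frame)
  geom1 <- .ring_plane(xyz[ring_a, , drop = FALSE])
  geom2 <- .ring_plane(xyz[ring_b, , drop = FALSE])
  rvec <- geom2$centroid - geom1$centroid
  R <- sqrt(sum(rvec^2))
  rhat <- if (R > 0) rvec / R else c(1, 0, 0)
  theta <- acos(min(1, abs(sum(geom1$normal * geom2$normal)))) * 180 / pi
  phi <- acos(min(1, abs(sum(geom1$normal * rhat)))) * 180 / pi
  list(centroid_a = geom1$centroid, centroid_b = geom2$centroid,
       normal_a = geom1$normal, normal_b = geom2$normal,
       R = R, theta = theta, phi = phi)
}

.ring_plane <- function(xyz) {
  if (nrow(xyz) < 3) stop("a ring needs at least 3 atoms")
  ctr <- colMeans(xyz)
  cen <- sweep(xyz, 2, ctr)
  sv <- svd(cen)
  if (sv$d[2] < 1e-9) stop("degenerate ring geometry: atoms are collinear")
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Classify an aromatic ring pair as parallel, T-stacked, or neither
#'
#' Parallel: R < 6.5 A, theta < 60 deg, phi < 45 deg. T-stacked: R < 7.5 A,
#' theta > 75 deg, phi < 45 deg. The theta conditions make the two classes
#' mutually exclusive.
#'
#' @param geom result of [ring_geometry()].
#' @param cutoffs cutoff list, see [interaction_cutoffs()].
#' @return one of "parallel", "t_stack", "none".
#' @export
classify_stacking <- function(geom, cutoffs = interaction_cutoffs()) {
  if (geom$R < cutoffs$parallel_r && geom$theta < cutoffs$parallel_theta &&
      geom$phi < cutoffs$parallel_phi) return("parallel")
  if (geom$R < cutoffs$tstack_r && geom$theta > cutoffs$tstack_theta &&
      geom$phi < cutoffs$tstack_phi) return("t_stack")
  "none"
}

#' Per-residue interaction population profile
#'
#' For each protein residue, the weighted fraction of frames in which the
#' residue forms each interaction class with the reference group (default:
#' the ligand): any heavy-atom contact, hydrophobic contact, hydrogen bond
#' (either direction), and parallel / T aromatic stacking between the
#' residue's ring groups and the reference ring groups.
#'
#' @param ens an `Ensemble`.
#' @param frames frame subset (default all).
#' @param reference_atoms reference atom ids (default: ligand atoms).
#' @param cutoffs cutoff list.
#' @return object of class `InteractionProfile`: data.frame (residue,
#'   res_number, contact, hydrophobic, hbond, parallel, t_stack) with the
#'   frame count in attribute `n_frames`.
#' @export
interaction_profile <- function(ens, frames = NULL, reference_atoms = NULL,
                                cutoffs = interaction_cutoffs()) {
  a <- ens$topology$atoms
  if (is.null(reference_atoms)) {
    reference_atoms <- a$id[a$ligand]
    if (!length(reference_atoms)) stop("no ligand atoms; give reference_atoms")
  }
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  if (!length(frames)) stop("empty frame subset")
  w <- ens$weights[frames]; w <- w / sum(w)
  ref_heavy <- reference_atoms[a$heavy[reference_atoms]]
  ref_c <- reference_atoms[toupper(a$element[reference_atoms]) %in% c("C", "CL")]
  ref_don <- reference_atoms[a$donor[reference_atoms]]
  ref_acc <- reference_atoms[a$acceptor[reference_atoms]]
  ref_rings <- Filter(function(g) all(g %in% reference_atoms),
                      ens$topology$ring_groups)
  res_ids <- sort(unique(a$res_index[!a$ligand & !(a$id %in% reference_atoms)]))
  prof <- matrix(0, length(res_ids), 5,
                 dimnames = list(NULL, c("contact", "hydrophobic", "hbond",
                                         "parallel", "t_stack")))
  res_rings <- lapply(res_ids, function(r) {
    ids <- a$id[a$res_index == r]
    Filter(function(g) all(g %in% ids), ens$topology$ring_groups)
  })
  for (k in seq_along(frames)) {
    f <- frames[k]
    xyz <- get_frame(ens, f)
    hb <- hydrogen_bonds(ens, f,
                         dist_cutoff = cutoffs$hbond_dist,
                         angle_cutoff = cutoffs$hbond_angle)
    for (ri in seq_along(res_ids)) {
      r <- res_ids[ri]
      res_heavy <- a$id[a$res_index == r & a$heavy]
      dmin <- min(.cross_dist(xyz[res_heavy, , drop = FALSE],
                              xyz[ref_heavy, , drop = FALSE]))
      if (dmin <= cutoffs$contact) prof[ri, "contact"] <- prof[ri, "contact"] + w[k]
      pc <- a$id[a$res_index == r & toupper(a$element) == "C"]
      if (length(pc) && length(ref_c) &&
          min(.cross_dist(xyz[pc, , drop = FALSE],
                          xyz[ref_c, , drop = FALSE])) <= cutoffs$hydrophobic)
        prof[ri, "hydrophobic"] <- prof[ri, "hydrophobic"] + w[k]
      res_atoms <- a$id[a$res_index == r]
      has_hb <- nrow(hb) > 0 &&
        any((hb$donor %in% res_atoms & hb$acceptor %in% ref_acc) |
            (hb$donor %in% ref_don & hb$acceptor %in% res_atoms))
      if (has_hb) prof[ri, "hbond"] <- prof[ri, "hbond"] + w[k]
      if (length(res_rings[[ri]]) && length(ref_rings)) {
        cls <- "none"
        for (g1 in res_rings[[ri]]) for (g2 in ref_rings) {
          cl <- classify_stacking(ring_geometry(ens, f, g1, g2), cutoffs)
          if (cl == "parallel") cls <- "parallel"
          if (cl == "t_stack" && cls != "parallel") cls <- "t_stack"
        }
        if (cls == "parallel") prof[ri, "parallel"] <- prof[ri, "parallel"] + w[k]
        if (cls == "t_stack") prof[ri, "t_stack"] <- prof[ri, "t_stack"] + w[k]
      }
    }
  }
  out <- data.frame(residue = res_ids,
                    res_number = a$res_number[match(res_ids, a$res_index)],
                    prof)
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("InteractionProfile", "data.frame")
  out
}

#' Coefficient of determination between two interaction profiles
#'
#' Squared Pearson correlation between the per-residue population vectors
#' of one interaction class in two profiles. Scale-free by construction (a
#' documented consequence of the Pearson choice).
#'
#' @param profile_a,profile_b `InteractionProfile` objects on the same
#'   residue support.
#' @param class interaction class column name (e.g. "contact").
#' @return squared Pearson r; NaN with a warning if either vector has zero
#'   variance.
#' @export
profile_r2 <- function(profile_a, profile_b, class = "contact") {
  x <- profile_a[[class]]; y <- profile_b[[class]]
  if (length(x) != length(y)) stop("profiles have different residue support")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance profile: r^2 undefined")
    return(NaN)
  }
  cor(x, y)^2
}
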