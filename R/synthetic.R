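# Synthetic conformational-ensemble generator. Emulates the statistical
# structure of enhanced-sampling ensembles of a 56-residue disordered
# androgen-receptor fragment: region-specific helical propensity, tunable
# compaction via a harmonic Rg restraint, an attached pseudo-ligand, and
# per-frame pseudo-observables linearly coupled to local helicity.
# Frames are an i.i.d.-style sample, not a time series.

# Soft-sphere hard core between non-bonded heavy atoms (Angstrom).
.CLASH_FLOOR_ANG <- 2.5

#' Configuration for the synthetic-ensemble generator
#'
#' @param n_residues chain length (default 56, the size of the disordered
#'   androgen-receptor fragment the toolkit targets).
#' @param helix_propensity per-residue probability of the helical state;
#'   scalar or length-`n_residues` vector, values in [0, 1].
#' @param helix_cooperativity state-copy probability in [0, 1): with this
#'   probability residue i copies residue i-1's state, otherwise it draws
#'   an independent Bernoulli(propensity). Higher values give longer
#'   helical segments at the same mean helicity.
#' @param rg_target target radius of gyration in nm, or NULL for no
#'   compaction bias.
#' @param rg_force_constant harmonic restraint strength in kT/nm^2 (kT = 1).
#' @param n_frames number of frames.
#' @param mc_sweeps_per_frame pivot Monte-Carlo sweeps per frame used to
#'   relax the chain under the Rg restraint.
#' @param seed integer seed fixing all randomness.
#' @param first_resid author-facing number of the first residue.
#' @param observable_model list with `baseline` (per-residue coil value,
#'   scalar or vector), `delta` (helix offset) and `sigma` (additive
#'   Gaussian noise sd) for [synth_observables()]. Defaults emulate
#'   C-alpha chemical shifts: coil baseline 58 ppm, helix offset +2.5 ppm,
#'   noise 0.3 ppm.
#' @return a `GeneratorConfig` list.
#' @export
generator_config <- function(n_residues = 56, helix_propensity = 0.2,
                             helix_cooperativity = 0.9, rg_target = NULL,
                             rg_force_constant = 0, n_frames = 100,
                             mc_sweeps_per_frame = 10, seed = 1,
                             first_resid = 1,
                             observable_model = list(baseline = 58,
                                                     delta = 2.5,
                                                     sigma = 0.3)) {
  if (n_residues < 7) stop("n_residues must be >= 7")
  if (n_frames < 1) stop("n_frames must be >= 1")
  p <- rep_len(helix_propensity, n_residues)
  if (any(p < 0 | p > 1)) stop("helix_propensity must lie in [0, 1]")
  if (helix_cooperativity < 0 || helix_cooperativity >= 1)
    stop("helix_cooperativity must lie in [0, 1)")
  if (!is.null(rg_target) && rg_target <= 0) stop("rg_target must be positive")
  structure(list(n_residues = n_residues, helix_propensity = p,
                 helix_cooperativity = helix_cooperativity,
                 rg_target = rg_target, rg_force_constant = rg_force_constant,
                 n_frames = n_frames, mc_sweeps_per_frame = mc_sweeps_per_frame,
                 seed = as.integer(seed), first_resid = first_resid,
                 observable_model = observable_model),
            class = "GeneratorConfig")
}

.draw_states <- function(p, coop) {
  n <- length(p)
  s <- integer(n)
  s[1] <- as.integer(runif(1) < p[1])
  for (i in seq_len(n)[-1])
    s[i] <- if (runif(1) < coop) s[i - 1] else as.integer(runif(1) < p[i])
  s
}

.draw_dihedrals <- function(states) {
  n <- length(states)
  phi <- numeric(n); psi <- numeric(n)
  for (i in seq_len(n)) {
    if (states[i] == 1) {
      phi[i] <- -57 + 5 * rnorm(1)
      psi[i] <- -47 + 5 * rnorm(1)
    } else {
      phi[i] <- runif(1, -180, -30)
      psi[i] <- if (runif(1) < 120 / 150) runif(1, 60, 180)
                else runif(1, -180, -150)
    }
  }
  list(phi = phi, psi = psi)
}

#' Sample a synthetic conformational ensemble
#'
#' Per frame: per-residue helix/coil states from a two-state Markov chain
#' (propensity + cooperativity); helical residues get phi,psi near
#' (-57, -47) with 5 deg Gaussian noise, coil residues sample a broad
#' non-helical basin; the chain is built with ideal covalent geometry and
#' relaxed by pivot Monte-Carlo under a hard steric core plus, when
#' requested, a harmonic Rg restraint (Metropolis, kT = 1). Identical
#' config (including seed) gives identical output.
#'
#' @param config a `GeneratorConfig`.
#' @return list with `ensemble` (an `Ensemble`) and `truth` (a
#'   `SyntheticTruth` list: per-frame helical state matrix, per-frame Rg in
#'   nm, ligand atom ids once attached, ground-truth weights once set).
#' @export
sample_ensemble <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  n <- config$n_residues
  nf <- config$n_frames
  top <- backbone_topology(n, config$first_resid)
  coords <- array(0, dim = c(nf, 5 * n, 3))
  states <- matrix(0L, nf, n)
  rg <- numeric(nf)
  k <- config$rg_force_constant
  tgt <- if (is.null(config$rg_target)) -1 else config$rg_target
  sweeps <- if (is.null(config$rg_target) || k <= 0) 0L
            else config$mc_sweeps_per_frame
  for (f in seq_len(nf)) {
    st <- .draw_states(config$helix_propensity, config$helix_cooperativity)
    dh <- .draw_dihedrals(st)
    res <- .cpp_mc_frame(dh$phi, dh$psi, st, tgt, if (tgt > 0) k else 0,
                         .CLASH_FLOOR_ANG, sweeps, 5000L)
    if (!res$resolved)
      stop("could not resolve steric clashes for frame ", f,
           " within the attempt budget")
    coords[f, , ] <- res$coords * .ANG2NM
    states[f, ] <- st
    rg[f] <- res$rg * .ANG2NM
  }
  if (!is.null(config$rg_target) && k > 0) {
    gap <- mean(rg) - config$rg_target
    if (gap > 0.3)
      warning("rg_target ", config$rg_target,
              " nm appears unreachable above the excluded-volume floor; ",
              "achieved mean Rg ", round(mean(rg), 3), " nm")
  }
  ens <- ensemble(top, coords,
                  provenance = sprintf("synthetic(seed=%d)", config$seed))
  truth <- structure(list(states = states, rg = rg, config = config,
                          ligand_atoms = integer(0), truth_weights = NULL,
                          true_means = NULL),
                     class = "SyntheticTruth")
  list(ensemble = ens, truth = truth)
}

# Pseudo-ligand internal geometry: a two-carbon linker off the site CA
# carrying a carbonyl acceptor and a hydroxyl, then a chlorinated aromatic
# six-ring with a second (phenolic) hydroxyl. 14 atoms.
.LIGAND_ATOMS <- data.frame(
  atom_name = c("L1", "O3", "L2", "O1", "H1", "C1", "C2", "C3", "C4", "C5",
                "C6", "CL1", "O2", "H2"),
  element = c("C", "O", "C", "O", "H", "C", "C", "C", "C", "C", "C", "CL",
              "O", "H"),
  stringsAsFactors = FALSE)

.build_ligand_coords <- function(Np, CAp, Cp, chi) {
  # chi: linker/ring/hydroxyl torsions (degrees), length 5
  P <- function(A, B, C, bond, ang, dih) .cpp_nerf_place(A, B, C, bond, ang, dih)
  L1 <- P(Cp, Np, CAp, 1.54, 110, chi[1])
  L2 <- P(Np, CAp, L1, 1.52, 111, chi[2])
  O3 <- P(Np, CAp, L1, 1.23, 120, chi[2] + 120)
  O1 <- P(CAp, L1, L2, 1.43, 109, chi[3])
  H1 <- P(L1, L2, O1, 0.96, 108, chi[4])
  C1 <- P(CAp, L1, L2, 1.51, 111, chi[3] + 120)
  C2 <- P(L1, L2, C1, 1.40, 120, chi[5])
  C3 <- P(L2, C1, C2, 1.40, 120, 180)
  C4 <- P(C1, C2, C3, 1.40, 120, 0)
  C5 <- P(C2, C3, C4, 1.40, 120, 0)
  C6 <- P(C3, C4, C5, 1.40, 120, 0)
  CL1 <- P(C2, C3, C4, 1.74, 120, 180)
  O2 <- P(C3, C4, C5, 1.36, 120, 180)
  H2 <- P(C4, C5, O2, 0.96, 109, 0)
  rbind(L1, O3, L2, O1, H1, C1, C2, C3, C4, C5, C6, CL1, O2, H2)
}

#' Attach a pseudo-ligand to a synthetic ensemble
#'
#' Appends a small-molecule moiety (six-carbon aromatic ring, one chlorine,
#' two hydroxyl donors, one carbonyl acceptor) tethered to the given
#' residue's C-alpha through sampled linker dihedrals, emulating a covalent
#' small-molecule adduct side chain. The topology gains the ring group,
#' donor/acceptor and hydrophobic flags. Placement resamples torsions until
#' the ligand is clash-free against the protein (bounded attempts).
#'
#' @param ens an `Ensemble` from [sample_ensemble()].
#' @param site internal residue index of the attachment site.
#' @param seed integer seed for torsion sampling.
#' @param truth optional `SyntheticTruth` to update with ligand atom ids.
#' @return the decorated `Ensemble`, or (when `truth` is given) a list with
#'   `ensemble` and `truth`.
#' @export
attach_pseudo_ligand <- function(ens, site, seed = 1, truth = NULL) {
  prot <- ens$topology$atoms
  if (any(prot$ligand)) stop("ensemble already carries a ligand")
  n_res <- max(prot$res_index)
  if (site < 1 || site > n_res) stop("ligand site ", site, " out of range 1..", n_res)
  set.seed(as.integer(seed))
  nf <- n_frames(ens)
  na_p <- nrow(prot)
  nlig <- nrow(.LIGAND_ATOMS)
  idN <- prot$id[prot$res_index == site & prot$atom_name == "N"]
  idCA <- prot$id[prot$res_index == site & prot$atom_name == "CA"]
  idC <- prot$id[prot$res_index == site & prot$atom_name == "C"]
  heavy_prot <- prot$id[prot$heavy & abs(prot$res_index - site) > 1]
  coords <- array(0, dim = c(nf, na_p + nlig, 3))
  coords[, seq_len(na_p), ] <- ens$coords
  lig_heavy <- which(.LIGAND_ATOMS$element != "H")
  for (f in seq_len(nf)) {
    xyz <- get_frame(ens, f) / .ANG2NM
    best <- NULL; best_min <- -Inf
    for (try in 1:200) {
      chi <- runif(5, -180, 180)
      lig <- .build_ligand_coords(xyz[idN, ], xyz[idCA, ], xyz[idC, ], chi)
      d <- sqrt(outer(rowSums(lig[lig_heavy, ]^2), rowSums(xyz[heavy_prot, ]^2), "+") -
                  2 * lig[lig_heavy, ] %*% t(xyz[heavy_prot, , drop = FALSE]))
      mind <- min(d)
      if (mind > best_min) { best <- lig; best_min <- mind }
      if (mind >= .CLASH_FLOOR_ANG) break
    }
    coords[f, na_p + seq_len(nlig), ] <- best * .ANG2NM
  }
  lig_atoms <- data.frame(
    id = na_p + seq_len(nlig),
    res_index = n_res + 1, res_number = max(prot$res_number) + 1,
    res_name = "LIG", atom_name = .LIGAND_ATOMS$atom_name,
    element = .LIGAND_ATOMS$element, stringsAsFactors = FALSE)
  lig_atoms$heavy <- lig_atoms$element != "H"
  lig_atoms$donor <- lig_atoms$atom_name %in% c("O1", "O2")
  lig_atoms$acceptor <- lig_atoms$element %in% c("N", "O")
  lig_atoms$hydrophobic <- lig_atoms$element %in% c("C", "CL")
  lig_atoms$ligand <- TRUE
  ah <- ens$topology$attached_h
  ah[[as.character(na_p + which(.LIGAND_ATOMS$atom_name == "O1"))]] <-
    na_p + which(.LIGAND_ATOMS$atom_name == "H1")
  ah[[as.character(na_p + which(.LIGAND_ATOMS$atom_name == "O2"))]] <-
    na_p + which(.LIGAND_ATOMS$atom_name == "H2")
  rings <- ens$topology$ring_groups
  rings[["ligand_ring"]] <- na_p + which(.LIGAND_ATOMS$atom_name %in%
                                           paste0("C", 1:6))
  top <- topology(rbind(prot, lig_atoms), attached_h = ah, ring_groups = rings)
  out <- ensemble(top, coords, weights = ens$weights,
                  provenance = paste0(ens$provenance, "+ligand@", site))
  if (is.null(truth)) return(out)
  truth$ligand_atoms <- lig_atoms$id
  list(ensemble = out, truth = truth)
}

#' Generate per-frame pseudo-observables coupled to local helicity
#'
#' Per frame and residue: observable = baseline + delta * helical_state +
#' Gaussian noise. "Experimental" targets are the weighted means of the
#' noiseless observables under a ground-truth weight vector, which is
#' recorded in the returned truth for recovery tests.
#'
#' @param ens the `Ensemble` the truth belongs to (frame count check).
#' @param truth a `SyntheticTruth` from [sample_ensemble()].
#' @param seed integer seed for the observation noise.
#' @param truth_weights optional ground-truth weight vector (default
#'   uniform); normalized internally.
#' @return list with `observables` (an `ObservableTable`) and the updated
#'   `truth` (gains `truth_weights` and `true_means`).
#' @export
synth_observables <- function(ens, truth, seed = 1, truth_weights = NULL) {
  om <- truth$config$observable_model
  if (is.null(om)) stop("generator config has no observable_model")
  st <- truth$states
  nf <- nrow(st); n <- ncol(st)
  if (nf != n_frames(ens)) stop("truth and ensemble frame counts differ")
  baseline <- rep_len(om$baseline, n)
  clean <- sweep(st * om$delta, 2, baseline, "+")
  set.seed(as.integer(seed))
  vals <- clean + matrix(rnorm(nf * n, sd = om$sigma), nf, n)
  if (is.null(truth_weights)) truth_weights <- rep(1 / nf, nf)
  truth_weights <- truth_weights / sum(truth_weights)
  targets <- as.numeric(crossprod(clean, truth_weights))
  sig <- rep(max(om$sigma, 1e-6), n)
  labels <- paste0("CA_", ens$topology$atoms$res_number[
    match(seq_len(n), ens$topology$atoms$res_index)])
  obs <- observable_table(vals, targets, sig, labels)
  truth$truth_weights <- truth_weights
  truth$true_means <- setNames(targets, labels)
  list(observables = obs, truth = truth)
}
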