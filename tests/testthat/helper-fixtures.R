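# Shared fixtures (memoized: built once per test run) and independent
# brute-force oracles kept deliberately naive and separate from the
# package's own implementations.

.fx <- new.env()

fx_memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small compact adduct ensemble with observables: 6 frames, ligand at 14.
fx_adduct <- function() fx_memo("adduct", function() {
  cfg <- generator_config(n_frames = 6, seed = 7, rg_target = 1.2,
                          rg_force_constant = 300, mc_sweeps_per_frame = 10)
  out <- sample_ensemble(cfg)
  lg <- attach_pseudo_ligand(out$ensemble, 14, seed = 2, truth = out$truth)
  so <- synth_observables(lg$ensemble, lg$truth, seed = 4)
  list(ens = lg$ensemble, truth = so$truth, obs = so$observables)
})

# Mixed coil ensemble (some helix) used for descriptor oracles.
fx_coil <- function() fx_memo("coil", function() {
  sample_ensemble(generator_config(n_frames = 10, seed = 3))
})

# Noiseless reweighting recovery fixture: Gibbs-form planted truth weights
# expressed through the first 28 residues' observables.
fx_reweight <- function() fx_memo("reweight", function() {
  cfg <- generator_config(n_frames = 200, seed = 9,
                          observable_model = list(baseline = 58, delta = 2.5,
                                                  sigma = 0))
  out <- sample_ensemble(cfg)
  set.seed(33)
  a <- rnorm(28, sd = 1.0)
  w <- as.numeric(exp(out$truth$states[, 1:28] %*% a))
  w <- w / sum(w)
  so <- synth_observables(out$ensemble, out$truth, seed = 5,
                          truth_weights = w)
  list(obs = so$observables, wtruth = w,
       restr = paste0("CA_", 1:28), held = paste0("CA_", 29:56))
})

# Independent Kabsch superposition oracle (plain R, svd).
oracle_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

# Independent Salpha oracle: explicit window loop over the ideal template.
oracle_salpha <- function(ca_ang, tmpl_ang, r0 = 1.0) {
  n <- nrow(ca_ang)
  total <- 0
  for (i in 1:(n - 6)) {
    r <- oracle_rmsd(ca_ang[i:(i + 6), , drop = FALSE], tmpl_ang)
    x <- r / r0
    total <- total + if (abs(x - 1) < 1e-9) 2 / 3 else (1 - x^8) / (1 - x^12)
  }
  total
}

# All-pairs brute-force interaction oracles operating directly on topology
# flags and nested distance loops.
oracle_min_dist <- function(xyz, ids_a, ids_b) {
  best <- Inf
  for (i in ids_a) for (j in ids_b) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < best) best <- d
  }
  best
}

oracle_hbonds <- function(ens, frame, dist_cutoff = 0.35, angle_cutoff = 150) {
  a <- ens$topology$atoms
  xyz <- get_frame(ens, frame)
  out <- list()
  for (d in a$id[a$donor]) for (h in ens$topology$attached_h[[as.character(d)]])
    for (ac in a$id[a$acceptor]) {
      if (a$res_index[ac] == a$res_index[d]) next
      if (sqrt(sum((xyz[h, ] - xyz[ac, ])^2)) > dist_cutoff) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[ac, ] - xyz[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang > angle_cutoff)
        out[[length(out) + 1]] <- c(d, h, ac)
    }
  if (!length(out)) return(matrix(integer(0), 0, 3))
  do.call(rbind, out)
}

# Minimal hand-built ensemble from explicit coordinates (nm) and a bare
# atom table; used for boundary-condition tests.
make_toy_ens <- function(coords, elements, res_index,
                         donor = rep(FALSE, length(elements)),
                         acceptor = rep(FALSE, length(elements)),
                         ligand = rep(FALSE, length(elements)),
                         attached_h = list(), ring_groups = list()) {
  n <- length(elements)
  atoms <- data.frame(
    id = seq_len(n), res_index = res_index, res_number = res_index,
    res_name = ifelse(ligand, "LIG", "RES"),
    atom_name = paste0(elements, seq_len(n)), element = elements,
    heavy = elements != "H", donor = donor, acceptor = acceptor,
    hydrophobic = elements %in% c("C", "CL") , ligand = ligand,
    stringsAsFactors = FALSE)
  top <- topology(atoms, attached_h = attached_h, ring_groups = ring_groups)
  arr <- array(0, dim = c(1, n, 3))
  arr[1, , ] <- coords
  ensemble(top, arr)
}

# Random rigid transform applied to an (m x 3) coordinate block.
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, rnorm(3), "+")
}

# Regular hexagon (ring) in a given plane, radius in nm.
hexagon <- function(center = c(0, 0, 0), radius = 0.14, normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal; u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  t(vapply(ang, function(a) center + radius * (cos(a) * u + sin(a) * v),
           numeric(3)))
}
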