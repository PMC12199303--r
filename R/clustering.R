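# Conformational clustering: all-to-all C-alpha RMSD, perplexity-calibrated
# Gaussian conditionals, exact t-SNE by KL gradient descent, k-means
# partitioning of the embedding, and dual-space silhouette model selection.

#' All-to-all C-alpha RMSD distance matrix
#'
#' Pairwise minimal RMSD (Kabsch superposition, proper rotations) between
#' all frames of one or several ensembles over a shared atom selection
#' (default backbone C-alpha). Merged ensembles must share the selection's
#' atom count; a covalent-adduct vs apo merge is the caller's job to
#' restrict to shared backbone atoms.
#'
#' @param ensembles an `Ensemble` or a (optionally named) list of them.
#' @param atom_names atom-name selection (default "CA").
#' @return object of class `DistanceMatrix`: the n x n RMSD matrix (nm)
#'   with a `labels` attribute (data.frame source, frame).
#' @export
rmsd_matrix <- function(ensembles, atom_names = "CA") {
  if (inherits(ensembles, "Ensemble")) ensembles <- list(merged = ensembles)
  if (is.null(names(ensembles)))
    names(ensembles) <- paste0("ens", seq_along(ensembles))
  sel <- lapply(ensembles, select_atoms, atom_names = atom_names,
                ligand = FALSE)
  m <- length(sel[[1]])
  if (!all(vapply(sel, length, integer(1)) == m))
    stop("ensembles have mismatched atom counts over the selection")
  rows <- list(); labels <- list()
  for (k in seq_along(ensembles)) {
    ens <- ensembles[[k]]
    nf <- n_frames(ens)
    block <- matrix(0, nf, 3 * m)
    for (f in seq_len(nf))
      block[f, ] <- t(get_frame(ens, f)[sel[[k]], , drop = FALSE])
    rows[[k]] <- block
    labels[[k]] <- data.frame(source = names(ensembles)[k], frame = seq_len(nf))
  }
  D <- .cpp_rmsd_matrix(do.call(rbind, rows))
  structure(D, labels = do.call(rbind, labels), class = "DistanceMatrix")
}

#' Downsample an ensemble to a target frame count
#'
#' @param ens an `Ensemble`.
#' @param target number of frames to keep (default 5000).
#' @param mode "stride" (evenly strided, deterministic) or "random"
#'   (seeded uniform without replacement).
#' @param seed seed for random mode.
#' @return list with `ensemble` (the subset) and `frames` (kept indices).
#' @export
downsample <- function(ens, target = 5000, mode = c("stride", "random"),
                       seed = 1) {
  mode <- match.arg(mode)
  nf <- n_frames(ens)
  if (target > nf) stop("target exceeds frame count")
  keep <- if (mode == "stride") unique(round(seq(1, nf, length.out = target)))
  else { set.seed(as.integer(seed)); sort(sample.int(nf, target)) }
  sub <- ensemble(ens$topology,
                  ens$coords[keep, , , drop = FALSE],
                  weights = ens$weights[keep],
                  provenance = paste0(ens$provenance, " [downsampled]"))
  list(ensemble = sub, frames = keep)
}

.row_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Calibrate per-point Gaussian conditionals to a target perplexity
#'
#' For each point, the Gaussian bandwidth sigma_i is found by bisection so
#' that the conditional distribution p(j|i) over all other points has
#' Shannon entropy log2(perplexity) bits (within `tol`). The symmetrized
#' joint is p_ij = (p(j|i) + p(i|j)) / (2n).
#'
#' @param distances a `DistanceMatrix` (or plain symmetric matrix).
#' @param perplexity target perplexity, 1 < perplexity < n.
#' @param tol entropy matching tolerance in bits (default 1e-5).
#' @return list (class `ConditionalModel`): `P_cond` (rows sum to 1),
#'   `P_joint` (sums to 1, symmetric), `sigma`, `perplexity`, `entropy`.
#' @export
calibrate_conditionals <- function(distances, perplexity, tol = 1e-5) {
  D <- unclass(distances)
  n <- nrow(D)
  if (perplexity <= 1 || perplexity >= n)
    stop("perplexity must satisfy 1 < perplexity < n")
  target <- log2(perplexity)
  P <- matrix(0, n, n)
  sigma <- numeric(n); ent <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D[i, -i]^2
    beta <- 1 # = 1 / (2 sigma^2)
    lo <- -Inf; hi <- Inf
    p <- NULL
    for (iter in 1:100) {
      e <- exp(-beta * (d2 - min(d2)))
      p <- e / sum(e)
      H <- .row_entropy_bits(p)
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
    sigma[i] <- 1 / sqrt(2 * beta)
    ent[i] <- H
  }
  PJ <- (P + t(P)) / (2 * n)
  structure(list(P_cond = P, P_joint = PJ, sigma = sigma,
                 perplexity = perplexity, entropy = ent),
            class = "ConditionalModel")
}

#' t-SNE embedding by KL-divergence gradient descent
#'
#' Exact (O(n^2)) t-SNE: a 2-D embedding initialized from a seeded
#' small-variance Gaussian is optimized by gradient descent with momentum
#' and early exaggeration to minimize the KL divergence between the
#' calibrated joint P and the Student-t joint Q of the embedding.
#'
#' @param model a `ConditionalModel`.
#' @param seed integer seed for the initialization.
#' @param n_iter gradient-descent iterations (default 1000).
#' @param eta learning rate (default 200).
#' @param momentum initial and final momentum, switching at
#'   `momentum_switch` (defaults 0.5, 0.8, 250).
#' @param momentum_switch iteration at which momentum switches.
#' @param exaggeration early-exaggeration factor (default 12) applied for
#'   the first `exaggeration_iter` iterations (default 250).
#' @param exaggeration_iter length of the early-exaggeration phase.
#' @param trace_every record the (unexaggerated) KL every this many
#'   iterations (default 50).
#' @return list (class `Embedding`): `Y` (n x 2), `kl` (final divergence),
#'   `trace` (data.frame iteration, kl), `seed`.
#' @export
tsne_embed <- function(model, seed = 1, n_iter = 1000, eta = 200,
                       momentum = c(0.5, 0.8), momentum_switch = 250,
                       exaggeration = 12, exaggeration_iter = 250,
                       trace_every = 50) {
  P <- model$P_joint
  n <- nrow(P)
  set.seed(as.integer(seed))
  Y <- matrix(rnorm(2 * n, sd = 1e-4), n, 2)
  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eps <- 1e-12
  kl_of <- function(Y) {
    W <- 1 / (1 + as.matrix(dist(Y))^2); diag(W) <- 0
    Q <- W / sum(W)
    sum(P[P > 0] * log(P[P > 0] / pmax(Q[P > 0], eps)))
  }
  trace <- list()
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exaggeration_iter) exaggeration * P else P
    W <- 1 / (1 + as.matrix(dist(Y))^2); diag(W) <- 0
    Q <- W / sum(W)
    M <- (Pe - Q) * W
    G <- 4 * (diag(rowSums(M)) %*% Y - M %*% Y)
    if (any(!is.finite(G))) stop("t-SNE diverged: non-finite gradient at iteration ", it)
    mom <- if (it < momentum_switch) momentum[1] else momentum[2]
    # per-parameter gain adaptation (standard t-SNE optimizer)
    gains <- ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    V <- mom * V - eta * gains * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))  # keep centered
    if (it %% trace_every == 0 || it == n_iter)
      trace[[length(trace) + 1]] <- data.frame(iteration = it, kl = kl_of(Y))
  }
  trace <- do.call(rbind, trace)
  structure(list(Y = Y, kl = trace$kl[nrow(trace)], trace = trace,
                 seed = seed), class = "Embedding")
}

#' k-means partition of a t-SNE embedding
#'
#' Lloyd iterations from a deterministic greedy farthest-point
#' initialization, best inertia over seeded restarts. Operates on
#' embedding coordinates only (squared-Euclidean inertia), never on the
#' RMSD matrix directly.
#'
#' @param embedding an `Embedding` (or plain n x 2 matrix).
#' @param N number of clusters (2 <= N <= n).
#' @param seed integer seed.
#' @param restarts number of seeded restarts (default 10).
#' @return integer vector of cluster labels in 1..N.
#' @export
kmeans_partition <- function(embedding, N, seed = 1, restarts = 10) {
  Y <- if (inherits(embedding, "Embedding")) embedding$Y else as.matrix(embedding)
  n <- nrow(Y)
  if (N < 2) stop("N must be >= 2")
  if (N > nrow(unique(Y))) stop("N exceeds the number of distinct points")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(as.integer(seed) + r - 1)
    centers <- matrix(0, N, 2)
    centers[1, ] <- Y[sample.int(n, 1), ]
    d2 <- colSums((t(Y) - centers[1, ])^2)
    for (k in seq_len(N)[-1]) {
      centers[k, ] <- Y[which.max(d2), ]
      d2 <- pmin(d2, colSums((t(Y) - centers[k, ])^2))
    }
    km <- suppressWarnings(kmeans(Y, centers = centers, iter.max = 100,
                                  algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

#' Silhouette scores from a distance matrix
#'
#' s_i = (b_i - a_i) / max(a_i, b_i), where a_i is the mean distance to the
#' other members of i's cluster and b_i the smallest mean distance to any
#' other cluster; singleton clusters score 0.
#'
#' @param labels integer cluster labels.
#' @param distances symmetric distance matrix (e.g. embedding Euclidean or
#'   the original RMSD metric).
#' @return list with `per_point` and `mean`.
#' @export
silhouette_score <- function(labels, distances) {
  D <- unclass(distances)
  n <- length(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("silhouette undefined for a single cluster")
  idx <- lapply(cl, function(c) which(labels == c))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- idx[[match(labels[i], cl)]]
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (length(own) - 1)
    b <- min(vapply(idx[cl != labels[i]],
                    function(o) mean(D[i, o]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  list(per_point = s, mean = mean(s))
}

#' Integrated silhouette score
#'
#' Mean silhouette in the 2-D embedding (Euclidean distance, S_ld) and
#' under the original high-dimensional RMSD metric (S_hd), combined as
#' S_i = S_ld x S_hd. A low S_hd flags clusters that look clean only in
#' the embedding. If both means are negative their product is positive; a
#' warning is raised for this documented pitfall.
#'
#' @param labels integer cluster labels.
#' @param embedding an `Embedding` (or n x 2 matrix).
#' @param distances the original `DistanceMatrix`.
#' @return list with `S_ld`, `S_hd`, `S_i`.
#' @export
integrated_silhouette <- function(labels, embedding, distances) {
  Y <- if (inherits(embedding, "Embedding")) embedding$Y else as.matrix(embedding)
  s_ld <- silhouette_score(labels, as.matrix(dist(Y)))$mean
  s_hd <- silhouette_score(labels, distances)$mean
  if (s_ld < 0 && s_hd < 0)
    warning("both silhouettes negative: S_i is positive but clustering quality is poor")
  list(S_ld = s_ld, S_hd = s_hd, S_i = s_ld * s_hd)
}

#' Hyperparameter scan over perplexity and cluster count
#'
#' For each perplexity: calibrate conditionals and embed once; for each N:
#' k-means partition and integrated silhouette. Returns the full score
#' table plus the best model (argmax S_i) under the N constraint.
#'
#' @param distances a `DistanceMatrix`.
#' @param perplexities numeric grid of perplexity values.
#' @param n_values integer grid of cluster counts (e.g. 4, or 10:20).
#' @param seed integer seed (embedding/partition seeds derive from it).
#' @param ... further arguments to [tsne_embed()] (e.g. n_iter).
#' @return list (class `ClusterScan`): `table` (perplexity, N, S_ld, S_hd,
#'   S_i), `best` (list: labels, embedding, perplexity, N, S_ld, S_hd,
#'   S_i), `labels` attribute carried over from the distance matrix.
#' @export
hyperparameter_scan <- function(distances, perplexities, n_values, seed = 1,
                                ...) {
  if (!length(perplexities) || !length(n_values)) stop("empty hyperparameter grid")
  rows <- list(); best <- NULL
  for (pi in seq_along(perplexities)) {
    perp <- perplexities[pi]
    model <- calibrate_conditionals(distances, perp)
    emb <- tsne_embed(model, seed = seed + 1000L * pi, ...)
    for (N in n_values) {
      labels <- kmeans_partition(emb, N, seed = seed + 17L * N)
      sil <- integrated_silhouette(labels, emb, distances)
      rows[[length(rows) + 1]] <- data.frame(perplexity = perp, N = N,
                                             S_ld = sil$S_ld, S_hd = sil$S_hd,
                                             S_i = sil$S_i)
      if (is.null(best) || sil$S_i > best$S_i)
        best <- list(labels = labels, embedding = emb, perplexity = perp,
                     N = N, S_ld = sil$S_ld, S_hd = sil$S_hd, S_i = sil$S_i)
    }
  }
  structure(list(table = do.call(rbind, rows), best = best,
                 frame_labels = attr(distances, "labels")),
            class = "ClusterScan")
}

#' Per-cluster, per-source summary report
#'
#' For each cluster of a merged ensemble, and for the merged set plus each
#' source ensemble separately: cluster population p, bound fraction BF
#' (when a ligand is present), helical-globule population p_Glob and mean
#' helix fraction HF. A cluster absent from a source yields a row of NAs
#' (the report's explicit absence marker).
#'
#' @param ensembles named list of source `Ensemble`s (as merged for the
#'   distance matrix).
#' @param labels integer cluster labels over the merged frames.
#' @param frame_labels data.frame (source, frame) aligning merged rows to
#'   sources, as produced by [rmsd_matrix()].
#' @return data.frame with columns cluster, source, p, BF, p_Glob, HF and
#'   standard errors.
#' @export
cluster_report <- function(ensembles, labels, frame_labels) {
  if (inherits(ensembles, "Ensemble")) ensembles <- list(merged = ensembles)
  if (length(labels) != nrow(frame_labels))
    stop("labels and frame_labels are misaligned")
  desc <- lapply(ensembles, frame_descriptors)
  out <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    # merged-set row: population over all merged frames
    rows <- list()
    for (src in names(ensembles)) {
      src_mask <- frame_labels$source == src
      frames <- frame_labels$frame[src_mask & in_cl]
      if (!length(frames)) {
        rows[[src]] <- data.frame(cluster = cl, source = src, p = NA_real_,
                                  p_se = NA, BF = NA_real_, BF_se = NA,
                                  p_Glob = NA_real_, p_Glob_se = NA,
                                  HF = NA_real_, HF_se = NA)
        next
      }
      s <- subensemble_summary(ensembles[[src]], frames,
                               descriptors = desc[[src]])
      # p relative to the merged ensemble, not the source alone
      s$p <- sum(in_cl & src_mask) / length(labels)
      rows[[src]] <- cbind(data.frame(cluster = cl, source = src), s)
    }
    out[[length(out) + 1]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
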