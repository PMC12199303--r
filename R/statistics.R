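# Ensemble statistics: free-energy surfaces, helical-globule populations,
# Flyvbjerg-Petersen blocking errors, and subensemble summaries.

#' Two-dimensional free-energy surface
#'
#' Weighted 2-D histogram converted to -ln p (kT = 1 units), shifted so the
#' occupied minimum is 0; empty bins are masked. Invariant to overall
#' weight rescaling and to sample order.
#'
#' @param x,y descriptor series of equal length.
#' @param weights optional per-sample weights (default uniform).
#' @param bins number of bins per axis, length 1 or 2 (default 40 x 40).
#' @param xlim,ylim optional axis ranges (default data range).
#' @return list with `x_edges`, `y_edges`, `free_energy` (matrix, NA in
#'   empty bins), `counts` (weighted), `occupied` (logical mask).
#' @export
fes2d <- function(x, y, weights = NULL, bins = c(40, 40), xlim = NULL,
                  ylim = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  bins <- rep_len(bins, 2)
  if (any(bins < 2)) stop("need at least 2 bins per axis")
  if (is.null(weights)) weights <- rep(1, length(x))
  weights <- weights / sum(weights)
  if (is.null(xlim)) xlim <- range(x)
  if (is.null(ylim)) ylim <- range(y)
  xe <- seq(xlim[1], xlim[2], length.out = bins[1] + 1)
  ye <- seq(ylim[1], ylim[2], length.out = bins[2] + 1)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1), bins[1])
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1), bins[2])
  p <- matrix(0, bins[1], bins[2])
  for (k in seq_along(x)) p[ix[k], iy[k]] <- p[ix[k], iy[k]] + weights[k]
  occ <- p > 0
  fe <- matrix(NA_real_, bins[1], bins[2])
  fe[occ] <- -log(p[occ])
  fe <- fe - min(fe, na.rm = TRUE)
  list(x_edges = xe, y_edges = ye, free_energy = fe, counts = p,
       occupied = occ)
}

#' Flyvbjerg-Petersen blocking error analysis
#'
#' Recursive pairwise averaging ("reblocking"): at each level the series is
#' halved by averaging adjacent pairs and the standard error of the mean is
#' re-estimated together with its own uncertainty. The optimal level is the
#' first at which the SE estimate plateaus within its uncertainty (the SE
#' no longer grows by more than one uncertainty at the next level); for
#' uncorrelated data this is level 0, for positively autocorrelated data it
#' recovers the autocorrelation-inflated SE.
#'
#' @param series numeric vector (length >= 8).
#' @param weights optional per-sample weights; blocks then average with
#'   their weights (block means are weighted, the across-block SE is
#'   unweighted over equal-size blocks).
#' @return object of class `BlockingResult`: list with `table` (level,
#'   block_size, n_blocks, se, se_err), `optimal_level`, `se` (final
#'   standard error), `mean`.
#' @export
blocking_error <- function(series, weights = NULL) {
  n <- length(series)
  if (sd(series) == 0) {
    return(structure(list(table = data.frame(level = 0, block_size = 1,
                                             n_blocks = n, se = 0, se_err = 0),
                          optimal_level = 0, se = 0, mean = series[1]),
                     class = "BlockingResult"))
  }
  if (n < 8) stop("blocking needs a series of length >= 8")
  if (is.null(weights)) weights <- rep(1, n)
  m <- sum(weights * series) / sum(weights)
  x <- series; w <- weights
  tab <- list(); level <- 0
  repeat {
    nb <- length(x)
    if (nb < 2) break
    mu <- sum(w * x) / sum(w)
    se <- sd(x) / sqrt(nb)
    tab[[length(tab) + 1]] <- data.frame(level = level, block_size = n / nb,
                                         n_blocks = nb, se = se,
                                         se_err = se / sqrt(2 * (nb - 1)))
    if (nb < 8) break
    half <- floor(nb / 2)
    i1 <- seq(1, 2 * half, by = 2); i2 <- i1 + 1
    wn <- w[i1] + w[i2]
    x <- (w[i1] * x[i1] + w[i2] * x[i2]) / wn
    w <- wn
    level <- level + 1
  }
  tab <- do.call(rbind, tab)
  opt <- nrow(tab)
  for (k in seq_len(nrow(tab) - 1)) {
    if (tab$se[k + 1] <= tab$se[k] + tab$se_err[k]) { opt <- k; break }
  }
  structure(list(table = tab, optimal_level = tab$level[opt],
                 se = tab$se[opt], mean = m),
            class = "BlockingResult")
}

#' @export
print.BlockingResult <- function(x, ...) {
  cat("Blocking analysis: SE =", format(x$se, digits = 4),
      "at level", x$optimal_level, "\n")
  invisible(x)
}

#' Helical-globule population
#'
#' Weighted fraction of frames in the compact multi-helix "helical globule"
#' state, defined by strict inequalities Salpha > 6.0 and Rg < 1.3 nm, with
#' a blocking standard error on the indicator series.
#'
#' @param descriptors data.frame from [frame_descriptors()] (columns
#'   `salpha`, `rg`).
#' @param weights optional per-frame weights.
#' @param salpha_min Salpha threshold (exclusive, default 6.0).
#' @param rg_max Rg threshold in nm (exclusive, default 1.3).
#' @return list with `population` and `se`.
#' @export
globule_population <- function(descriptors, weights = NULL, salpha_min = 6.0,
                               rg_max = 1.3) {
  ind <- as.numeric(descriptors$salpha > salpha_min & descriptors$rg < rg_max)
  if (is.null(weights)) weights <- rep(1, length(ind))
  weights <- weights / sum(weights)
  p <- sum(weights * ind)
  se <- if (length(ind) >= 8) blocking_error(ind, weights)$se else NA_real_
  list(population = p, se = se)
}

#' Summary statistics of a frame subset
#'
#' Population p (the subset's weight share of the ensemble), bound fraction
#' BF (when a ligand is present), helical-globule population p_Glob, and
#' mean helix fraction HF, each with a blocking standard error.
#'
#' @param ens an `Ensemble`.
#' @param subset frame indices of the subensemble.
#' @param descriptors optional precomputed [frame_descriptors()] for the
#'   whole ensemble (computed on demand otherwise).
#' @return one-row data.frame: p, BF, p_Glob, HF and their SEs.
#' @export
subensemble_summary <- function(ens, subset, descriptors = NULL) {
  if (!length(subset)) stop("empty frame subset")
  if (is.null(descriptors)) descriptors <- frame_descriptors(ens)
  w_all <- ens$weights
  p <- sum(w_all[subset])
  ind_p <- as.numeric(seq_len(n_frames(ens)) %in% subset)
  p_se <- if (n_frames(ens) >= 8) blocking_error(ind_p, w_all)$se else NA_real_
  w <- w_all[subset] / sum(w_all[subset])
  has_lig <- any(ens$topology$atoms$ligand)
  if (has_lig) {
    b <- as.numeric(bound_frames(ens, subset))
    bf <- sum(w * b)
    bf_se <- if (length(subset) >= 8) blocking_error(b, w)$se else NA_real_
  } else { bf <- NA_real_; bf_se <- NA_real_ }
  d <- descriptors[subset, ]
  gl <- globule_population(d, w)
  hf <- sum(w * d$helix_fraction)
  hf_se <- if (length(subset) >= 8) blocking_error(d$helix_fraction, w)$se
           else NA_real_
  data.frame(p = p, p_se = p_se, BF = bf, BF_se = bf_se,
             p_Glob = gl$population, p_Glob_se = gl$se, HF = hf, HF_se = hf_se)
}

#' Stationary AR(1) series with unit marginal variance
#'
#' Fixture generator for blocking-analysis tests: x_t = rho x_(t-1) +
#' sqrt(1 - rho^2) e_t with x_1 ~ N(0, 1).
#'
#' @param n series length.
#' @param rho lag-1 autocorrelation, |rho| < 1.
#' @param seed optional integer seed.
#' @return numeric vector of length n.
#' @export
ar1_series <- function(n, rho, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  e <- rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  s <- sqrt(1 - rho^2)
  for (t in seq_len(n)[-1]) x[t] <- rho * x[t - 1] + s * e[t]
  x
}
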