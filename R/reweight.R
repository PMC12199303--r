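# Maximum-entropy ensemble reweighting against experimental observables:
# Gibbs-form weights w_i proportional to w0_i exp(-sum_j lambda_j s_ij),
# with the restraint multipliers found by minimizing the convex dual with a
# Gaussian uncertainty allowance, plus Kish-ratio-targeted selection of the
# regularization strength and held-out cross-validation.

#' Kish effective-sample-size ratio
#'
#' With normalized weights, 1 / (n * sum(w^2)): the fraction of frames
#' effectively retained by a weighted ensemble (1 for uniform weights,
#' 1/n for a one-hot vector).
#'
#' @param weights non-negative weights (normalized internally).
#' @return fraction in (0, 1].
#' @export
kish_ratio <- function(weights) {
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  w <- weights / s
  1 / (length(w) * sum(w^2))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Maximum-entropy reweighting fit
#'
#' Finds per-frame weights of Gibbs form w_i proportional to
#' w0_i exp(-sum_j lambda_j s_ij) whose reweighted means match the
#' restrained targets up to a Gaussian allowance theta * sigma_j^2, by
#' minimizing the convex dual Gamma(lambda) = log Z + sum(lambda * F_exp)
#' + (theta/2) sum(sigma^2 lambda^2). Smaller theta enforces the
#' restraints harder (theta -> 0 is the hard-constraint limit); larger
#' theta leaves the prior weights intact.
#'
#' @param observables an `ObservableTable`.
#' @param restraints indices or labels of the restrained observables
#'   (default: all).
#' @param prior_weights optional prior frame weights (default uniform).
#' @param theta confidence (regularization) parameter, > 0; use a small
#'   value such as 1e-8 for effectively hard constraints.
#' @param holdout indices or labels used for cross-validation RMSE
#'   (default: all observables not restrained).
#' @param grad_tol convergence tolerance on the dual gradient norm.
#' @return object of class `ReweightResult`: `weights`, `lambda`,
#'   `kish`, `residuals` (restrained), `rmse_fit`, `rmse_cv`, `theta`,
#'   `converged`.
#' @export
maxent_fit <- function(observables, restraints = NULL, prior_weights = NULL,
                       theta = 1e-8, holdout = NULL, grad_tol = 1e-6) {
  obs <- observables
  nf <- nrow(obs$values)
  all_idx <- seq_len(ncol(obs$values))
  ridx <- .resolve_obs(obs, restraints, all_idx)
  hidx <- if (is.null(holdout)) setdiff(all_idx, ridx)
          else .resolve_obs(obs, holdout, integer(0))
  if (length(intersect(ridx, hidx)))
    stop("restraint and held-out observable sets must be disjoint")
  if (theta <= 0) stop("theta must be positive")
  S <- obs$values[, ridx, drop = FALSE]
  Fx <- obs$targets[ridx]
  sig <- obs$uncertainties[ridx]
  if (is.null(prior_weights)) prior_weights <- rep(1 / nf, nf)
  w0 <- prior_weights / sum(prior_weights)
  lw0 <- log(w0)
  # center the observables on their prior means: the weights are invariant
  # and the dual becomes far better conditioned at small theta
  mu0 <- as.numeric(crossprod(S, w0))
  Sc <- sweep(S, 2, mu0)
  Fc <- Fx - mu0
  weights_of <- function(lambda) {
    lw <- lw0 - as.numeric(Sc %*% lambda)
    exp(lw - .logsumexp(lw))
  }
  dual <- function(lambda) {
    .logsumexp(lw0 - as.numeric(Sc %*% lambda)) + sum(lambda * Fc) +
      theta / 2 * sum(sig^2 * lambda^2)
  }
  dual_grad <- function(lambda) {
    w <- weights_of(lambda)
    Fc - as.numeric(crossprod(Sc, w)) + theta * sig^2 * lambda
  }
  # damped Newton on the convex dual: Hessian = Cov_w(s) + theta diag(sig^2)
  lambda <- rep(0, length(ridx))
  f_cur <- dual(lambda)
  damp <- 0
  for (iter in 1:500) {
    w <- weights_of(lambda)
    g <- dual_grad(lambda)
    if (sqrt(sum(g^2)) < grad_tol) break
    Sw <- Sc * w
    H <- crossprod(Sc, Sw) - tcrossprod(colSums(Sw)) +
      diag(theta * sig^2 + 1e-12, length(lambda))
    # Levenberg damping keeps steps sane when the weights concentrate and
    # the covariance degenerates
    scale <- mean(diag(H))
    step <- NULL
    for (k in 0:12) {
      mu <- damp + ifelse(k == 0, 0, scale * 10^(k - 9))
      step <- tryCatch(solve(H + diag(mu, nrow(H)), g), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) break
    }
    if (is.null(step)) step <- g / max(scale, 1e-12)
    t_ls <- 1
    ok <- FALSE
    repeat {
      cand <- lambda - t_ls * step
      f_new <- dual(cand)
      if (is.finite(f_new) && f_new <= f_cur - 1e-4 * t_ls * sum(g * step)) {
        ok <- TRUE; break
      }
      t_ls <- t_ls / 2
      if (t_ls < 1e-13) break
    }
    if (!ok) {
      # fall back to a damped gradient step before giving up
      step <- g / max(scale, 1e-12)
      t_ls <- 1
      repeat {
        cand <- lambda - t_ls * step
        f_new <- dual(cand)
        if (is.finite(f_new) && f_new < f_cur) { ok <- TRUE; break }
        t_ls <- t_ls / 2
        if (t_ls < 1e-13) break
      }
      if (!ok) break
    }
    lambda <- lambda - t_ls * step
    f_cur <- dual(lambda)
  }
  gnorm <- sqrt(sum(dual_grad(lambda)^2))
  converged <- gnorm < max(grad_tol, 1e-8 * (1 + sqrt(sum(Fc^2))))
  if (!converged)
    warning("maxent dual not fully converged: gradient norm ", format(gnorm))
  w <- weights_of(lambda)
  resid <- as.numeric(crossprod(S, w)) - Fx
  rmse_cv <- if (length(hidx)) observable_rmse(obs, w, hidx) else NA_real_
  structure(list(weights = w, lambda = setNames(lambda, obs$labels[ridx]),
                 kish = kish_ratio(w),
                 residuals = setNames(resid, obs$labels[ridx]),
                 rmse_fit = sqrt(mean(resid^2)), rmse_cv = rmse_cv,
                 theta = theta, converged = converged,
                 restraints = ridx, holdout = hidx),
            class = "ReweightResult")
}

.resolve_obs <- function(obs, sel, default) {
  if (is.null(sel)) return(default)
  if (is.character(sel)) {
    idx <- match(sel, obs$labels)
    if (anyNA(idx)) stop("unknown observable label(s): ",
                         paste(sel[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(sel)
}

#' @export
print.ReweightResult <- function(x, ...) {
  cat("Max-ent reweighting: theta =", format(x$theta, digits = 3),
      " Kish =", round(x$kish, 4), "\n")
  cat("  fit RMSE =", format(x$rmse_fit, digits = 4),
      " cross-validation RMSE =", format(x$rmse_cv, digits = 4), "\n")
  invisible(x)
}

#' Tune the restraint strength to a target Kish ratio
#'
#' The Kish ratio is monotone non-decreasing in theta (weaker restraints
#' keep the weights closer to uniform), so bisection on log10(theta)
#' matches the target within `tol`.
#'
#' @inheritParams maxent_fit
#' @param target_kish target effective-sample-size fraction in (0, 1).
#' @param tol Kish matching tolerance (default 0.005).
#' @param log10_range search bracket for log10(theta).
#' @return list with `theta` and `result` (the matched `ReweightResult`).
#' @export
tune_theta <- function(observables, restraints = NULL, prior_weights = NULL,
                       target_kish = 0.101, tol = 0.005,
                       log10_range = c(-8, 8), holdout = NULL) {
  if (target_kish <= 0 || target_kish >= 1)
    stop("target_kish must lie in (0, 1)")
  kish_at <- function(lt) {
    maxent_fit(observables, restraints, prior_weights, theta = 10^lt,
               holdout = holdout)$kish
  }
  lo <- log10_range[1]; hi <- log10_range[2]
  klo <- kish_at(lo); khi <- kish_at(hi)
  # the allowance enters as theta * sigma^2, so the useful theta range moves
  # with the stated uncertainties; expand the bracket until it straddles
  for (k in 1:6) {
    if (khi < target_kish && hi < 40) { hi <- hi + 8; khi <- kish_at(hi) }
    if (klo > target_kish && lo > -40) { lo <- lo - 8; klo <- kish_at(lo) }
  }
  if (target_kish < klo || target_kish > khi)
    stop("target Kish ", target_kish, " unreachable: achievable range [",
         round(klo, 4), ", ", round(khi, 4), "]")
  for (iter in 1:80) {
    mid <- (lo + hi) / 2
    km <- kish_at(mid)
    if (abs(km - target_kish) < tol) break
    if (km > target_kish) hi <- mid else lo <- mid
  }
  res <- maxent_fit(observables, restraints, prior_weights, theta = 10^mid,
                    holdout = holdout)
  list(theta = 10^mid, result = res)
}

#' RMSE between reweighted ensemble means and experimental targets
#'
#' @param observables an `ObservableTable`.
#' @param weights per-frame weights (normalized internally).
#' @param subset observable indices or labels (default all).
#' @return root-mean-square error over the subset.
#' @export
observable_rmse <- function(observables, weights, subset = NULL) {
  idx <- .resolve_obs(observables, subset, seq_len(ncol(observables$values)))
  if (!length(idx)) stop("empty observable subset")
  w <- weights / sum(weights)
  mu <- as.numeric(crossprod(observables$values[, idx, drop = FALSE], w))
  sqrt(mean((mu - observables$targets[idx])^2))
}
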