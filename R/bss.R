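# Blind source separation of evoked LFPs.  JADE (Joint Approximate
# Diagonalization of Eigen-matrices) is implemented from its standard
# definition: whitening, parallel fourth-order cumulant matrices, joint
# diagonalization by Jacobi rotations.

#' JADE blind source separation
#'
#' Separates `n_components` independent sources from a set of observed
#' traces. The observations are centered and whitened internally; the
#' fourth-order cumulant matrix set is jointly diagonalized by Givens
#' rotations. As with any ICA, recovery is up to permutation and scale.
#'
#' @param observations numeric matrix, one observation trace per row (at
#'   least `n_components` rows), or a list of [LfpTrace-class] objects.
#' @param n_components number of sources (4 for the mossy-fiber counts).
#' @param max_sweeps maximum Jacobi sweeps.
#' @param tol rotation threshold (radians) under which a pair is skipped.
#' @return list: `S` (components x time), `A` (mixing, observations x
#'   components), `W` (unmixing, components x observations), `kurtosis`
#'   (per-component excess kurtosis), `reliable` (FALSE when all components
#'   look Gaussian and separation is not identifiable).
#' @examples
#' set.seed(1)
#' S <- rbind(sign(sin(1:2000 / 7)), stats::rexp(2000) - 1,
#'            stats::runif(2000) - 0.5, sin((1:2000) / 31)^3)
#' X <- matrix(stats::rnorm(24), 6, 4) %*% S
#' fit <- jade(X)
#' @export
jade <- function(observations, n_components = 4, max_sweeps = 100,
                 tol = NULL) {
  if (is.list(observations))
    observations <- do.call(rbind, lapply(observations, traceValues))
  X <- as.matrix(observations)
  n <- nrow(X); T <- ncol(X)
  if (n < n_components)
    stop("need at least ", n_components, " observation traces")
  m <- n_components
  X <- X - rowMeans(X)
  # whitening by PCA: keep the m leading directions
  C <- tcrossprod(X) / T
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[m] < 1e-12 * eg$values[1])
    stop("observations are rank deficient after whitening; ",
         "fewer than ", m, " independent sources present")
  W_white <- diag(1 / sqrt(eg$values[1:m])) %*% t(eg$vectors[, 1:m])
  Z <- W_white %*% X                              # m x T, identity covariance
  # parallel cumulant matrices Q_ij = E[z_i z_j z z'] - delta terms
  nq <- m * (m + 1) / 2
  Q <- array(0, c(m, m, nq))
  q <- 0
  I <- diag(m)
  for (i in 1:m) for (j in 1:i) {
    q <- q + 1
    Zi <- Z[i, ]; Zj <- Z[j, ]
    M <- (Z * rep(Zi * Zj, each = m)) %*% t(Z) / T
    M <- M - I * (i == j) - tcrossprod(I[, i], I[, j]) -
         tcrossprod(I[, j], I[, i])
    Q[, , q] <- M
  }
  # joint diagonalization by Jacobi (Givens) rotations
  V <- diag(m)
  if (is.null(tol)) tol <- 1e-6 / sqrt(T)
  for (sweep in seq_len(max_sweeps)) {
    rotated <- FALSE
    for (p in 1:(m - 1)) for (qq in (p + 1):m) {
      g1 <- Q[p, p, ] - Q[qq, qq, ]
      g2 <- Q[p, qq, ] + Q[qq, p, ]
      ton <- sum(g1 * g1) - sum(g2 * g2)
      toff <- 2 * sum(g1 * g2)
      # closed-form Givens angle maximizing the sum of squared diagonals
      theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
      if (abs(sin(theta)) > tol) {
        rotated <- TRUE
        cs <- cos(theta); sn <- sin(theta)
        # apply rotation on rows/cols p,q of every Q and accumulate in V
        Gp <- Q[p, , ]; Gq <- Q[qq, , ]
        Q[p, , ] <- cs * Gp + sn * Gq
        Q[qq, , ] <- -sn * Gp + cs * Gq
        Gp <- Q[, p, ]; Gq <- Q[, qq, ]
        Q[, p, ] <- cs * Gp + sn * Gq
        Q[, qq, ] <- -sn * Gp + cs * Gq
        vp <- V[, p]; vq <- V[, qq]
        V[, p] <- cs * vp + sn * vq
        V[, qq] <- -sn * vp + cs * vq
      }
    }
    if (!rotated) break
  }
  W <- t(V) %*% W_white                           # m x n unmixing
  S <- W %*% X
  # fix sign and scale: unit RMS components, dominant deflection negative
  rms <- sqrt(rowMeans(S^2))
  sgn <- apply(S, 1, function(s) if (abs(min(s)) >= abs(max(s))) 1 else -1)
  S <- S * sgn / rms
  A <- MASS_ginv(W) * rep(rms * sgn, each = n)
  kurt <- apply(S, 1, function(s) mean(s^4) / mean(s^2)^2 - 3)
  list(S = S, A = A, W = W, kurtosis = kurt,
       reliable = any(abs(kurt) > 0.5))
}

# Moore-Penrose pseudoinverse (small matrices; avoids an extra dependency)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Regenerated per-n_mf candidate fields: jittered kernel for each mossy-fiber
# count, scaled to a per-cell field (the cross-validation basis).
.candidateFields <- function(kernels, jitter = jitterSpec()) {
  ord <- order(kernels@combos[, 1])
  lapply(kernels@kernels[ord], function(k) temporalConvolve(k, jitter)@trace)
}

# score an assignment: waveform MSE (%) between scale-matched components and
# candidates over the analysis window
.assignmentMse <- function(S, cands, window) {
  sapply(seq_len(nrow(S)), function(i) {
    s <- S[i, window]; s <- s - mean(s)
    f <- cands[[i]][window]; f <- f - mean(f)
    lam <- sum(s * f) / sum(s * s)              # scale ambiguity resolution
    100 * sum((lam * s - f)^2) / sum(f^2)
  })
}

#' Map BSS components to mossy-fiber counts by cross-validation
#'
#' Every assignment of the separated components to n_mf = 1..4 is scored by
#' the waveform mean-squared error between the components (scale-matched) and
#' the ReConv-regenerated candidate fields for the counts, over the window
#' from stimulus onset to +50 ms. Connectivity fractions are estimated per
#' trace by non-negative projection onto the candidate fields. Under `n`
#' random 2-fold splits, the weights are re-estimated on the training fold,
#' the LFP is regenerated with them, and the reported MSE is its waveform
#' error against the held-out traces.
#'
#' @param observations matrix (traces x time) or list of [LfpTrace-class].
#' @param kernels [KernelSet-class] with kernels for n_mf 1..4 (the ReConv
#'   engine configured as the observations' protocol).
#' @param onset_ms,dt_ms stimulus onset and sampling of the observations
#'   (taken from the traces when a list is given).
#' @param folds number of folds (2). @param n repetitions (10).
#' @param seed RNG seed for the fold splits.
#' @return list: `assignment` (component index per n_mf), `mse` (%,
#'   cross-validated), `per_component_mse` (%), `weights` (fractions per
#'   n_mf), `trace_weights`, `tie` (logical), `fit` (the full-data [jade()]
#'   fit).
#' @export
crossValidate <- function(observations, kernels, onset_ms = NULL,
                          dt_ms = NULL, folds = 2, n = 10, seed = 1) {
  if (is.list(observations)) {
    onset_ms <- observations[[1]]@onset_ms
    dt_ms <- observations[[1]]@dt
    observations <- do.call(rbind, lapply(observations, traceValues))
  }
  stopifnot(!is.null(onset_ms), !is.null(dt_ms))
  cands <- .candidateFields(kernels)
  i0 <- round(onset_ms / dt_ms) + 1L
  window <- i0:min(i0 + round(50 / dt_ms), ncol(observations),
                   length(cands[[1]]))
  perms <- .permutations(4)
  Fk <- do.call(rbind, cands)[, window, drop = FALSE]   # candidate k x time

  # per-trace connectivity fractions: non-negative projection of each
  # observation onto the regenerated candidate fields
  fit_weights <- function(obs) {
    basis <- t(Fk)
    t(apply(obs[, window, drop = FALSE], 1, function(y) {
      cf <- pmax(unname(stats::lm.fit(basis, y)$coefficients), 0)
      if (sum(cf) <= 0) rep(0.25, 4) else cf / sum(cf)
    }))
  }

  # component ci vs candidate k waveform error and matching scale; the best
  # assignment maps components to counts by waveform shape
  analyse_fit <- function(f) {
    err <- matrix(0, 4, 4)
    for (k in 1:4) for (ci in 1:4) {
      # components are centered in time; compare shapes mean-free
      sc <- f$S[ci, window]; sc <- sc - mean(sc)
      fc <- Fk[k, ]; fc <- fc - mean(fc)
      l <- sum(sc * fc) / sum(sc * sc)
      err[k, ci] <- 100 * sum((l * sc - fc)^2) / sum(fc^2)
    }
    tot <- apply(perms, 1, function(pp) sum(err[cbind(1:4, pp)]))
    list(best = perms[which.min(tot), ], tot = tot, err = err)
  }

  fit <- jade(observations)
  full <- analyse_fit(fit)
  tie <- sum(abs(full$tot - min(full$tot)) < 1e-12) > 1
  wtr <- fit_weights(observations)
  w <- colMeans(wtr); w <- w / sum(w)

  # cross-validated regeneration error: weights estimated on the training
  # fold, the regenerated LFP scored against the held-out traces
  set.seed(seed)
  nt <- nrow(observations)
  cv <- c()
  for (r in seq_len(n)) {
    fold_id <- sample(rep(seq_len(folds), length.out = nt))
    for (k in seq_len(folds)) {
      train <- observations[fold_id != k, , drop = FALSE]
      test <- observations[fold_id == k, , drop = FALSE]
      if (nrow(train) < 1 || nrow(test) < 1) next
      wk <- colMeans(fit_weights(train))
      recon <- as.numeric(wk %*% Fk)
      err <- sapply(seq_len(nrow(test)), function(j) {
        y <- test[j, window]
        sc <- sum(y * recon) / sum(recon^2)     # free amplitude scale
        100 * sum((y - sc * recon)^2) / sum(y^2)
      })
      cv <- c(cv, mean(err))
    }
  }
  list(assignment = full$best, mse = mean(cv),
       per_component_mse = full$err[cbind(1:4, full$best)],
       weights = w, trace_weights = wtr,
       tie = tie, fit = fit, window = window, cands = cands)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Estimate mossy-fiber connectivity weights from evoked LFPs
#'
#' Full pipeline: JADE separation into four components, cross-validated
#' mapping of components to mossy-fiber counts, and per-trace weight
#' estimation by non-negative projection onto the regenerated candidate
#' fields. Reports the mean fraction w_i per n_mf and the min-max range of
#' the per-trace fractions.
#'
#' @inheritParams crossValidate
#' @return A [BssResult-class].
#' @examples
#' \donttest{
#' fx <- generateFixture(fixtureSpec(n_traces = 8), seed = 2)
#' res <- estimateWeights(fx$traces, fx$kernels, n = 2)
#' recoveredWeights(res)
#' }
#' @export
estimateWeights <- function(observations, kernels, onset_ms = NULL,
                            dt_ms = NULL, folds = 2, n = 10, seed = 1) {
  if (is.list(observations)) {
    onset_ms <- observations[[1]]@onset_ms
    dt_ms <- observations[[1]]@dt
    observations <- do.call(rbind, lapply(observations, traceValues))
  }
  cvr <- crossValidate(observations, kernels, onset_ms, dt_ms,
                       folds = folds, n = n, seed = seed)
  new("BssResult",
      components = cvr$fit$S[cvr$assignment, , drop = FALSE],
      mixing = cvr$fit$A, weights = cvr$weights,
      ranges = rbind(min = apply(cvr$trace_weights, 2, min),
                     max = apply(cvr$trace_weights, 2, max)),
      mse = cvr$mse, per_component_mse = cvr$per_component_mse,
      assignment = as.integer(cvr$assignment),
      reliable = cvr$fit$reliable, tie = cvr$tie)
}
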