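synthSources <- function(T = 8000) {
  # independent, non-Gaussian sources with distinct temporal structure
  rbind(sign(sin((1:T) / 9)) * (1 + 0.2 * sin((1:T) / 401)),
        stats::rexp(T) - 1,
        stats::runif(T, -1, 1)^3,
        sin((1:T) / 23) * stats::rbinom(T, 1, 0.3))
}

test_that("JADE separates synthetic non-Gaussian mixtures (Amari < 0.05)", {
  idx <- sapply(1:20, function(s) {
    set.seed(s)
    S <- synthSources()
    A <- matrix(rnorm(6 * 4), 6, 4)
    fit <- jade(A %*% S)
    amariIndex(fit$W %*% A)
  })
  expect_lt(median(idx), 0.03)
  expect_true(all(idx < 0.05))
})

test_that("already-independent observations yield a permutation unmixing", {
  set.seed(3)
  S <- synthSources()
  fit <- jade(S)   # identity mixing, 4 observations
  P <- fit$W %*% diag(4)
  expect_lt(amariIndex(P), 0.05)
  # every row has exactly one non-negligible entry
  Pn <- abs(P) / apply(abs(P), 1, max)
  expect_true(all(rowSums(Pn > 0.1) == 1))
})

test_that("Gaussian-only sources are flagged unreliable", {
  set.seed(4)
  S <- matrix(rnorm(4 * 4000), 4)
  fit <- jade(matrix(rnorm(24), 6, 4) %*% S)
  expect_false(fit$reliable)
  set.seed(5)
  fit2 <- jade(matrix(rnorm(24), 6, 4) %*% synthSources())
  expect_true(fit2$reliable)
})

test_that("rank-deficient observations raise a dimensionality error", {
  set.seed(6)
  S <- synthSources()[1:2, ]
  X <- matrix(rnorm(12), 6, 2) %*% S   # only 2 sources present
  expect_error(jade(X), "rank deficient")
})

test_that("the correct component assignment beats scrambled ones", {
  ks <- cachedKernels()
  fx <- generateFixture(fixtureSpec(n_traces = 8, noise_sd = 0.2,
                                    weight_jitter = 0.15),
                        seed = 21, kernels = ks)
  cv <- crossValidate(fx$traces, ks, n = 2, seed = 1)
  # exhaustive enumeration of all 24 assignments
  fit <- jade(do.call(rbind, lapply(fx$traces, traceValues)))
  cands <- grclfp:::.candidateFields(ks)
  window <- cv$window
  perms <- grclfp:::.permutations(4)
  Fk <- do.call(rbind, cands)[, window]
  err <- matrix(0, 4, 4)
  for (k in 1:4) for (ci in 1:4) {
    s <- fit$S[ci, window]; s <- s - mean(s)
    f <- Fk[k, ]; f <- f - mean(f)
    l <- sum(s * f) / sum(s * s)
    err[k, ci] <- 100 * sum((l * s - f)^2) / sum(f^2)
  }
  tot <- apply(perms, 1, function(pp) sum(err[cbind(1:4, pp)]))
  expect_equal(cv$assignment, perms[which.min(tot), ])
  expect_gt(sort(tot)[2], min(tot))
})

test_that("a target equal to a regenerated candidate is matched with ~0 MSE", {
  ks <- cachedKernels()
  cands <- grclfp:::.candidateFields(ks)
  # observations: scaled copies of the n_mf = 2 candidate (tiny noise keeps
  # the observation matrix full rank for the whitening step)
  set.seed(9)
  f2 <- cands[[2]]
  X <- do.call(rbind, lapply(seq(0.8, 1.5, 0.1), function(s)
    s * f2 + rnorm(length(f2), 0, 1e-4 * max(abs(f2)))))
  cv <- crossValidate(X, ks, onset_ms = 10, dt_ms = 0.025, n = 2, seed = 1)
  expect_lt(cv$mse, 0.5)
  # the component carrying the waveform matches candidate 2 best
  carrier <- which.max(abs(cor(t(cv$fit$S), f2)))
  errs <- sapply(1:4, function(k) {
    sc <- cv$fit$S[carrier, cv$window]; sc <- sc - mean(sc)
    fc <- cands[[k]][cv$window]; fc <- fc - mean(fc)
    l <- sum(sc * fc) / sum(sc * sc)
    sum((l * sc - fc)^2) / sum(fc^2)
  })
  expect_equal(which.min(errs), 2)
})

test_that("closed-loop weight recovery matches the generating fractions", {
  ks <- cachedKernels()
  errs <- sapply(1:4, function(s) {
    fx <- generateFixture(fixtureSpec(n_traces = 10), seed = 100 + s,
                          kernels = ks)
    res <- estimateWeights(fx$traces, ks, n = 2, seed = s)
    max(abs(recoveredWeights(res) - fx$truth$weights))
  })
  expect_lt(mean(errs), 0.01)        # within 1% absolute per component
  expect_true(all(errs < 0.02))
})

test_that("weights sum to one and are invariant to trace relabeling", {
  ks <- cachedKernels()
  fx <- generateFixture(fixtureSpec(n_traces = 8), seed = 31, kernels = ks)
  r1 <- estimateWeights(fx$traces, ks, n = 2, seed = 1)
  r2 <- estimateWeights(rev(fx$traces), ks, n = 2, seed = 1)
  expect_equal(sum(recoveredWeights(r1)), 1, tolerance = 1e-6)
  expect_equal(recoveredWeights(r1), recoveredWeights(r2), tolerance = 1e-6)
})

test_that("a single dominant component is recovered as such", {
  ks <- cachedKernels()
  fx <- generateFixture(fixtureSpec(n_traces = 8,
                                    weights = c(0.97, 0.01, 0.01, 0.01),
                                    weight_jitter = 0.3),
                        seed = 41, kernels = ks)
  res <- estimateWeights(fx$traces, ks, n = 2, seed = 1)
  expect_equal(which.max(recoveredWeights(res)), 1)
  expect_gt(recoveredWeights(res)[1], 0.6)
})

test_that("in vitro connectivity puts the largest fraction on 2 fibers", {
  ks <- cachedKernels()
  fx <- generateFixture(fixtureSpec(n_traces = 10,
                                    weights = connectivityWeights("invitro")),
                        seed = 51, kernels = ks)
  res <- estimateWeights(fx$traces, ks, n = 2, seed = 1)
  expect_equal(which.max(recoveredWeights(res)), 2)
})
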