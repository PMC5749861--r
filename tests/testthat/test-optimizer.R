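test_that("objective evaluates term by term", {
  pr <- randomProblem(30, n = 6, t = 4)
  L <- Reduce(`+`, pr$Ls) / 9
  G0 <- lapply(pr$X, function(x) matrix(0, nrow(x), pr$t))

  # F = Y, G = 0: fit term 0, subspace term mu * m * ||Y||^2
  expect_equal(lrsslObjective(pr$Y, G0, pr$X, pr$Y, L),
               sum(pr$Y * (L %*% pr$Y)) + 2 * sum(pr$Y^2))
  # everything zero
  Y0 <- matrix(0, pr$n, pr$t)
  expect_equal(lrsslObjective(Y0, G0, pr$X, Y0, L), 0)

  # raising any G entry strictly increases the L1 penalty
  set.seed(31)
  G <- lapply(pr$X, function(x) matrix(runif(nrow(x) * pr$t), nrow(x), pr$t))
  l1 <- function(G) lrsslObjective(pr$Y, G, pr$X, pr$Y, L, lambda = 1) -
    lrsslObjective(pr$Y, G, pr$X, pr$Y, L, lambda = 0)
  G2 <- G
  G2[[1]][2, 3] <- G2[[1]][2, 3] + 0.5
  expect_gt(l1(G2), l1(G))

  Fbad <- matrix(c(NaN, rep(0, pr$n * pr$t - 1)), pr$n, pr$t)
  expect_error(lrsslObjective(Fbad, G0, pr$X, pr$Y, L), "non-finite")
})

test_that("F update is the stationary point of the objective", {
  # L = 0, G = 0, mu = 1, m = 2: F = Y / 3
  pr <- randomProblem(32, n = 5, t = 3)
  G0 <- lapply(pr$X, function(x) matrix(0, nrow(x), pr$t))
  P0 <- solve(matrix(0, pr$n, pr$n) + 3 * diag(pr$n))
  expect_equal(updateF(P0, pr$X, G0, pr$Y), pr$Y / 3)
  expect_equal(updateF(P0, pr$X, G0, matrix(0, pr$n, pr$t)),
               matrix(0, pr$n, pr$t))

  # finite-difference gradient vanishes at the returned F
  pr <- randomProblem(33, n = 7, t = 4)
  L <- Reduce(`+`, pr$Ls) / 9
  set.seed(33)
  G <- lapply(pr$X, function(x) matrix(runif(nrow(x) * pr$t), nrow(x), pr$t))
  P <- solve(L + 3 * diag(pr$n))
  F <- updateF(P, pr$X, G, pr$Y)
  obj <- function(Fm) lrsslObjective(Fm, G, pr$X, pr$Y, L)
  eps <- 1e-6
  grad <- matrix(0, pr$n, pr$t)
  for (i in seq_len(pr$n)) for (j in seq_len(pr$t)) {
    E <- matrix(0, pr$n, pr$t)
    E[i, j] <- eps
    grad[i, j] <- (obj(F + E) - obj(F - E)) / (2 * eps)
  }
  expect_lt(sqrt(sum(grad^2)), 1e-5 * (1 + abs(obj(F))))
})

test_that("multiplicative updates keep zeros fixed and reject negative input", {
  pr <- randomProblem(34, n = 6, t = 4)
  L <- Reduce(`+`, pr$Ls) / 9
  P <- solve(L + 3 * diag(pr$n))
  G0 <- lapply(pr$X, function(x) matrix(0, nrow(x), pr$t))
  expect_equal(updateG(1, G0, pr$X, P, pr$Y), G0[[1]])

  Gneg <- G0
  Gneg[[1]][1, 1] <- -0.1
  expect_error(updateG(1, Gneg, pr$X, P, pr$Y), "negative")
})

test_that("entries with no driving force are annihilated when lambda = 0 and P = I", {
  # A_p = X (mu I - mu^2 I) X' = 0: the update is driven by B signs alone
  set.seed(35)
  n <- 5; t <- 3
  X <- list(matrix(runif(4 * n), 4, n), matrix(0, 3, n))
  Y <- matrix(rbinom(n * t, 1, 0.4), n, t)
  G <- list(matrix(runif(4 * t), 4, t), matrix(runif(3 * t), 3, t))
  # for p = 2, B_2 = X_2 (...) = 0 entirely, so G_2 -> 0
  G2 <- updateG(2, G, X, diag(n), Y, lambda = 0)
  expect_equal(G2, matrix(0, 3, t))
})

test_that("the combined G and F steps never increase the objective", {
  # descent oracle: objective measured at the F-optimum before and after
  # one multiplicative sweep, over 100 random instances
  for (s in 1:100) {
    pr <- randomProblem(200 + s)
    set.seed(300 + s)
    alpha <- rep(1 / 3, 3)
    L <- Reduce(`+`, Map(function(a, Lq) a^2 * Lq, alpha, pr$Ls))
    P <- solve(L + 3 * diag(pr$n))
    P <- (P + t(P)) / 2
    G <- lapply(pr$X, function(x) matrix(runif(nrow(x) * pr$t), nrow(x), pr$t))
    F0 <- updateF(P, pr$X, G, pr$Y)
    before <- lrsslObjective(F0, G, pr$X, pr$Y, L)
    for (p in 1:2) G[[p]] <- updateG(p, G, pr$X, P, pr$Y)
    F1 <- updateF(P, pr$X, G, pr$Y)
    after <- lrsslObjective(F1, G, pr$X, pr$Y, L)
    expect_lte(after, before + 1e-8)
    expect_true(all(G[[1]] >= 0) && all(G[[2]] >= 0))
  }
})

test_that("alpha update follows the closed form and sums to one", {
  n <- 6
  F <- diag(n)[, 1:3]
  mk <- function(c) c * diag(n) - 0 # scaled identity is PSD with Tr = c * ||F||^2
  # traces (1, 1, 1) -> uniform
  expect_equal(updateAlpha(F / sqrt(3), list(diag(n), diag(n), diag(n))),
               rep(1 / 3, 3))
  # traces (1, 2, 2) at gamma 2 -> (1/2, 1/4, 1/4)
  expect_equal(updateAlpha(F / sqrt(3), list(diag(n), 2 * diag(n), 2 * diag(n))),
               c(1 / 2, 1 / 4, 1 / 4))
  # swapping the profile Laplacians swaps the weights
  a <- updateAlpha(F, list(diag(n), 3 * diag(n), 2 * diag(n)))
  b <- updateAlpha(F, list(3 * diag(n), diag(n), 2 * diag(n)))
  expect_equal(a[c(2, 1, 3)], b)

  # zero-trace graphs absorb all mass, uniformly among themselves
  Z <- matrix(0, n, n)
  expect_equal(updateAlpha(F, list(Z, diag(n), Z)), c(0.5, 0, 0.5))
  expect_equal(updateAlpha(F, list(Z, Z, Z)), rep(1 / 3, 3))

  for (s in 1:10) {
    pr <- randomProblem(400 + s)
    F <- matrix(rnorm(pr$n * pr$t), pr$n, pr$t)
    a <- updateAlpha(F, pr$Ls)
    expect_equal(sum(a), 1)
    expect_true(all(a >= 0))
  }
})

test_that("fit is deterministic, monotone and respects the tolerance contract", {
  pr <- randomProblem(50, n = 10, t = 8)
  ctl <- lrsslControl(maxIter = 80, seed = 7)
  fit1 <- fitLRSSL(pr$X, pr$Y, pr$Ls, ctl)
  fit2 <- fitLRSSL(pr$X, pr$Y, pr$Ls, ctl)
  expect_identical(fit1@F, fit2@F) # bit-identical under equal seeds

  tr <- objectiveTrace(fit1)
  expect_true(all(diff(tr) <= 1e-8))
  expect_true(all(vapply(fit1@G, function(g) all(g >= 0), TRUE)))
  expect_equal(sum(alphaWeights(fit1)), 1)

  one <- fitLRSSL(pr$X, pr$Y, pr$Ls, lrsslControl(tol = Inf, seed = 7))
  expect_equal(one@iterations, 1L)
  expect_length(objectiveTrace(one), 1)

  # a different seed changes the initialization but not validity
  fit3 <- fitLRSSL(pr$X, pr$Y, pr$Ls, lrsslControl(maxIter = 80, seed = 8))
  expect_false(identical(fit1@F, fit3@F))
})

test_that("nonnegativity of projections survives long runs", {
  pr <- randomProblem(60, n = 8, t = 5)
  fit <- fitLRSSL(pr$X, pr$Y, pr$Ls, lrsslControl(maxIter = 500, seed = 1))
  expect_true(all(fit@G[[1]] >= 0))
  expect_true(all(fit@G[[2]] >= 0))
  expect_true(all(diff(objectiveTrace(fit)) <= 1e-8))
})
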