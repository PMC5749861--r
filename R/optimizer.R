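#' Hyperparameter control list
#'
#' Collects the tunable parameters of the model and its surrounding
#' pipeline. Defaults follow the published parameterization: subspace
#' balance `mu = 1`, sparsity weight `lambda = 1`, Laplacian weight exponent
#' `gamma = 2` (must exceed 1 so every graph contributes), kernel bandwidth
#' scale `gammaPrime = 1`, `k = 10` for both the feature-neighborhood and
#' the kNN graphs, 10 histogram bins. `maxIter`/`tol` govern the
#' alternating optimization (stop when the relative objective change drops
#' below `tol`); `seed` makes the uniform nonnegative initialization of the
#' projection matrices reproducible.
#'
#' @param mu positive subspace regression weight.
#' @param lambda nonnegative L1-sparsity weight.
#' @param gamma Laplacian weight exponent, > 1.
#' @param gammaPrime positive Gaussian kernel bandwidth scale.
#' @param kGraph neighborhood size of the kNN graphs.
#' @param kFeatures neighborhood size inside the graph-theoretical profile.
#' @param bins histogram bins of the statistical profile.
#' @param maxIter iteration cap of the alternating optimization.
#' @param tol relative objective-change tolerance; `Inf` performs exactly
#'   one iteration.
#' @param seed integer seed for the projection-matrix initialization.
#' @return A named list of class `lrsslControl`.
#' @export
lrsslControl <- function(mu = 1, lambda = 1, gamma = 2, gammaPrime = 1,
                         kGraph = 10, kFeatures = 10, bins = 10,
                         maxIter = 1000, tol = 1e-6, seed = 0) {
  stopifnot(mu > 0, lambda >= 0, gamma > 1, gammaPrime > 0,
            kGraph >= 1, kFeatures >= 1, bins >= 1, maxIter >= 1, tol > 0)
  structure(list(mu = mu, lambda = lambda, gamma = gamma,
                 gammaPrime = gammaPrime, kGraph = kGraph,
                 kFeatures = kFeatures, bins = bins, maxIter = maxIter,
                 tol = tol, seed = seed),
            class = "lrsslControl")
}

#' Model objective value
#'
#' Evaluates the fitting criterion: squared Frobenius distance of the
#' prediction `F` to the observed associations `Y`, the Laplacian
#' smoothness penalty `Tr(F' L F)`, the subspace regression error
#' `mu * sum_p ||X_p' G_p - F||_F^2`, and the squared column-wise L1 norm
#' of each projection matrix weighted by `lambda`.
#'
#' @param F n-by-t prediction matrix.
#' @param G list of d_p-by-t nonnegative projection matrices.
#' @param X list of d_p-by-n feature matrices.
#' @param Y n-by-t 0/1 association matrix (this side's orientation).
#' @param L combined n-by-n graph Laplacian.
#' @param mu,lambda weights, see [lrsslControl()].
#' @return The objective value, a finite nonnegative number.
#' @export
lrsslObjective <- function(F, G, X, Y, L, mu = 1, lambda = 1) {
  fit <- sum((F - Y)^2) + sum(F * (L %*% F))
  sub <- sum(vapply(seq_along(X),
                    function(p) sum((crossprod(X[[p]], G[[p]]) - F)^2), 0))
  l1 <- sum(vapply(G, function(g) sum(colSums(g)^2), 0))
  obj <- fit + mu * sub + lambda * l1
  if (!is.finite(obj)) {
    parts <- c(fit = fit, subspace = sub, l1 = l1)
    stop(sprintf("non-finite objective (offending term: %s)",
                 paste(names(parts)[!is.finite(parts)], collapse = ", ")), call. = FALSE)
  }
  obj
}

#' Closed-form update of the prediction matrix
#'
#' `F` is the unconstrained stationary point of the objective:
#' `F = P (Y + mu * sum_p X_p' G_p)` with `P = (L + (1 + m*mu) I)^{-1}`.
#' The diagonal shift makes the system strictly positive definite, so the
#' solve always succeeds.
#'
#' @param P the precomputed inverse `(L + (1 + m*mu) I)^{-1}`.
#' @param X list of feature matrices.
#' @param G list of projection matrices.
#' @param Y association matrix, this side's orientation.
#' @param mu subspace regression weight.
#' @return The updated `F`.
#' @export
updateF <- function(P, X, G, Y, mu = 1) {
  acc <- Y
  for (p in seq_along(X)) acc <- acc + mu * crossprod(X[[p]], G[[p]])
  P %*% acc
}

#' Multiplicative update of one projection matrix
#'
#' Auxiliary-function update with positive/negative part splitting:
#' with `A_p = X_p (mu I - mu^2 P) X_p' + lambda 11'` and
#' `B_p = mu X_p P Y + mu^2 sum_{q != p} X_p P X_q' G_q`, each entry is
#' rescaled by `sqrt((A_p^- G_p + B_p^+) / (A_p^+ G_p + B_p^- + eps))`.
#' Zero entries are fixed points; nonnegativity is preserved. This is a
#' block-coordinate descent step on the objective with `F` eliminated at
#' its optimum.
#'
#' @param p index of the profile to update.
#' @param G list of current projection matrices (entrywise nonnegative).
#' @param X list of feature matrices.
#' @param P the inverse `(L + (1 + m*mu) I)^{-1}` (symmetric).
#' @param Y association matrix, this side's orientation.
#' @param mu,lambda weights.
#' @param eps denominator guard.
#' @return The updated `G_p`, entrywise nonnegative.
#' @export
updateG <- function(p, G, X, P, Y, mu = 1, lambda = 1, eps = 1e-12) {
  if (any(G[[p]] < 0)) stop("projection matrix has negative entries", call. = FALSE)
  n <- ncol(X[[p]])
  Xp <- X[[p]]
  A <- Xp %*% (mu * diag(n) - mu^2 * P) %*% t(Xp) + lambda
  B <- mu * Xp %*% P %*% Y
  for (q in seq_along(X)) {
    if (q == p) next
    B <- B + mu^2 * Xp %*% P %*% crossprod(X[[q]], G[[q]])
  }
  num <- negPart(A) %*% G[[p]] + posPart(B)
  den <- posPart(A) %*% G[[p]] + negPart(B) + eps
  out <- G[[p]] * sqrt(num / den)
  if (any(!is.finite(out))) stop("non-finite projection update", call. = FALSE)
  out
}

#' Closed-form update of the Laplacian contribution weights
#'
#' Minimizes `sum_q alpha_q^gamma Tr(F' L_q F)` subject to the weights
#' summing to 1: `alpha_q` is proportional to
#' `(1 / Tr(F' L_q F))^(1/(gamma-1))`. Graphs on which `F` is already
#' perfectly smooth (zero trace) absorb all the mass, split uniformly among
#' themselves; if every trace is zero the weights are uniform.
#'
#' @param F current prediction matrix.
#' @param Ls list of the individual Laplacians (profile 1, profile 2,
#'   association graph).
#' @param gamma weight exponent, > 1.
#' @return Numeric weight vector summing to 1.
#' @export
updateAlpha <- function(F, Ls, gamma = 2) {
  tr <- vapply(Ls, function(L) sum(F * (L %*% F)), 0)
  tr <- pmax(tr, 0) # PSD up to round-off
  if (all(tr == 0)) return(rep(1 / length(tr), length(tr)))
  if (any(tr == 0)) {
    a <- as.numeric(tr == 0)
    return(a / sum(a))
  }
  w <- tr^(-1 / (gamma - 1))
  w / sum(w)
}

#' Fit the subspace-learning model for one side
#'
#' Alternating optimization of the objective in [lrsslObjective()]. The
#' Laplacian weights start uniform at 1/3 and the projection matrices at
#' uniform random nonnegative values (seeded). Each iteration rebuilds the
#' combined Laplacian `L = sum_p alpha_p^gamma L_p + alpha_MDA^gamma L_MDA`
#' and its resolvent `P`, takes one multiplicative descent step per
#' projection matrix, recomputes `F` in closed form, records the objective,
#' and renews the weights. The recorded trace is non-increasing; iteration
#' stops when its relative change falls below `tol` or at `maxIter`.
#'
#' @param X list of two scaled feature matrices (d_p-by-n).
#' @param Y n-by-t 0/1 association matrix, this side's orientation.
#' @param Ls list of three Laplacian matrices (profile 1, profile 2,
#'   association graph), n-by-n.
#' @param control an [lrsslControl()] list.
#' @param side label stored in the fit, `"mirna"` or `"disease"`.
#' @return An [LRSSLFit-class].
#' @export
fitLRSSL <- function(X, Y, Ls, control = lrsslControl(),
                     side = c("mirna", "disease")) {
  side <- match.arg(side)
  X <- lapply(X, as.matrix)
  Y <- as.matrix(Y)
  m <- length(X)
  stopifnot(m == 2, length(Ls) == m + 1)
  n <- ncol(X[[1]])
  t <- ncol(Y)
  stopifnot(nrow(Y) == n, all(vapply(Ls, nrow, 0L) == n))
  mu <- control$mu
  lambda <- control$lambda
  gamma <- control$gamma

  alpha <- rep(1 / 3, m + 1)
  G <- withSeed(control$seed, lapply(X, function(x) {
    matrix(stats::runif(nrow(x) * t), nrow(x), t)
  }))
  trace <- numeric(0)
  converged <- FALSE
  F <- NULL
  it <- 0L
  while (it < control$maxIter) {
    it <- it + 1L
    L <- Reduce(`+`, Map(function(a, Lq) a^gamma * Lq, alpha, Ls))
    P <- solve(L + (1 + m * mu) * diag(n))
    P <- (P + t(P)) / 2
    for (p in seq_len(m)) {
      G[[p]] <- updateG(p, G, X, P, Y, mu = mu, lambda = lambda)
    }
    F <- updateF(P, X, G, Y, mu = mu)
    obj <- lrsslObjective(F, G, X, Y, L, mu = mu, lambda = lambda)
    trace <- c(trace, obj)
    alpha <- updateAlpha(F, Ls, gamma = gamma)
    if (is.infinite(control$tol)) break
    if (it > 1) {
      rel <- abs(trace[it] - trace[it - 1]) / max(1, abs(trace[it - 1]))
      if (rel < control$tol) {
        converged <- TRUE
        break
      }
    }
  }
  new("LRSSLFit", F = F, G = G, alpha = alpha, objective = trace,
      iterations = it, converged = converged, side = side,
      control = unclass(control))
}
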