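# Fixtures and independent oracles shared across tests. Everything is
# generated in code; no data files.

named01 <- function(values, nm, nd, prefix = c("m", "d")) {
  matrix(values, nm, nd, dimnames = list(sprintf("%s%02d", prefix[1], seq_len(nm)),
                                         sprintf("%s%02d", prefix[2], seq_len(nd))))
}

randomAssoc <- function(nm, nd, density = 0.3, seed = 1) {
  set.seed(seed)
  named01(rbinom(nm * nd, 1, density), nm, nd)
}

randomSim <- function(n, seed = 1, names = sprintf("e%02d", seq_len(n))) {
  set.seed(seed)
  v <- matrix(runif(n * n), n)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  dimnames(v) <- list(names, names)
  v
}

# Symmetric binary Laplacian from a random graph.
randomLaplacian <- function(n, seed = 1, p = 0.3) {
  set.seed(seed)
  S <- matrix(rbinom(n^2, 1, p), n)
  S <- pmax(S, t(S))
  diag(S) <- 0
  diag(rowSums(S)) - S
}

# Random optimizer problem of the model's shape (two profiles, three
# Laplacians).
randomProblem <- function(seed, n = NULL, t = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(5:15, 1)
  if (is.null(t)) t <- sample(3:10, 1)
  d1 <- sample(4:20, 1)
  d2 <- sample(4:20, 1)
  list(X = list(matrix(runif(d1 * n), d1, n), matrix(runif(d2 * n), d2, n)),
       Y = matrix(rbinom(n * t, 1, 0.3), n, t),
       Ls = list(randomLaplacian(n, seed + 1), randomLaplacian(n, seed + 2),
                 randomLaplacian(n, seed + 3)),
       n = n, t = t)
}

# Exhaustive enumeration oracle for the pooled rank ROC: place every
# round's items explicitly (test at its rank, candidates at the remaining
# positions) and sweep every integer threshold.
rocOracle <- function(ranks, counts) {
  thr <- 0:(max(counts) + 1)
  tp <- fp <- numeric(length(thr))
  for (r in seq_along(ranks)) {
    candPos <- setdiff(seq_len(counts[r] + 1), ranks[r])
    tp <- tp + vapply(thr, function(t) as.numeric(ranks[r] <= t), 0)
    fp <- fp + vapply(thr, function(t) sum(candPos <= t), 0)
  }
  tpr <- tp / length(ranks)
  fpr <- fp / sum(counts)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Brute-force directed top-k by cosine similarity with index tie-breaks,
# then OR symmetrization; independent of the package implementation.
bruteKnnCosine <- function(X, k) {
  n <- ncol(X)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sims <- vapply(seq_len(n), function(j) cosv(X[, i], X[, j]), 0)
    cand <- setdiff(seq_len(n), i)
    cand <- cand[order(-sims[cand], cand)]
    S[i, cand[seq_len(min(k, length(cand)))]] <- 1
  }
  pmax(S, t(S))
}

# Semantic similarity recomputed independently with a configurable log
# base, straight from the defining sums.
bruteSemanticSim <- function(dags, base = exp(1)) {
  nodes <- lapply(dags, function(d) d@nodes)
  n <- length(dags)
  member <- table(unlist(lapply(nodes, unique)))
  contrib <- -log(as.numeric(member) / n, base = base)
  names(contrib) <- names(member)
  dv <- vapply(nodes, function(nd) sum(contrib[nd]), 0)
  ss <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (dv[i] > 0 && dv[j] > 0) {
      sh <- intersect(nodes[[i]], nodes[[j]])
      ss[i, j] <- 2 * sum(contrib[sh]) / (dv[i] + dv[j])
    }
  }
  ss
}

tinyData <- function(seed = 2) simulateMDA(syntheticPreset("tiny", seed = seed))

tinyControl <- function(maxIter = 150, ...) {
  lrsslControl(kGraph = 4, kFeatures = 4, maxIter = maxIter, ...)
}

# AUC of scores at given positive indices against negative indices
# (mid-rank Mann-Whitney), independent of rocAuc().
scoreAuc <- function(S, pos, neg) {
  mean(vapply(S[pos], function(x) mean(S[neg] < x) + 0.5 * mean(S[neg] == x), 0))
}
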