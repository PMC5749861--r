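makeSim <- function(v) {
  n <- nrow(v)
  dimnames(v) <- list(sprintf("e%02d", 1:n), sprintf("e%02d", 1:n))
  v
}

test_that("statistical profile reproduces hand-computed summaries", {
  # entity 1's off-diagonal similarity row is (0.5, 0.3, 1.0)
  v <- diag(4)
  v[1, 2:4] <- v[2:4, 1] <- c(0.5, 0.3, 1.0)
  v[2, 3] <- v[3, 2] <- 0.4
  v[2, 4] <- v[4, 2] <- 0.6
  v[3, 4] <- v[4, 3] <- 0.2
  diag(v) <- 1
  sim <- makeSim(v)
  a <- randomAssoc(4, 3, seed = 1)
  rownames(a) <- rownames(sim)
  X <- statisticalProfile(a, SimilarityMatrix(sim), "mirna")

  expect_equal(dim(X), c(18L, 4L))
  expect_equal(X["n.obs", 1], unname(rowSums(a)[1]))
  expect_equal(X["min.sim", 1], 0.3)
  expect_equal(X["max.sim", 1], 1.0)
  expect_equal(X["median.sim", 1], 0.5)
  expect_equal(X["ave.sim", 1], 0.6)
  expect_equal(X["s.d.sim", 1], sd(c(0.5, 0.3, 1.0)))
  q <- quantile(c(0.5, 0.3, 1.0), c(0.25, 0.75), names = FALSE)
  expect_equal(unname(X[c("first.q.sim", "third.q.sim"), 1]), q)
  # histogram: one value each in bins 4 (0.3), 6 (0.5) and 10 (1.0)
  hist1 <- X[paste0("hist.sim.", 1:10), 1]
  expect_equal(unname(hist1[c(4, 6, 10)]), rep(1 / 3, 3))
  expect_equal(sum(hist1), 1)
})

test_that("degenerate similarity rows give zero spread and histogram mass one", {
  v <- matrix(0.4, 3, 3)
  diag(v) <- 1
  sim <- makeSim(v)
  a <- randomAssoc(3, 4, seed = 2)
  rownames(a) <- rownames(sim)
  X <- statisticalProfile(a, SimilarityMatrix(sim), "mirna")
  expect_equal(unname(X["s.d.sim", ]), rep(0, 3))
  expect_equal(unname(X["min.sim", ]), unname(X["max.sim", ]))
  expect_equal(unname(X["median.sim", 1]), 0.4)

  a0 <- a
  a0[2, ] <- 0
  expect_equal(unname(statisticalProfile(a0, SimilarityMatrix(sim), "mirna")["n.obs", 2]), 0)

  expect_error(statisticalProfile(a[1, , drop = FALSE],
                                  SimilarityMatrix(matrix(1, 1, 1, dimnames = list("e01", "e01"))),
                                  "mirna"), "at least 2")
})

test_that("histogram rows are proportions summing to one on random inputs", {
  for (s in 1:10) {
    n <- sample(3:12, 1)
    sim <- randomSim(n, seed = s)
    a <- randomAssoc(n, 5, seed = s)
    rownames(a) <- rownames(sim)
    X <- statisticalProfile(a, SimilarityMatrix(sim), "mirna")
    hs <- colSums(X[paste0("hist.sim.", 1:10), , drop = FALSE])
    expect_equal(unname(hs), rep(1, n), tolerance = 1e-12)
  }
})

test_that("unweighted graph thresholds at the global mean, strictly", {
  expect_equal(sum(unweightedGraph(makeSim(matrix(0.5, 4, 4)))), 0)
  # diag-1, off-diag 0 at n = 3: mean 1/3 > 0, no edges
  expect_equal(sum(unweightedGraph(makeSim(diag(3)))), 0)
  # brute-force check on random matrices
  for (s in 1:5) {
    v <- randomSim(6, seed = 20 + s)
    adj <- unweightedGraph(SimilarityMatrix(v))
    m <- mean(v)
    for (i in 1:6) for (j in 1:6) {
      expect_identical(adj[i, j], as.numeric(i != j && v[i, j] > m))
    }
  }
})

test_that("graph profile centralities match known small graphs", {
  # star: center-leaf 0.8 above the mean, leaf-leaf 0.1 below
  v <- matrix(0.1, 4, 4)
  v[1, 2:4] <- v[2:4, 1] <- 0.8
  diag(v) <- 1
  sim <- makeSim(v)
  a <- randomAssoc(4, 3, seed = 3)
  rownames(a) <- rownames(sim)
  stat <- statisticalProfile(a, SimilarityMatrix(sim), "mirna")
  X <- graphProfile(SimilarityMatrix(sim), stat, k = 2)

  expect_equal(nrow(X), 1 + 2 + 18 + 18 + 4)
  expect_equal(unname(X["num.nb", ]), c(3, 1, 1, 1))
  expect_equal(unname(X["bt", ]), c(3, 0, 0, 0)) # unnormalized pair counts
  expect_equal(unname(X["cl", 1]), 1 / 3) # distance 1 to each leaf
  expect_gt(X["pr", 1], X["pr", 2])
  expect_equal(X["ev", 1], 1) # dominant eigenvector peaks at the hub
})

test_that("symmetric components give uniform PageRank and zero betweenness", {
  # two disjoint triangles
  v <- matrix(0.1, 6, 6)
  v[1:3, 1:3] <- 0.9
  v[4:6, 4:6] <- 0.9
  diag(v) <- 1
  sim <- makeSim(v)
  a <- randomAssoc(6, 3, seed = 4)
  rownames(a) <- rownames(sim)
  stat <- statisticalProfile(a, SimilarityMatrix(sim), "mirna")
  X <- graphProfile(SimilarityMatrix(sim), stat, k = 3)
  expect_equal(unname(X["bt", ]), rep(0, 6))
  expect_equal(unname(X["pr", ]), rep(1 / 6, 6), tolerance = 1e-6)
  expect_equal(unname(X["cl", ]), rep(1 / 2, 6)) # within-component closeness
})

test_that("isolated nodes get zero centralities and uniform PageRank", {
  sim <- makeSim(diag(3)) # no edges at all
  a <- randomAssoc(3, 3, seed = 5)
  rownames(a) <- rownames(sim)
  stat <- statisticalProfile(a, SimilarityMatrix(sim), "mirna")
  X <- graphProfile(SimilarityMatrix(sim), stat, k = 2)
  expect_equal(unname(X["num.nb", ]), rep(0, 3))
  expect_equal(unname(X["bt", ]), rep(0, 3))
  expect_equal(unname(X["cl", ]), rep(0, 3))
  expect_equal(unname(X["ev", ]), rep(0, 3))
  expect_equal(unname(X["pr", ]), rep(1 / 3, 3))
})

test_that("neighbor features use similarity ranking with zero padding", {
  v <- randomSim(3, seed = 6)
  a <- randomAssoc(3, 4, seed = 6)
  rownames(a) <- rownames(v)
  stat <- statisticalProfile(a, SimilarityMatrix(v), "mirna")
  X <- graphProfile(SimilarityMatrix(v), stat, k = 10)
  # only 2 other entities: k.sim descending then zero-padded to 10
  ks <- X[paste0("k.sim.", 1:10), 1]
  expect_equal(unname(ks[1:2]), unname(sort(v[1, 2:3], decreasing = TRUE)))
  expect_equal(unname(ks[3:10]), rep(0, 8))
})

test_that("weighted and plain neighbor averages agree for equal similarities", {
  v <- matrix(0.6, 4, 4)
  v[1, 2] <- v[2, 1] <- 0.6
  diag(v) <- 1
  sim <- makeSim(v)
  a <- randomAssoc(4, 3, seed = 7)
  rownames(a) <- rownames(sim)
  stat <- statisticalProfile(a, SimilarityMatrix(sim), "mirna")
  X <- graphProfile(SimilarityMatrix(sim), stat, k = 3)
  expect_equal(X[paste0("k.ave.", rownames(stat)), ],
               X[paste0("k.w.ave.", rownames(stat)), ],
               ignore_attr = TRUE)
})

test_that("feature scaling maps min to 0 and max to 1, constants to 0", {
  X <- rbind(a = c(2, 4, 6), b = c(1, 1, 1), c = c(0, 0.5, 0.25))
  S <- scaleFeatures(X)
  expect_equal(unname(S["a", ]), c(0, 0.5, 1))
  expect_equal(unname(S["b", ]), c(0, 0, 0))
  expect_equal(range(S["c", ]), c(0, 1))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("entity permutation permutes profile columns identically", {
  n <- 7
  sim <- randomSim(n, seed = 8)
  a <- randomAssoc(n, 5, seed = 8)
  rownames(a) <- rownames(sim)
  X <- statisticalProfile(a, SimilarityMatrix(sim), "mirna")
  perm <- sample(n)
  simP <- sim[perm, perm]
  aP <- a[perm, ]
  XP <- statisticalProfile(aP, SimilarityMatrix(simP), "mirna")
  expect_equal(XP, X[, perm])

  G <- graphProfile(SimilarityMatrix(sim), X, k = 3)
  GP <- graphProfile(SimilarityMatrix(simP), XP, k = 3)
  expect_equal(GP, G[, perm], tolerance = 1e-9)
})

test_that("disease side summarizes columns of the association matrix", {
  a <- randomAssoc(5, 4, seed = 9)
  sim <- randomSim(4, seed = 9, names = colnames(a))
  X <- statisticalProfile(a, SimilarityMatrix(sim), "disease")
  expect_equal(unname(X["n.obs", ]), unname(colSums(a)))
  expect_identical(colnames(X), colnames(a))
})
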