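test_that("semantic value sums per-term contributions", {
  # ubiquitous term contributes -log(1) = 0
  dag <- DiseaseDAG("A", c("A", "R"), cbind("A", "R"))
  sv <- semanticValue(dag, c(A = 2, R = 2), 2)
  expect_equal(unname(sv$contribution), c(0, 0))
  expect_equal(sv$DV, 0)

  # DAG {A, R} among 2 diseases with A private: DV = log 2
  sv2 <- semanticValue(dag, c(A = 1, R = 2), 2)
  expect_equal(unname(sv2$contribution[["A"]]), log(2))
  expect_equal(sv2$DV, log(2))

  # three private terms among 8 diseases: DV = 3 log 8
  dag3 <- DiseaseDAG("X", c("X", "p1", "p2"),
                     rbind(c("X", "p1"), c("p1", "p2")))
  sv3 <- semanticValue(dag3, c(X = 1, p1 = 1, p2 = 1), 8)
  expect_equal(sv3$DV, 3 * log(8))

  expect_error(semanticValue(dag, c(A = 3, R = 2), 2), "exceeds")
})

test_that("semantic similarity follows DAG overlap", {
  a <- DiseaseDAG("A", c("A", "R"), cbind("A", "R"))
  b <- DiseaseDAG("B", c("B", "R"), cbind("B", "R"))
  ss <- as.matrix(semanticSimilarity(list(a, b)))
  expect_equal(diag(ss), c(A = 1, B = 1)) # identical DAG with itself
  # shared node R is ubiquitous (contribution 0), so SS(A, B) = 0
  expect_equal(ss["A", "B"], 0)

  # disjoint DAGs have similarity 0
  c1 <- DiseaseDAG("C", c("C", "S"), cbind("C", "S"))
  ss2 <- as.matrix(semanticSimilarity(list(a, b, c1)))
  expect_equal(ss2["A", "C"], 0)

  # partially shared, non-ubiquitous ancestor gives similarity in (0, 1)
  d1 <- DiseaseDAG("D1", c("D1", "P", "R"), rbind(c("D1", "P"), c("P", "R")))
  d2 <- DiseaseDAG("D2", c("D2", "P", "R"), rbind(c("D2", "P"), c("P", "R")))
  d3 <- DiseaseDAG("D3", c("D3", "R"), cbind("D3", "R"))
  ss3 <- as.matrix(semanticSimilarity(list(d1, d2, d3)))
  # P has membership 2/3: shared contribution log(3/2) from each side,
  # R contributes 0; DV_i = log 3 + log(3/2)
  expect_equal(ss3["D1", "D2"], 2 * log(3 / 2) / (2 * (log(3) + log(3 / 2))))
  expect_gt(ss3["D1", "D2"], ss3["D1", "D3"])
})

test_that("semantic similarity matches an independent oracle and is log-base invariant", {
  set.seed(8)
  pool <- sprintf("t%02d", 1:12)
  dags <- lapply(1:6, function(i) {
    anc <- sample(pool, sample(2:5, 1))
    own <- sprintf("own%d", i)
    chain <- c(own, anc)
    DiseaseDAG(sprintf("D%d", i), chain,
               cbind(chain[-length(chain)], chain[-1]))
  })
  got <- as.matrix(semanticSimilarity(dags))
  expect_equal(unname(got), bruteSemanticSim(dags), tolerance = 1e-12)
  # base-2 logs rescale numerator and denominator identically
  expect_equal(unname(got), bruteSemanticSim(dags, base = 2), tolerance = 1e-12)
  expect_true(isSymmetric(got))
})

test_that("adding a shared non-ubiquitous ancestor never decreases similarity", {
  base <- list(
    DiseaseDAG("A", c("A", "R"), cbind("A", "R")),
    DiseaseDAG("B", c("B", "R"), cbind("B", "R")),
    DiseaseDAG("C", c("C", "R"), cbind("C", "R")))
  before <- as.matrix(semanticSimilarity(base))["A", "B"]
  richer <- list(
    DiseaseDAG("A", c("A", "S", "R"), rbind(c("A", "S"), c("S", "R"))),
    DiseaseDAG("B", c("B", "S", "R"), rbind(c("B", "S"), c("S", "R"))),
    base[[3]])
  after <- as.matrix(semanticSimilarity(richer))["A", "B"]
  expect_gte(after, before)
})

test_that("all-ubiquitous DAGs are flagged undefined with a warning", {
  # single disease: its own term has membership 1 = nTotal, DV = 0
  solo <- DiseaseDAG("A", "A")
  expect_warning(ss <- semanticSimilarity(list(solo)), "undefined")
  expect_true(is.na(as.matrix(ss)[1, 1]))
})

test_that("Gaussian kernel matches hand evaluation and is PSD", {
  ip <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), NULL))
  k <- as.matrix(gaussianKernel(ip))
  # mean squared norm 1 -> gamma 1; distance^2 = 2
  expect_equal(k["m1", "m2"], exp(-2))
  expect_equal(diag(k), c(m1 = 1, m2 = 1))

  dup <- matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(as.matrix(gaussianKernel(dup))["a", "b"], 1)

  set.seed(9)
  for (rep in 1:5) {
    p <- matrix(rbinom(12 * 7, 1, 0.4), 12)
    if (all(p == 0)) p[1, 1] <- 1
    rownames(p) <- sprintf("x%02d", 1:12)
    km <- as.matrix(gaussianKernel(p))
    expect_true(isSymmetric(km))
    expect_true(all(km > 0 & km <= 1 + 1e-12))
    expect_gte(min(eigen(km, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }

  expect_error(gaussianKernel(matrix(0, 3, 2)), "bandwidth undefined")
  # gammaPrime scales the bandwidth
  k2 <- as.matrix(gaussianKernel(ip, gammaPrime = 2))
  expect_equal(k2["m1", "m2"], exp(-4))
})

test_that("integration prefers the primary source and falls back elsewhere", {
  n <- 4
  fall <- randomSim(n, seed = 10)
  prim <- matrix(NA_real_, n, n, dimnames = dimnames(fall))
  diag(prim) <- 1
  prim[1, 2] <- prim[2, 1] <- 0.77

  out <- as.matrix(integrateSimilarity(SimilarityMatrix(prim), SimilarityMatrix(fall)))
  expect_equal(out[1, 2], 0.77)
  expect_equal(out[1, 3], fall[1, 3])
  expect_false(anyNA(out))
  expect_true(all(out >= 0 & out <= 1))

  # fully defined primary wins everywhere
  full <- randomSim(n, seed = 11)
  dimnames(full) <- dimnames(fall)
  expect_equal(as.matrix(integrateSimilarity(SimilarityMatrix(full),
                                             SimilarityMatrix(fall))), full)
  # empty primary returns the fallback
  none <- matrix(NA_real_, n, n, dimnames = dimnames(fall))
  expect_equal(as.matrix(integrateSimilarity(SimilarityMatrix(none),
                                             SimilarityMatrix(fall))), fall)

  wrong <- randomSim(n, seed = 12, names = sprintf("z%d", 1:n))
  expect_error(integrateSimilarity(SimilarityMatrix(wrong), SimilarityMatrix(fall)),
               "do not match")
})

test_that("alignment expands a similarity onto the association index", {
  v <- randomSim(3, seed = 13, names = c("m1", "m9", "m2"))
  expect_warning(out <- alignSimilarity(SimilarityMatrix(v), c("m1", "m2", "m3")),
                 "m9")
  o <- as.matrix(out)
  expect_equal(o["m1", "m2"], v["m1", "m2"])
  expect_true(all(is.na(o["m3", ])))
})
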