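#' Configuration of the synthetic association generator
#'
#' The generator plants exactly the signal the model assumes: miRNAs and
#' diseases fall into matched clusters and associations are `boost` times
#' more likely within a matched cluster. Cluster sizes are heavy-tailed
#' (each cluster about half the previous one) and each cluster has its own
#' internal similarity tightness, mimicking real miRNA families and MeSH
#' branches, whose sizes and cohesion vary widely; both properties are what
#' make the similarity distribution of an entity informative about its
#' cluster. The functional similarity is raised for same-cluster miRNA
#' pairs by `fsBonus` times the cluster tightness (plus Gaussian noise,
#' clipped to `[0, 1]`), and is defined only on a random `fsCoverage`
#' fraction of pairs so the kernel fallback is exercised. Disease DAGs
#' share a per-cluster ancestor backbone, so the semantic similarity is
#' high within clusters (at a cluster-size-dependent level) and zero
#' across. A fraction of the true positives is withheld as ground truth
#' for recovery experiments.
#'
#' @param nm,nd numbers of miRNAs and diseases.
#' @param nClusters number of matched miRNA/disease clusters.
#' @param density target fraction of pairs labelled 1 (before holdout).
#' @param boost within-cluster association probability multiplier, >= 1.
#' @param fsBase,fsBonus baseline functional similarity and same-cluster
#'   increment.
#' @param fsNoise standard deviation of the similarity noise.
#' @param fsCoverage fraction of miRNA pairs with a defined functional
#'   similarity value, in `[0, 1]`.
#' @param dagDepth number of shared backbone terms per disease cluster.
#' @param heldOut fraction of the generated positives withheld as ground
#'   truth.
#' @param seed integer seed.
#' @return A named list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nm = 60, nd = 40, nClusters = 3, density = 0.05,
                            boost = 6, fsBase = 0.2, fsBonus = 0.5,
                            fsNoise = 0.05, fsCoverage = 0.6, dagDepth = 3,
                            heldOut = 0.15, seed = 1) {
  stopifnot(density > 0, density < 1, boost >= 1,
            fsCoverage >= 0, fsCoverage <= 1, heldOut >= 0, heldOut < 1,
            nClusters >= 1, dagDepth >= 1)
  structure(list(nm = nm, nd = nd, nClusters = nClusters, density = density,
                 boost = boost, fsBase = fsBase, fsBonus = fsBonus,
                 fsNoise = fsNoise, fsCoverage = fsCoverage,
                 dagDepth = dagDepth, heldOut = heldOut, seed = seed),
            class = "syntheticConfig")
}

#' Named presets of the synthetic generator
#'
#' `"small"` is the 60 x 40, three-cluster, easy-signal regime used
#' throughout the validation experiments; `"tiny"` (16 x 12) is for fast
#' examples and unit tests; `"hmdd-like"` mimics the shape and sparsity of
#' the curated human dataset (495 miRNAs, 383 diseases, 2.86% density).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A `syntheticConfig` list.
#' @export
syntheticPreset <- function(name = c("small", "tiny", "hmdd-like"), seed = 1) {
  switch(match.arg(name),
    "small" = syntheticConfig(seed = seed),
    "tiny" = syntheticConfig(nm = 16, nd = 12, nClusters = 2, density = 0.12,
                             boost = 4, fsCoverage = 0.7, dagDepth = 2,
                             heldOut = 0.15, seed = seed),
    "hmdd-like" = syntheticConfig(nm = 495, nd = 383, nClusters = 8,
                                  density = 0.0286, boost = 6,
                                  fsCoverage = 0.6, dagDepth = 4, seed = seed))
}

#' Generate a synthetic miRNA-disease dataset
#'
#' Draws a dataset under the block-structured generative model described in
#' [syntheticConfig()]. The within/between association probabilities are
#' solved from the target density and the boost; an unreachable density
#' (boosted probability above 1) is an error stating the feasible range.
#'
#' @param config a [syntheticConfig()] (or preset) list.
#' @return A list of class `lrsslSyntheticData` with elements `assoc`
#'   (visible [AssociationMatrix-class]), `fs` (partial
#'   [SimilarityMatrix-class]), `dags` (list of [DiseaseDAG-class]),
#'   `heldOut` (two-column matrix of withheld positive name pairs),
#'   `mirCluster`, `disCluster`, and `config`.
#' @export
simulateMDA <- function(config = syntheticConfig()) {
  cf <- config
  withSeed(cf$seed, {
    mirNames <- sprintf("hsa-mir-%03d", seq_len(cf$nm))
    disNames <- sprintf("disease-%03d", seq_len(cf$nd))
    K <- cf$nClusters
    # heavy-tailed cluster sizes (each cluster half the previous), as in
    # real miRNA families / disease branches
    props <- 2^((K - 1):0) / sum(2^((K - 1):0))
    mirCluster <- sort(sample(K, cf$nm, replace = TRUE, prob = props))
    disCluster <- sort(sample(K, cf$nd, replace = TRUE, prob = props))
    # guarantee every cluster is populated on both sides
    mirCluster[seq_len(K)] <- seq_len(K)
    disCluster[seq_len(K)] <- seq_len(K)
    mirCluster <- sample(mirCluster)
    disCluster <- sample(disCluster)
    # per-cluster within-cluster similarity level: families differ in
    # internal tightness, which is what makes the similarity histograms
    # cluster-specific
    tightness <- 1 - 0.6 * (seq_len(K) - 1) / max(1, K - 1)
    same <- outer(mirCluster, disCluster, "==")
    fWithin <- mean(same)
    pOut <- cf$density / (fWithin * cf$boost + (1 - fWithin))
    pIn <- cf$boost * pOut
    if (pIn > 1) {
      stop(sprintf(
        "density %.3f unreachable with boost %.1f: need density <= %.3f",
        cf$density, cf$boost, (fWithin * cf$boost + 1 - fWithin) / cf$boost),
        call. = FALSE)
    }
    prob <- ifelse(same, pIn, pOut)
    A <- matrix(stats::rbinom(cf$nm * cf$nd, 1, prob), cf$nm, cf$nd,
                dimnames = list(mirNames, disNames))

    ones <- which(A == 1)
    nHold <- floor(cf$heldOut * length(ones))
    heldIdx <- if (nHold > 0) sample(ones, nHold) else integer(0)
    A[heldIdx] <- 0
    hij <- arrayInd(heldIdx, dim(A))
    heldOut <- cbind(miRNA = mirNames[hij[, 1]], disease = disNames[hij[, 2]])

    sameM <- outer(mirCluster, mirCluster, "==")
    fs <- cf$fsBase + cf$fsBonus * sameM * tightness[mirCluster[row(sameM)]] +
      matrix(stats::rnorm(cf$nm^2, sd = cf$fsNoise), cf$nm)
    fs[lower.tri(fs)] <- t(fs)[lower.tri(fs)]
    fs <- pmin(pmax(fs, 0), 1)
    diag(fs) <- 1
    defined <- matrix(FALSE, cf$nm, cf$nm)
    defined[upper.tri(defined)] <- stats::runif(cf$nm * (cf$nm - 1) / 2) < cf$fsCoverage
    defined <- defined | t(defined)
    diag(defined) <- TRUE
    fs[!defined] <- NA
    dimnames(fs) <- list(mirNames, mirNames)

    dags <- lapply(seq_len(cf$nd), function(j) {
      cl <- disCluster[j]
      backbone <- sprintf("C%d-L%d", cl, seq_len(cf$dagDepth))
      own <- sprintf("T-%s", disNames[j])
      nodes <- c(own, backbone)
      edges <- rbind(cbind(own, backbone[cf$dagDepth]),
                     if (cf$dagDepth > 1) {
                       cbind(backbone[2:cf$dagDepth], backbone[1:(cf$dagDepth - 1)])
                     })
      DiseaseDAG(disNames[j], nodes, edges)
    })
    names(dags) <- disNames

    structure(list(assoc = AssociationMatrix(A), fs = SimilarityMatrix(fs),
                   dags = dags, heldOut = heldOut,
                   mirCluster = stats::setNames(mirCluster, mirNames),
                   disCluster = stats::setNames(disCluster, disNames),
                   config = cf),
              class = "lrsslSyntheticData")
  })
}

#' @export
print.lrsslSyntheticData <- function(x, ...) {
  a <- as.matrix(x$assoc)
  cat(sprintf(
    "synthetic dataset: %d x %d, %d visible + %d held-out associations, %d clusters\n",
    nrow(a), ncol(a), sum(a), nrow(x$heldOut), x$config$nClusters))
  invisible(x)
}

#' Held-out-positive recovery experiment
#'
#' Trains on a synthetic dataset's visible associations and ranks the
#' withheld true positives against the true negatives (pairs labelled 0 in
#' both the visible matrix and the ground truth), reporting the pooled AUC
#' and the per-disease top-`top` hit counts. With `permuteLabels = TRUE`
#' the visible 1s are scattered to uniformly random positions before
#' training, which calibrates the null: recovery should then sit at an AUC
#' near 0.5.
#'
#' @param data an `lrsslSyntheticData` object from [simulateMDA()], or a
#'   [syntheticConfig()] to generate one.
#' @param control an [lrsslControl()] list.
#' @param permuteLabels scatter the training labels before fitting.
#' @param top list length for the per-disease hit report.
#' @return A list with `auc`, per-pair `ranks`, `candidates`, `topHits`
#'   (named per-disease counts of held-out positives in the top `top`
#'   candidates), and the trained `result`.
#' @export
recoveryHarness <- function(data, control = lrsslControl(),
                            permuteLabels = FALSE, top = 50) {
  if (inherits(data, "syntheticConfig")) data <- simulateMDA(data)
  stopifnot(inherits(data, "lrsslSyntheticData"))
  if (!nrow(data$heldOut)) stop("no held-out ground truth pairs", call. = FALSE)
  A <- as.matrix(data$assoc)
  heldIdx <- cbind(match(data$heldOut[, 1], rownames(A)),
                   match(data$heldOut[, 2], colnames(A)))
  Atrain <- A
  if (permuteLabels) {
    Atrain[] <- 0
    Atrain[withSeed(data$config$seed + 1L, sample(length(A), sum(A)))] <- 1
  }
  res <- lrsslmda(AssociationMatrix(Atrain), fs = data$fs, dags = data$dags,
                  control = control)
  S <- as.matrix(predictedScores(res))
  truth <- matrix(0, nrow(A), ncol(A))
  truth[heldIdx] <- 1
  negIdx <- which(A == 0 & truth == 0)
  ranks <- vapply(seq_len(nrow(heldIdx)), function(r) {
    .rankAmong(S[heldIdx[r, 1], heldIdx[r, 2]], S[negIdx])
  }, 0)
  auc <- rocAuc(ranks, rep(length(negIdx), length(ranks)))$auc
  topHits <- vapply(unique(data$heldOut[, 2]), function(d) {
    lst <- rankCandidates(S, Atrain, d, top = top)
    sum(lst$miRNA %in% data$heldOut[data$heldOut[, 2] == d, 1])
  }, 0L)
  list(auc = auc, ranks = ranks, candidates = length(negIdx),
       topHits = topHits, result = res)
}

#' New-disease prediction protocol
#'
#' Removes every known miRNA of one disease from the training matrix (the
#' way a disease without any known association would present), refits, and
#' checks two things: that the final scores for that disease column equal
#' the disease-perspective scores exactly (the second prediction scenario),
#' and how well the removed true miRNAs are recovered, as a pooled AUC of
#' their ranks among the disease's other miRNAs.
#'
#' @param data an `lrsslSyntheticData` object or a [syntheticConfig()].
#' @param disease disease name; defaults to the visible disease with the
#'   most known associations.
#' @param control an [lrsslControl()] list.
#' @return A list with `disease`, `columnMatchesDiseasePerspective`
#'   (logical), `auc`, `ranks`, `removed` (the miRNA names taken out), and
#'   the refit `result`.
#' @export
newDiseaseEvaluation <- function(data, disease = NULL,
                                 control = lrsslControl()) {
  if (inherits(data, "syntheticConfig")) data <- simulateMDA(data)
  A <- as.matrix(data$assoc)
  if (is.null(disease)) disease <- colnames(A)[which.max(colSums(A))]
  if (!disease %in% colnames(A)) stop(sprintf("unknown disease '%s'", disease), call. = FALSE)
  removed <- rownames(A)[A[, disease] == 1]
  if (!length(removed)) stop("disease has no known associations to remove", call. = FALSE)
  Atr <- A
  Atr[, disease] <- 0
  res <- lrsslmda(AssociationMatrix(Atr), fs = data$fs, dags = data$dags,
                  control = control)
  S <- as.matrix(predictedScores(res))
  SD <- as.matrix(predictedScores(res, "disease"))
  colMatch <- identical(S[, disease], SD[, disease])
  negM <- setdiff(rownames(A)[A[, disease] == 0], removed)
  ranks <- vapply(removed, function(m) {
    .rankAmong(S[m, disease], S[negM, disease])
  }, 0)
  auc <- rocAuc(ranks, rep(length(negM), length(ranks)))$auc
  list(disease = disease, columnMatchesDiseasePerspective = colMatch,
       auc = auc, ranks = ranks, removed = removed, result = res)
}
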