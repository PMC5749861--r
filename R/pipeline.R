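# Core pipeline shared by lrsslmda() and the cross-validation loops.
# `fsValues` / `ssValues` are similarity matrices already aligned onto the
# association index (NA where the source is undefined) or NULL; they are
# NOT recomputed per CV round since they do not depend on the association
# matrix, whereas the interaction-profile kernels are rebuilt from the
# (possibly masked) training matrix to avoid label leakage.
.lrsslCore <- function(A, fsValues = NULL, ssValues = NULL,
                       control = lrsslControl(), renormalizeAlpha = FALSE) {
  KM <- gaussianKernel(A, gammaPrime = control$gammaPrime)@values
  KD <- gaussianKernel(t(A), gammaPrime = control$gammaPrime)@values
  SM <- if (is.null(fsValues)) KM else {
    v <- fsValues
    v[is.na(v)] <- KM[is.na(v)]
    v
  }
  SD <- if (is.null(ssValues)) KD else {
    v <- ssValues
    v[is.na(v)] <- KD[is.na(v)]
    v
  }
  simM <- SimilarityMatrix(SM)
  simD <- SimilarityMatrix(SD)

  sides <- list()
  for (side in c("mirna", "disease")) {
    Ys <- if (side == "mirna") A else t(A)
    sim <- if (side == "mirna") simM else simD
    other <- if (side == "mirna") simD else simM
    X <- featureProfiles(A, sim, side, bins = control$bins, k = control$kFeatures)
    L1 <- knnProfileGraph(X$raw1, k = control$kGraph)
    L2 <- knnProfileGraph(X$raw2, k = control$kGraph)
    LA <- knnAssociationGraph(Ys, other, k = control$kGraph)
    fit <- fitLRSSL(X[c("X1", "X2")], Ys, list(L1$L, L2$L, LA$L), control,
                    side = side)
    sides[[side]] <- list(X = X, fit = fit,
                          scores = perspectiveScores(fit, X[c("X1", "X2")],
                                                     renormalizeAlpha))
  }
  sMir <- sides$mirna$scores
  sDis <- t(sides$disease$scores) # back into miRNA-by-disease orientation
  dimnames(sMir) <- dimnames(A)
  dimnames(sDis) <- dimnames(A)
  final <- combineScores(sMir, sDis, A)
  list(SM = simM, SD = simD, sides = sides,
       scores = list(mirna = sMir, disease = sDis, final = final))
}

# Align optional external similarities onto the association index once.
.alignedInputs <- function(A, fs = NULL, dags = NULL, ss = NULL) {
  fsValues <- NULL
  if (!is.null(fs)) {
    fsValues <- alignSimilarity(fs, rownames(A))@values
  }
  ssValues <- NULL
  if (!is.null(ss)) {
    ssValues <- alignSimilarity(ss, colnames(A), warnUnmatched = FALSE)@values
  } else if (!is.null(dags)) {
    ssValues <- alignSimilarity(semanticSimilarity(dags), colnames(A))@values
  }
  list(fs = fsValues, ss = ssValues)
}

#' Predict miRNA-disease association scores
#'
#' Runs the full pipeline on a training association matrix: Gaussian
#' interaction-profile kernels for both sides, integration with the miRNA
#' functional similarity and the DAG-derived disease semantic similarity
#' where those define a pair, feature extraction, kNN graph Laplacians, one
#' subspace-learning fit per side, and the three-scenario combination of
#' the two perspectives.
#'
#' @param assoc an [AssociationMatrix-class] (or 0/1 matrix with dimnames).
#' @param fs optional miRNA functional [SimilarityMatrix-class]; pairs it
#'   does not define fall back to the kernel. Entities are matched to the
#'   association index on exact names; unmatched ones are reported.
#' @param dags optional list of [DiseaseDAG-class] objects from which the
#'   disease semantic similarity is computed.
#' @param control an [lrsslControl()] list.
#' @param ss optional precomputed disease semantic similarity, overriding
#'   `dags`.
#' @param renormalizeAlpha divide the two profile weights by their sum in
#'   the per-perspective scores (sensitivity analysis; the printed
#'   combination leaves the association-graph weight out without
#'   renormalizing).
#' @return An [LRSSLResult-class].
#' @examples
#' set.seed(1)
#' sim <- simulateMDA(syntheticPreset("tiny"))
#' res <- lrsslmda(sim$assoc, fs = sim$fs, dags = sim$dags,
#'                 control = lrsslControl(maxIter = 50))
#' predictedScores(res)
#' @export
lrsslmda <- function(assoc, fs = NULL, dags = NULL, control = lrsslControl(),
                     ss = NULL, renormalizeAlpha = FALSE) {
  A <- .asAssocMatrix(assoc)
  ext <- .alignedInputs(A, fs, dags, ss)
  core <- .lrsslCore(A, ext$fs, ext$ss, control, renormalizeAlpha)
  new("LRSSLResult",
      assoc = AssociationMatrix(A), SM = core$SM, SD = core$SD,
      fits = list(mirna = core$sides$mirna$fit,
                  disease = core$sides$disease$fit),
      scores = list(
        mirna = ScoreMatrix(core$scores$mirna, "mirna-perspective"),
        disease = ScoreMatrix(core$scores$disease, "disease-perspective"),
        final = ScoreMatrix(core$scores$final, "final")))
}
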