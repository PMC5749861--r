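#' Per-perspective association scores
#'
#' Combines the fitted projections into this side's score matrix:
#' `sum_p alpha_p * rownormalize(X_p' G_p)`, where row normalization
#' divides each entity's row by its sum (all-zero rows stay zero). Only the
#' two profile weights enter; the association-graph weight is not part of
#' the printed combination, so rows carry total mass `alpha_1 + alpha_2 < 1`
#' unless `renormalizeAlpha` is set (exposed for sensitivity analysis).
#'
#' @param fit an [LRSSLFit-class].
#' @param X the list of feature matrices the fit was trained on.
#' @param renormalizeAlpha divide the two profile weights by their sum.
#' @return An n-by-t nonnegative score matrix in this side's orientation.
#' @export
perspectiveScores <- function(fit, X, renormalizeAlpha = FALSE) {
  m <- length(fit@G)
  a <- fit@alpha[seq_len(m)]
  if (renormalizeAlpha) a <- a / sum(a)
  out <- 0
  for (p in seq_len(m)) {
    proj <- crossprod(as.matrix(X[[p]]), fit@G[[p]])
    if (any(proj < -1e-12)) stop("negative entries in X_p' G_p", call. = FALSE)
    proj[proj < 0] <- 0
    out <- out + a[p] * rowNormalize(proj)
  }
  out
}

#' Combine the two perspectives under the three prediction scenarios
#'
#' For a miRNA without any known associated disease the miRNA-perspective
#' score is used; for a disease without any known associated miRNA, the
#' disease-perspective score; otherwise the average of the two. A pair
#' where both sides are new is not covered by the three cases; the
#' miRNA-perspective clause (first in document order) applies, with a
#' warning.
#'
#' @param mirnaScores miRNA-perspective score matrix (miRNA rows by disease
#'   columns).
#' @param diseaseScores disease-perspective score matrix, same orientation.
#' @param assoc the training [AssociationMatrix-class].
#' @return The final score matrix, miRNA rows by disease columns.
#' @export
combineScores <- function(mirnaScores, diseaseScores, assoc) {
  a <- .asAssocMatrix(assoc)
  sM <- as.matrix(mirnaScores)
  sD <- as.matrix(diseaseScores)
  stopifnot(identical(dim(sM), dim(a)), identical(dim(sD), dim(a)))
  newMir <- rowSums(a) == 0
  newDis <- colSums(a) == 0
  out <- (sM + sD) / 2
  out[, newDis] <- sD[, newDis]
  out[newMir, ] <- sM[newMir, ] # also resolves both-new pairs
  if (any(newMir) && any(newDis)) {
    warning("pairs where both the miRNA and the disease are new: miRNA-perspective scores used")
  }
  dimnames(out) <- dimnames(a)
  out
}

#' Rank candidate miRNAs for one disease
#'
#' Orders the miRNAs not known to be associated with the disease by
#' descending predicted score (ties broken by ascending miRNA index) and
#' returns the top of the list.
#'
#' @param scores a [ScoreMatrix-class] or score matrix.
#' @param assoc the training [AssociationMatrix-class].
#' @param disease disease name.
#' @param top number of candidates to return; larger than the candidate
#'   count returns the full list.
#' @return A data frame with columns `rank`, `miRNA`, `score`.
#' @export
rankCandidates <- function(scores, assoc, disease, top = 50) {
  s <- if (is(scores, "ScoreMatrix")) scores@scores else as.matrix(scores)
  a <- .asAssocMatrix(assoc)
  if (!disease %in% colnames(a)) {
    stop(sprintf("unknown disease '%s'", disease), call. = FALSE)
  }
  cand <- which(a[, disease] == 0)
  ord <- cand[order(-s[cand, disease], cand)]
  ord <- ord[seq_len(min(top, length(ord)))]
  data.frame(rank = seq_along(ord), miRNA = rownames(a)[ord],
             score = s[ord, disease], row.names = NULL)
}
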