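# Mid-rank of a test score among candidate scores: 1 + #better + ties/2.
.rankAmong <- function(testScore, candidateScores) {
  1 + sum(candidateScores > testScore) + 0.5 * sum(candidateScores == testScore)
}

#' ROC curve and AUC from pooled test-sample ranks
#'
#' Pools all validation rounds, each contributing the held-out sample's
#' rank among its candidates, and sweeps rank thresholds: at threshold `t`
#' the true positive rate is the fraction of test samples ranked at or
#' above `t`, and the false positive rate is the fraction of all candidates
#' occupying a position at or above `t`. The AUC is the trapezoidal area;
#' for a single test ranked `r` among `n` candidates it equals
#' `1 - (r - 1)/n`, and when rounds share a candidate set it coincides
#' with the Mann-Whitney statistic on the pooled scores. Ties with
#' candidates are assumed folded into mid-ranks.
#'
#' @param ranks numeric vector of test-sample ranks (1 = best; mid-ranks
#'   may be fractional).
#' @param counts integer vector of candidate counts per round.
#' @return A list with `auc` and the ROC polyline `roc` (data frame with
#'   `threshold`, `fpr`, `tpr`).
#' @export
rocAuc <- function(ranks, counts) {
  if (!length(ranks)) stop("no validation rounds supplied", call. = FALSE)
  stopifnot(length(ranks) == length(counts), all(counts >= 1),
            all(ranks >= 1), all(ranks <= counts + 1))
  thr <- sort(unique(c(0, seq_len(max(counts) + 1), ranks)))
  tpr <- vapply(thr, function(t) mean(ranks <= t), 0)
  fp <- vapply(thr, function(t) {
    sum(pmin(pmax(t - (ranks <= t), 0), counts))
  }, 0)
  fpr <- fp / sum(counts)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

# One masked refit returning the final score matrix; FS/SS stay fixed,
# kernels and everything downstream are recomputed from the masked matrix.
.maskedScores <- function(A, maskIdx, ext, control) {
  Atr <- A
  Atr[maskIdx] <- 0
  .lrsslCore(Atr, ext$fs, ext$ss, control)$scores$final
}

.newCV <- function(scheme, rounds, auc, roc, aucSd = NA_real_, perGroup = NULL) {
  structure(list(scheme = scheme, rounds = rounds, auc = auc, aucSd = aucSd,
                 roc = roc, perGroup = perGroup),
            class = "lrsslCV")
}

#' @export
print.lrsslCV <- function(x, ...) {
  cat(sprintf("%s: %d rounds, AUC = %.4f%s\n", x$scheme, nrow(x$rounds), x$auc,
              if (!is.na(x$aucSd)) sprintf(" +/- %.4f", x$aucSd) else ""))
  invisible(x)
}

#' Global leave-one-out cross validation
#'
#' Leaves each known association out in turn: the pair is zeroed in the
#' training matrix, the kernels, integrated similarities, features, graphs
#' and both model fits are recomputed from the masked matrix, and the
#' held-out pair is ranked against all pairs never labelled 1 in the full
#' data (the candidates). Ranks are pooled into a single ROC.
#'
#' @param assoc an [AssociationMatrix-class] (or 0/1 matrix with dimnames),
#'   with at least two known associations.
#' @param fs,dags optional external similarity inputs, as in [lrsslmda()];
#'   they do not depend on the association matrix and are not recomputed
#'   per round.
#' @param control an [lrsslControl()] list (its `seed` also drives the
#'   optional round subsampling).
#' @param rounds optional cap on the number of rounds: a seeded random
#'   subsample of the held-out pairs, for smoke-scale runs. The result is
#'   then an approximation of the full protocol.
#' @return An `lrsslCV` list: `scheme`, per-round `rounds` data frame
#'   (`miRNA`, `disease`, `rank`, `candidates`), `auc`, `roc`.
#' @export
globalLOOCV <- function(assoc, fs = NULL, dags = NULL,
                        control = lrsslControl(), rounds = NULL) {
  A <- .asAssocMatrix(assoc)
  known <- which(A == 1)
  if (length(known) < 2) stop("need at least two known associations", call. = FALSE)
  ext <- .alignedInputs(A, fs, dags)
  if (!is.null(rounds) && rounds < length(known)) {
    known <- withSeed(control$seed, sample(known, rounds))
  }
  cand <- which(A == 0)
  res <- lapply(known, function(idx) {
    S <- .maskedScores(A, idx, ext, control)
    .rankAmong(S[idx], S[cand])
  })
  rk <- unlist(res)
  ij <- arrayInd(known, dim(A))
  roc <- rocAuc(rk, rep(length(cand), length(rk)))
  .newCV("global-loocv",
         data.frame(miRNA = rownames(A)[ij[, 1]], disease = colnames(A)[ij[, 2]],
                    rank = rk, candidates = length(cand)),
         roc$auc, roc$roc)
}

#' Local leave-one-out cross validation
#'
#' As [globalLOOCV()], but each held-out miRNA is ranked only against the
#' miRNAs whose association with the same disease is unconfirmed in the
#' full data. Rounds are pooled into one ROC; the mean of per-disease AUCs
#' is also reported for comparison.
#'
#' @inheritParams globalLOOCV
#' @return An `lrsslCV` list; `perGroup` holds the per-disease AUCs and
#'   `perGroupMeanAuc` their mean.
#' @export
localLOOCV <- function(assoc, fs = NULL, dags = NULL,
                       control = lrsslControl(), rounds = NULL) {
  A <- .asAssocMatrix(assoc)
  known <- which(A == 1)
  if (length(known) < 2) stop("need at least two known associations", call. = FALSE)
  ext <- .alignedInputs(A, fs, dags)
  if (!is.null(rounds) && rounds < length(known)) {
    known <- withSeed(control$seed, sample(known, rounds))
  }
  ij <- arrayInd(known, dim(A))
  rk <- numeric(length(known))
  nc <- integer(length(known))
  for (r in seq_along(known)) {
    i <- ij[r, 1]
    j <- ij[r, 2]
    candM <- which(A[, j] == 0)
    if (!length(candM)) {
      rk[r] <- NA
      next
    }
    S <- .maskedScores(A, known[r], ext, control)
    rk[r] <- .rankAmong(S[i, j], S[candM, j])
    nc[r] <- length(candM)
  }
  keep <- !is.na(rk)
  roc <- rocAuc(rk[keep], nc[keep])
  dis <- colnames(A)[ij[keep, 2]]
  perGroup <- vapply(split(seq_along(dis), dis), function(sel) {
    rocAuc(rk[keep][sel], nc[keep][sel])$auc
  }, 0)
  out <- .newCV("local-loocv",
                data.frame(miRNA = rownames(A)[ij[keep, 1]], disease = dis,
                           rank = rk[keep], candidates = nc[keep]),
                roc$auc, roc$roc, perGroup = perGroup)
  out$perGroupMeanAuc <- mean(perGroup)
  out
}

#' Repeated k-fold cross validation
#'
#' Randomly partitions the known associations into `k` near-equal folds
#' (sizes differing by at most one), zeroes each fold in turn, refits from
#' the masked matrix, and ranks every held-out pair against the pairs never
#' labelled 1 in the full data. One AUC is produced per repeat from that
#' repeat's pooled rounds; the mean and standard deviation across repeats
#' are returned (`aucSd` is 0, flagged, when `repeats = 1`).
#'
#' @inheritParams globalLOOCV
#' @param k number of folds (>= 2).
#' @param repeats number of seeded repetitions of the random partition.
#' @return An `lrsslCV` list with `auc` (mean), `aucSd`, `perRepeat`.
#' @export
kfoldCV <- function(assoc, fs = NULL, dags = NULL, control = lrsslControl(),
                    k = 5, repeats = 10) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  A <- .asAssocMatrix(assoc)
  known <- which(A == 1)
  if (length(known) < k) stop("fewer known associations than folds", call. = FALSE)
  ext <- .alignedInputs(A, fs, dags)
  cand <- which(A == 0)
  aucs <- numeric(repeats)
  allRounds <- list()
  for (r in seq_len(repeats)) {
    fold <- withSeed(control$seed + r, sample(rep(seq_len(k), length.out = length(known))))
    rk <- numeric(0)
    for (f in seq_len(k)) {
      test <- known[fold == f]
      S <- .maskedScores(A, test, ext, control)
      rk <- c(rk, vapply(test, function(idx) .rankAmong(S[idx], S[cand]), 0))
    }
    aucs[r] <- rocAuc(rk, rep(length(cand), length(rk)))$auc
    allRounds[[r]] <- data.frame(repeatId = r, rank = rk, candidates = length(cand))
  }
  out <- .newCV("kfold", do.call(rbind, allRounds), mean(aucs),
                roc = NULL, aucSd = if (repeats > 1) stats::sd(aucs) else 0)
  out$perRepeat <- aucs
  out$sdDefined <- repeats > 1
  out
}
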