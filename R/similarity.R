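#' Semantic value of one disease DAG
#'
#' Each term `t` in a disease's ancestor DAG contributes
#' `-log(membership(t) / nTotal)` to the disease's semantic value, where
#' `membership(t)` is the number of DAGs (over the disease corpus under
#' analysis) that contain `t`. A term shared by every disease contributes
#' zero; rarer, more specific terms contribute more. The semantic value DV
#' is the sum of contributions over all DAG nodes. Natural log is used; the
#' downstream semantic similarity is invariant to the base.
#'
#' @param dag a [DiseaseDAG-class].
#' @param membership named integer vector: for each term, the number of DAGs
#'   containing it (computed over the corpus the similarity is built on).
#' @param nTotal number of diseases in the corpus.
#' @return A list with `contribution` (named numeric per term) and `DV`
#'   (their sum).
#' @export
semanticValue <- function(dag, membership, nTotal) {
  stopifnot(nTotal >= 1)
  if (!all(dag@nodes %in% names(membership))) {
    stop(sprintf("term '%s' missing from DAG membership counts",
                 setdiff(dag@nodes, names(membership))[1]), call. = FALSE)
  }
  m <- membership[dag@nodes]
  if (any(m < 1)) stop("membership counts must be >= 1", call. = FALSE)
  if (any(m > nTotal)) {
    stop("term membership exceeds the number of diseases", call. = FALSE)
  }
  contribution <- -log(m / nTotal)
  list(contribution = contribution, DV = sum(contribution))
}

#' Disease semantic similarity from ancestor DAGs
#'
#' The similarity of two diseases is the summed contribution of their shared
#' DAG terms, from both sides, divided by the sum of their semantic values:
#' diseases whose ancestor graphs overlap more are more similar. Diseases
#' whose semantic value is zero (every term ubiquitous) get an undefined
#' row/column with a warning; the kernel fallback covers them at
#' integration.
#'
#' @param dags a list of [DiseaseDAG-class] objects; term membership is
#'   counted over exactly this list.
#' @return A [SimilarityMatrix-class] over the DAGs' disease names.
#' @examples
#' a <- DiseaseDAG("A", c("A", "R"), cbind("A", "R"))
#' b <- DiseaseDAG("B", c("B", "R"), cbind("B", "R"))
#' as.matrix(semanticSimilarity(list(a, b)))
#' @export
semanticSimilarity <- function(dags) {
  stopifnot(length(dags) >= 1)
  names(dags) <- vapply(dags, function(d) d@disease, "")
  if (anyDuplicated(names(dags))) stop("duplicated disease in DAG list", call. = FALSE)
  n <- length(dags)
  membership <- table(unlist(lapply(dags, function(d) unique(d@nodes))))
  membership <- stats::setNames(as.integer(membership), names(membership))
  sv <- lapply(dags, semanticValue, membership = membership, nTotal = n)
  dv <- vapply(sv, `[[`, 0, "DV")
  zero <- dv <= 0
  if (any(zero)) {
    warning(sprintf("semantic value is 0 for %d disease(s) (%s): rows left undefined",
                    sum(zero), paste(names(dags)[zero], collapse = ", ")))
  }
  ss <- matrix(NA_real_, n, n, dimnames = list(names(dags), names(dags)))
  for (i in seq_len(n)) {
    if (zero[i]) next
    for (j in i:n) {
      if (zero[j]) next
      shared <- intersect(dags[[i]]@nodes, dags[[j]]@nodes)
      num <- sum(sv[[i]]$contribution[shared]) + sum(sv[[j]]$contribution[shared])
      ss[i, j] <- ss[j, i] <- num / (dv[i] + dv[j])
    }
  }
  SimilarityMatrix(ss)
}

#' Gaussian interaction profile kernel similarity
#'
#' Computes `K(i, j) = exp(-gamma * ||IP_i - IP_j||^2)` over binary
#' interaction profiles (the rows of `profiles`), with the bandwidth scaled
#' by the mean squared profile norm:
#' `gamma = gammaPrime / mean(||IP_i||^2)`. For miRNAs the profiles are the
#' rows of the association matrix (each miRNA's disease profile); for
#' diseases, its columns.
#'
#' @param profiles n-by-k binary matrix, one interaction profile per row.
#' @param gammaPrime positive bandwidth scale, 1 by default.
#' @return A [SimilarityMatrix-class] with unit diagonal and all entries in
#'   `(0, 1]`.
#' @examples
#' ip <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
#'   dimnames = list(c("m1", "m2"), NULL))
#' as.matrix(gaussianKernel(ip)) # off-diagonal exp(-2)
#' @export
gaussianKernel <- function(profiles, gammaPrime = 1) {
  p <- as.matrix(profiles)
  stopifnot(gammaPrime > 0)
  sq <- rowSums(p^2)
  msn <- mean(sq)
  if (msn == 0) {
    stop("kernel bandwidth undefined: all interaction profiles are zero", call. = FALSE)
  }
  gamma <- gammaPrime / msn
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0 # numeric round-off
  k <- exp(-gamma * d2)
  diag(k) <- 1
  dimnames(k) <- list(rownames(p), rownames(p))
  SimilarityMatrix(k)
}

#' Align a similarity matrix onto a target name index
#'
#' Reorders a similarity onto `names`; entities absent from the source get
#' fully undefined rows/columns. Used to place an external functional or
#' semantic similarity onto the association matrix's index before
#' integration.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param names target entity names.
#' @param warnUnmatched warn about source entities not in `names` (matched
#'   on exact strings).
#' @return A [SimilarityMatrix-class] over `names`.
#' @export
alignSimilarity <- function(sim, names, warnUnmatched = TRUE) {
  v <- .asSimMatrix(sim)
  extra <- setdiff(rownames(v), names)
  if (length(extra) && warnUnmatched) {
    warning(sprintf("%d similarity entities not present in the target index (e.g. '%s')",
                    length(extra), extra[1]))
  }
  out <- matrix(NA_real_, length(names), length(names), dimnames = list(names, names))
  hit <- intersect(names, rownames(v))
  out[hit, hit] <- v[hit, hit]
  SimilarityMatrix(out)
}

#' Integrate a partially defined similarity with a kernel fallback
#'
#' Casewise combination: where the primary source (functional or semantic
#' similarity) defines a pair, its value is used; everywhere else the fully
#' defined fallback (the Gaussian interaction profile kernel) fills in.
#'
#' @param primary a [SimilarityMatrix-class], possibly with undefined
#'   entries.
#' @param fallback a fully defined [SimilarityMatrix-class] on the same
#'   entity index.
#' @return A fully defined [SimilarityMatrix-class].
#' @export
integrateSimilarity <- function(primary, fallback) {
  p <- .asSimMatrix(primary)
  f <- .asSimMatrix(fallback)
  if (!identical(dimnames(p), dimnames(f))) {
    stop("primary and fallback similarity indices do not match", call. = FALSE)
  }
  if (anyNA(f)) stop("fallback similarity must be fully defined", call. = FALSE)
  out <- p
  out[is.na(p)] <- f[is.na(p)]
  SimilarityMatrix(out)
}
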