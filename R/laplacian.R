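#' k-nearest-neighbor graph Laplacian of a feature profile
#'
#' Connects each entity to the `k` entities whose feature vectors have the
#' highest cosine similarity to its own (self excluded, ties broken by
#' ascending index), then symmetrizes the directed relation by logical OR —
#' a symmetric adjacency is required for a positive semidefinite Laplacian.
#' Returns `L = D - S` with `D` the diagonal degree matrix of the
#' symmetrized adjacency.
#'
#' @param X features-by-entities matrix (columns are the entity vectors).
#' @param k neighborhood size; must be below the number of entities.
#' @return A list with the binary adjacency `S`, the degree vector
#'   `degree`, and the Laplacian `L`.
#' @export
knnProfileGraph <- function(X, k = 10) {
  X <- as.matrix(X)
  n <- ncol(X)
  stopifnot(k >= 1)
  if (k >= n) stop("k must be smaller than the number of entities", call. = FALSE)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) {
    bad <- colnames(X)[which(nrm == 0)[1]]
    if (is.null(bad)) bad <- which(nrm == 0)[1]
    stop(sprintf("cosine similarity undefined: entity '%s' has an all-zero feature vector",
                 bad), call. = FALSE)
  }
  cs <- crossprod(sweep(X, 2, nrm, "/"))
  dimnames(cs) <- list(colnames(X), colnames(X))
  laplacianFromAdjacency(topkAdjacency(cs, k))
}

#' k-nearest-neighbor graph Laplacian of association profiles
#'
#' For entities with at least one known association, the closeness of two
#' entities is the maximum integrated similarity between their associated
#' groups on the other side (for two miRNAs: the best disease-disease
#' similarity across their associated disease sets; two entities sharing an
#' association have closeness 1). The top-`k` relation on this closeness is
#' OR-symmetrized as in [knnProfileGraph()]. Entities without any known
#' association are isolated (zero rows and columns).
#'
#' @param assoc the association matrix oriented with this side on the rows
#'   (pass the matrix itself for the miRNA side, its transpose for the
#'   disease side).
#' @param otherSim fully defined [SimilarityMatrix-class] over the other
#'   side's entities (SD for the miRNA side, SM for the disease side).
#' @param k neighborhood size.
#' @return A list with `S`, `degree` and `L` as in [knnProfileGraph()].
#' @export
knnAssociationGraph <- function(assoc, otherSim, k = 10) {
  a <- .asAssocMatrix(assoc)
  sim <- .asSimMatrix(otherSim)
  if (anyNA(sim)) stop("similarity must be fully defined", call. = FALSE)
  if (!identical(colnames(a), rownames(sim))) {
    stop("similarity index does not match the other side of the association matrix",
         call. = FALSE)
  }
  n <- nrow(a)
  sets <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  active <- lengths(sets) > 0
  close <- matrix(-Inf, n, n, dimnames = list(rownames(a), rownames(a)))
  act <- which(active)
  if (length(act)) {
    # best[i, b]: highest similarity from i's associated set to entity b
    best <- t(vapply(act, function(i) {
      apply(sim[sets[[i]], , drop = FALSE], 2, max)
    }, numeric(ncol(a))))
    for (ii in seq_along(act)) {
      i <- act[ii]
      close[i, act] <- vapply(act, function(j) max(best[ii, sets[[j]]]), 0)
    }
  }
  laplacianFromAdjacency(topkAdjacency(close, k, eligible = active))
}
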