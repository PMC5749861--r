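# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Divide each row by its sum; all-zero rows are left at zero.
rowNormalize <- function(m) {
  rs <- rowSums(m)
  pos <- rs > 0
  m[pos, ] <- m[pos, , drop = FALSE] / rs[pos]
  m
}

# Positive / negative parts of a matrix, (|M| + M)/2 and (|M| - M)/2.
posPart <- function(m) (abs(m) + m) / 2
negPart <- function(m) (abs(m) - m) / 2

# Directed top-k adjacency from a score matrix: row i points to the k
# eligible entities with the highest score[i, j], ties broken by ascending
# index, self excluded. `eligible` restricts both endpoints. Returns the
# OR-symmetrized binary matrix.
topkAdjacency <- function(score, k, eligible = rep(TRUE, nrow(score))) {
  n <- nrow(score)
  S <- matrix(0, n, n, dimnames = dimnames(score))
  idx <- which(eligible)
  for (i in idx) {
    others <- setdiff(idx, i)
    if (!length(others)) next
    ord <- others[order(-score[i, others], others)]
    S[i, ord[seq_len(min(k, length(ord)))]] <- 1
  }
  S <- pmax(S, t(S))
  S
}

# Graph Laplacian bundle from a binary symmetric adjacency.
laplacianFromAdjacency <- function(S) {
  deg <- rowSums(S)
  L <- diag(deg, nrow(S)) - S
  dimnames(L) <- dimnames(S)
  list(S = S, degree = deg, L = L)
}

.asAssocMatrix <- function(assoc) {
  if (is(assoc, "AssociationMatrix")) assoc@assoc else as.matrix(assoc)
}

.asSimMatrix <- function(sim) {
  if (is(sim, "SimilarityMatrix")) sim@values else as.matrix(sim)
}

# Format a number so that it round-trips bit-exactly through read.
fmtNum <- function(x) sprintf("%.17g", x)
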