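.statFeatureNames <- c("n.obs", "ave.sim", "s.d.sim", "min.sim", "first.q.sim",
                       "median.sim", "third.q.sim", "max.sim",
                       paste0("hist.sim.", 1:10))

#' Statistical feature profile
#'
#' Summarizes each entity's integrated similarity row (diagonal excluded,
#' since self-similarity is uninformative) and its association count into 18
#' features: `n.obs` (number of known associations), mean, standard
#' deviation, min, quartiles, median and max of the similarity scores, and a
#' 10-bin histogram of proportions over `[0, 1]` (bins right-open except the
#' last, proportions summing to 1). Values are returned unscaled; apply
#' [scaleFeatures()] before model fitting.
#'
#' @param sim fully defined [SimilarityMatrix-class] for this side (SM for
#'   miRNAs, SD for diseases).
#' @param assoc the [AssociationMatrix-class].
#' @param side `"mirna"` (similarity over rows of the association matrix)
#'   or `"disease"` (over its columns).
#' @param bins number of histogram bins over `[0, 1]`.
#' @return An 18-by-n numeric matrix, feature names on the rows, entity
#'   names on the columns.
#' @export
statisticalProfile <- function(assoc, sim, side = c("mirna", "disease"), bins = 10) {
  side <- match.arg(side)
  a <- .asAssocMatrix(assoc)
  v <- .asSimMatrix(sim)
  if (anyNA(v)) stop("similarity must be fully defined (integrate it first)", call. = FALSE)
  nObs <- if (side == "mirna") rowSums(a) else colSums(a)
  ent <- if (side == "mirna") rownames(a) else colnames(a)
  if (!identical(rownames(v), ent)) {
    stop("similarity index does not match the chosen side of the association matrix",
         call. = FALSE)
  }
  n <- nrow(v)
  if (n < 2) stop("need at least 2 entities for the statistical profile", call. = FALSE)
  X <- matrix(0, 8 + bins, n,
              dimnames = list(c(.statFeatureNames[1:8],
                                paste0("hist.sim.", seq_len(bins))), ent))
  for (i in seq_len(n)) {
    row <- v[i, -i]
    q <- stats::quantile(row, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    bin <- pmin(floor(row * bins) + 1, bins) # right-open bins, last closed
    X[, i] <- c(nObs[i], mean(row), stats::sd(row), min(row), q[1], q[2], q[3],
                max(row), tabulate(bin, nbins = bins) / length(row))
  }
  X
}

#' Threshold a similarity matrix into an unweighted graph
#'
#' Places an undirected edge between two distinct entities when their
#' similarity strictly exceeds the mean of all `n^2` matrix entries
#' (diagonal included in the mean).
#'
#' @param sim fully defined [SimilarityMatrix-class] or numeric matrix.
#' @return A binary symmetric adjacency matrix with zero diagonal.
#' @export
unweightedGraph <- function(sim) {
  v <- .asSimMatrix(sim)
  if (anyNA(v)) stop("similarity must be fully defined", call. = FALSE)
  adj <- (v > mean(v)) * 1
  diag(adj) <- 0
  adj <- pmax(adj, t(adj)) # symmetric input keeps this a no-op
  adj
}

#' Graph-theoretical feature profile
#'
#' Describes each entity as a node: degree in the thresholded
#' [unweightedGraph()]; the `k` largest similarity values to other entities
#' (descending, zero-padded below `k`); the plain and similarity-weighted
#' means of the 18 statistical features over the `k` most similar entities
#' (weights normalized to sum 1, uniform when all weights vanish); and four
#' centralities of the node in the unweighted graph — betweenness
#' (unnormalized pair counts), classical closeness within the connected
#' component, eigenvector centrality from the dominant eigenvector of the
#' whole adjacency (zero on components where it vanishes, scaled to max 1),
#' and PageRank with damping 0.85. 51 features in total. Neighbors are taken
#' by similarity value, ties broken by ascending entity index.
#'
#' @param sim fully defined [SimilarityMatrix-class] for this side.
#' @param stat the (unscaled) matrix from [statisticalProfile()] for the
#'   same entities.
#' @param k neighborhood size, 10 by default.
#' @return A 51-by-n numeric matrix, feature names on the rows.
#' @export
graphProfile <- function(sim, stat, k = 10) {
  v <- .asSimMatrix(sim)
  if (anyNA(v)) stop("similarity must be fully defined", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  n <- nrow(v)
  if (!identical(colnames(stat), rownames(v))) {
    stop("statistical profile entities do not match the similarity index", call. = FALSE)
  }
  adj <- unweightedGraph(v)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  bt <- igraph::betweenness(g, directed = FALSE)
  cl <- suppressWarnings(igraph::closeness(g)) # within-component, NaN if isolated
  cl[!is.finite(cl)] <- 0
  ev <- .dominantEigenCentrality(adj)
  pr <- igraph::page_rank(g, damping = 0.85)$vector

  ns <- nrow(stat)
  X <- matrix(0, 1 + k + 2 * ns + 4, n)
  rownames(X) <- c("num.nb", paste0("k.sim.", seq_len(k)),
                   paste0("k.ave.", rownames(stat)),
                   paste0("k.w.ave.", rownames(stat)), "bt", "cl", "ev", "pr")
  colnames(X) <- rownames(v)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-v[i, others], others)]
    nb <- ord[seq_len(min(k, length(ord)))]
    ksim <- c(v[i, nb], rep(0, k - length(nb)))
    kave <- rowMeans(stat[, nb, drop = FALSE])
    w <- v[i, nb]
    if (sum(w) > 0) w <- w / sum(w) else w <- rep(1 / length(nb), length(nb))
    kwave <- as.vector(stat[, nb, drop = FALSE] %*% w)
    X[, i] <- c(sum(adj[i, ]), ksim, kave, kwave, bt[i], cl[i], ev[i], pr[i])
  }
  X
}

# Dominant eigenvector of the adjacency, absolute values scaled to max 1;
# all-zero when the graph has no edges.
.dominantEigenCentrality <- function(adj) {
  if (sum(adj) == 0) return(rep(0, nrow(adj)))
  e <- eigen(adj, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v[v < .Machine$double.eps * nrow(adj)] <- 0
  v / max(v)
}

#' Min-max scale features across entities
#'
#' Rescales every feature (row) so its minimum maps to 0 and its maximum to
#' 1 across entities; constant features map to 0. Count-scale features
#' (association counts, betweenness) and `[0, 1]`-scale similarities are
#' thereby made commensurate before entering the subspace model.
#'
#' @param X features-by-entities matrix.
#' @return The scaled matrix, all values in `[0, 1]`.
#' @export
scaleFeatures <- function(X) {
  lo <- apply(X, 1, min)
  hi <- apply(X, 1, max)
  span <- hi - lo
  span[span == 0] <- 1 # constant features -> 0 after centering
  sweep(sweep(X, 1, lo), 1, span, "/")
}

#' Build both scaled feature profiles for one side
#'
#' Convenience wrapper: statistical profile, graph-theoretical profile
#' (averaging the unscaled statistical features), then min-max scaling of
#' each profile.
#'
#' @inheritParams statisticalProfile
#' @param k neighborhood size for the graph profile.
#' @return A list with the scaled feature matrices `X1` (18 x n) and `X2`
#'   (51 x n) that enter the subspace model, plus the unscaled `raw1` and
#'   `raw2` from which the feature kNN graphs are built (raw profiles
#'   always contain strictly positive entries, so their cosine geometry is
#'   defined for every entity).
#' @export
featureProfiles <- function(assoc, sim, side = c("mirna", "disease"),
                            bins = 10, k = 10) {
  side <- match.arg(side)
  stat <- statisticalProfile(assoc, sim, side, bins = bins)
  graph <- graphProfile(sim, stat, k = k)
  list(X1 = scaleFeatures(stat), X2 = scaleFeatures(graph),
       raw1 = stat, raw2 = graph)
}
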