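#' @import methods
#' @include AllGenerics.R
NULL

.checkNames <- function(nm, what) {
  if (is.null(nm)) return(sprintf("%s names are required", what))
  if (anyDuplicated(nm)) return(sprintf("duplicated %s names", what))
  if (any(!nzchar(nm))) return(sprintf("empty %s name", what))
  NULL
}

#' Binary miRNA-disease association matrix
#'
#' Container for the supervision signal: an `nm x nd` matrix with entries in
#' \{0, 1\}, miRNAs on the rows and diseases on the columns, both carried as
#' unique ordered name indices (the matrix `dimnames`).
#'
#' @slot assoc numeric matrix of 0/1 values with complete, unique dimnames.
#' @seealso [readAssociations()], [simulateMDA()]
#' @export
setClass("AssociationMatrix", slots = c(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  a <- object@assoc
  msg <- character()
  if (!is.numeric(a)) msg <- c(msg, "association values must be numeric")
  msg <- c(msg, .checkNames(rownames(a), "miRNA"), .checkNames(colnames(a), "disease"))
  if (is.numeric(a) && length(a) && !all(a == 0 | a == 1)) {
    msg <- c(msg, "association entries must all be 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AssociationMatrix
#'
#' @param assoc numeric 0/1 matrix with miRNA rownames and disease colnames.
#' @return An [AssociationMatrix-class] object.
#' @export
AssociationMatrix <- function(assoc) {
  new("AssociationMatrix", assoc = as.matrix(assoc))
}

#' Square similarity matrix with partial definition
#'
#' Holds a symmetric similarity in `[0, 1]` over one entity set. Entries the
#' source does not define (e.g. miRNA pairs absent from the functional
#' similarity network) are stored as `NA`; [knownMask()] exposes the defined
#' pattern and [integrateSimilarity()] fills the gaps from a kernel fallback.
#'
#' @slot values numeric square matrix, `NA` where undefined, identical
#'   row/column names; defined entries lie in `[0, 1]`, are symmetric, and
#'   the defined diagonal equals 1.
#' @seealso [readSimilarity()], [gaussianKernel()], [semanticSimilarity()]
#' @export
setClass("SimilarityMatrix", slots = c(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  tol <- 1e-9
  if (!is.numeric(v)) msg <- c(msg, "similarity values must be numeric")
  if (nrow(v) != ncol(v)) msg <- c(msg, "similarity matrix must be square")
  msg <- c(msg, .checkNames(rownames(v), "entity"))
  if (!is.null(rownames(v)) && !identical(rownames(v), colnames(v))) {
    msg <- c(msg, "row and column names must match in the same order")
  }
  if (is.numeric(v) && length(v)) {
    def <- !is.na(v)
    if (any(v[def] < -tol | v[def] > 1 + tol)) {
      msg <- c(msg, "defined similarity values must lie in [0, 1]")
    }
    if (nrow(v) == ncol(v)) {
      if (!identical(def, t(def))) {
        msg <- c(msg, "definition pattern must be symmetric")
      } else {
        d2 <- def & t(def)
        if (any(abs(v[d2] - t(v)[d2]) > tol)) {
          msg <- c(msg, "defined similarity values must be symmetric")
        }
      }
      dg <- diag(v)
      if (any(abs(dg[!is.na(dg)] - 1) > tol)) {
        msg <- c(msg, "defined diagonal entries must equal 1")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values numeric square matrix with matching dimnames; `NA` marks
#'   undefined entries.
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values) {
  new("SimilarityMatrix", values = as.matrix(values))
}

#' Disease ancestor graph
#'
#' The MeSH-style directed acyclic graph of one disease: its own term plus
#' ancestor terms, with edges pointing from each child term to a parent.
#'
#' @slot disease disease name (length-one character).
#' @slot nodes character vector of term identifiers, including the disease's
#'   own term.
#' @slot edges two-column character matrix of (child, parent) term pairs;
#'   endpoints are a subset of `nodes` and the graph is acyclic.
#' @seealso [readDiseaseDAGs()], [semanticSimilarity()]
#' @export
setClass("DiseaseDAG",
  slots = c(disease = "character", nodes = "character", edges = "matrix"))

setValidity("DiseaseDAG", function(object) {
  msg <- character()
  if (length(object@disease) != 1L) msg <- c(msg, "disease must be a single name")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated DAG nodes")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns (child, parent)")
  if (nrow(e)) {
    if (!all(e %in% object@nodes)) msg <- c(msg, "edge endpoint not among nodes")
    g <- igraph::graph_from_edgelist(e, directed = TRUE)
    if (!igraph::is_dag(g)) {
      msg <- c(msg, sprintf("cycle in DAG of disease '%s'", object@disease))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DiseaseDAG
#'
#' @param disease disease name.
#' @param nodes character vector of term identifiers.
#' @param edges two-column character matrix of (child, parent) pairs; may
#'   have zero rows.
#' @return A [DiseaseDAG-class] object.
#' @export
DiseaseDAG <- function(disease, nodes, edges = matrix(character(), 0, 2)) {
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("child", "parent")))
  new("DiseaseDAG", disease = disease, nodes = as.character(nodes), edges = edges)
}

#' Predicted association score matrix
#'
#' Real-valued `nm x nd` scores, always oriented miRNA rows by disease
#' columns, whether they come from the miRNA perspective, the disease
#' perspective, or the final three-scenario combination.
#'
#' @slot scores finite numeric matrix with miRNA rownames, disease colnames.
#' @slot provenance one of `"mirna-perspective"`, `"disease-perspective"`,
#'   `"final"`.
#' @seealso [lrsslmda()], [writeScores()]
#' @export
setClass("ScoreMatrix", slots = c(scores = "matrix", provenance = "character"))

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  s <- object@scores
  if (!is.numeric(s) || (length(s) && !all(is.finite(s)))) {
    msg <- c(msg, "scores must be finite numeric values")
  }
  msg <- c(msg, .checkNames(rownames(s), "miRNA"), .checkNames(colnames(s), "disease"))
  if (!object@provenance %in% c("mirna-perspective", "disease-perspective", "final")) {
    msg <- c(msg, "unknown provenance")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScoreMatrix
#'
#' @param scores finite numeric matrix with dimnames.
#' @param provenance score provenance label.
#' @return A [ScoreMatrix-class] object.
#' @export
ScoreMatrix <- function(scores, provenance = "final") {
  new("ScoreMatrix", scores = as.matrix(scores), provenance = provenance)
}

#' Fitted subspace-learning model for one side
#'
#' State returned by [fitLRSSL()]: the predicted association matrix `F` in
#' this side's orientation, the nonnegative projection matrices `G_p` (one
#' per feature profile), the Laplacian contribution weights `alpha`
#' (profile 1, profile 2, association graph), and the objective trace.
#'
#' @slot F numeric n-by-t matrix of smoothed association predictions.
#' @slot G list of nonnegative d_p-by-t projection matrices.
#' @slot alpha numeric weights summing to 1.
#' @slot objective recorded objective value per iteration (non-increasing).
#' @slot iterations iterations performed.
#' @slot converged whether the relative-change tolerance was reached.
#' @slot side `"mirna"` or `"disease"`.
#' @slot control the hyperparameter list used (see [lrsslControl()]).
#' @export
setClass("LRSSLFit",
  slots = c(F = "matrix", G = "list", alpha = "numeric",
            objective = "numeric", iterations = "integer",
            converged = "logical", side = "character", control = "list"))

setValidity("LRSSLFit", function(object) {
  msg <- character()
  if (any(vapply(object@G, function(g) any(g < 0), logical(1)))) {
    msg <- c(msg, "projection matrices must be nonnegative")
  }
  if (abs(sum(object@alpha) - 1) > 1e-9) msg <- c(msg, "alpha must sum to 1")
  if (any(object@alpha < 0)) msg <- c(msg, "alpha must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' End-to-end prediction result
#'
#' Returned by [lrsslmda()]: the integrated similarities actually used, the
#' per-side fits, and the per-perspective plus final score matrices.
#'
#' @slot assoc the training [AssociationMatrix-class].
#' @slot SM,SD integrated miRNA / disease [SimilarityMatrix-class].
#' @slot fits list with elements `mirna` and `disease` ([LRSSLFit-class]).
#' @slot scores list with elements `mirna`, `disease`, `final`
#'   ([ScoreMatrix-class], all in miRNA-by-disease orientation).
#' @export
setClass("LRSSLResult",
  slots = c(assoc = "AssociationMatrix", SM = "SimilarityMatrix",
            SD = "SimilarityMatrix", fits = "list", scores = "list"))

## ---- accessors and show methods ----

#' @rdname accessors
#' @export
setMethod("mirnaNames", "AssociationMatrix", function(x) rownames(x@assoc))

#' @rdname accessors
#' @export
setMethod("diseaseNames", "AssociationMatrix", function(x) colnames(x@assoc))

#' @rdname accessors
#' @export
setMethod("mirnaNames", "ScoreMatrix", function(x) rownames(x@scores))

#' @rdname accessors
#' @export
setMethod("diseaseNames", "ScoreMatrix", function(x) colnames(x@scores))

#' @rdname accessors
#' @export
setMethod("mirnaNames", "LRSSLResult", function(x) rownames(x@assoc@assoc))

#' @rdname accessors
#' @export
setMethod("diseaseNames", "LRSSLResult", function(x) colnames(x@assoc@assoc))

#' @rdname accessors
#' @export
setMethod("entityNames", "SimilarityMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("knownMask", "SimilarityMatrix", function(x) {
  m <- !is.na(x@values)
  dimnames(m) <- dimnames(x@values)
  m
})

#' @rdname fit-accessors
#' @export
setMethod("alphaWeights", "LRSSLFit", function(x) x@alpha)

#' @rdname fit-accessors
#' @export
setMethod("objectiveTrace", "LRSSLFit", function(x) x@objective)

#' Coerce containers to a base matrix
#'
#' @param x an `AssociationMatrix`, `SimilarityMatrix` or `ScoreMatrix`.
#' @param ... ignored.
#' @return The underlying numeric matrix (with `NA` marking undefined
#'   similarity entries).
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@assoc)

#' @rdname as.matrix-AssociationMatrix-method
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)

#' @rdname as.matrix-AssociationMatrix-method
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@scores)

setMethod("show", "AssociationMatrix", function(object) {
  a <- object@assoc
  cat(sprintf("AssociationMatrix: %d miRNAs x %d diseases, %d known associations (%.2f%%)\n",
              nrow(a), ncol(a), sum(a), 100 * mean(a)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  cat(sprintf("SimilarityMatrix: %d entities, %.1f%% of entries defined\n",
              nrow(v), 100 * mean(!is.na(v))))
})

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG '%s': %d terms, %d edges\n",
              object@disease, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "ScoreMatrix", function(object) {
  s <- object@scores
  cat(sprintf("ScoreMatrix (%s): %d miRNAs x %d diseases, score range [%.4g, %.4g]\n",
              object@provenance, nrow(s), ncol(s), min(s), max(s)))
})

setMethod("show", "LRSSLFit", function(object) {
  cat(sprintf("LRSSLFit (%s side): %d x %d, %d iterations (%s), objective %.6g\n",
              object@side, nrow(object@F), ncol(object@F), object@iterations,
              if (object@converged) "converged" else "max iterations",
              utils::tail(object@objective, 1)))
  cat(sprintf("  alpha: profile1 %.3f, profile2 %.3f, association graph %.3f\n",
              object@alpha[1], object@alpha[2], object@alpha[3]))
})

setMethod("show", "LRSSLResult", function(object) {
  show(object@assoc)
  cat("Fits:\n")
  show(object@fits$mirna)
  show(object@fits$disease)
})

#' Extract score matrices from a result
#'
#' @param x an [LRSSLResult-class].
#' @param which `"final"`, `"mirna"` (miRNA perspective) or `"disease"`
#'   (disease perspective).
#' @return A [ScoreMatrix-class], miRNA rows by disease columns.
#' @export
predictedScores <- function(x, which = c("final", "mirna", "disease")) {
  stopifnot(is(x, "LRSSLResult"))
  x@scores[[match.arg(which)]]
}
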