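#' Accessors for association, similarity and score containers
#'
#' `mirnaNames()` and `diseaseNames()` return the ordered entity identifiers
#' of an object carrying the miRNA-by-disease orientation;
#' `entityNames()` returns the (single) index of a square similarity matrix;
#' `knownMask()` returns the logical matrix marking entries the similarity
#' source actually defines (the integration fallback fills the rest).
#'
#' @param x an object of the corresponding class.
#' @return A character vector of names, or for `knownMask()` a logical
#'   matrix of the similarity's dimensions.
#' @name accessors
#' @aliases mirnaNames diseaseNames entityNames knownMask
#' @examples
#' a <- AssociationMatrix(matrix(c(1, 0, 1, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' mirnaNames(a)
NULL

#' @rdname accessors
#' @export
setGeneric("mirnaNames", function(x) standardGeneric("mirnaNames"))

#' @rdname accessors
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))

#' @rdname accessors
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))

#' @rdname accessors
#' @export
setGeneric("knownMask", function(x) standardGeneric("knownMask"))

#' Model-fit accessors
#'
#' `alphaWeights()` returns the fitted Laplacian contribution weights
#' (profile 1, profile 2, association graph), which sum to one;
#' `objectiveTrace()` returns the recorded objective value per iteration.
#'
#' @param x an [LRSSLFit-class] object.
#' @return A numeric vector.
#' @name fit-accessors
#' @aliases alphaWeights objectiveTrace
NULL

#' @rdname fit-accessors
#' @export
setGeneric("alphaWeights", function(x) standardGeneric("alphaWeights"))

#' @rdname fit-accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
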