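#' Read known miRNA-disease associations
#'
#' Reads a two-column tab-separated file of (miRNA, disease) name pairs —
#' the format of curated association tables such as the HMDD export — and
#' builds the binary adjacency matrix. Duplicate pairs collapse to a single
#' 1. Row and column order follow first appearance in the file, which keeps
#' downstream ranks reproducible from a fixed input; set `sortNames = TRUE`
#' to canonicalize when comparing across inputs.
#'
#' @param path path to a UTF-8 TSV file; lines starting with `#` are ignored.
#' @param sortNames sort miRNA and disease names lexicographically instead
#'   of keeping first-appearance order.
#' @param quiet suppress the summary message.
#' @return An [AssociationMatrix-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("m1\td1", "m2\td2", "m1\td1"), f)
#' readAssociations(f, quiet = TRUE)
#' @export
readAssociations <- function(path, sortNames = FALSE, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("association file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines)
  rows <- which(keep & nzchar(lines))
  if (!length(rows)) stop(sprintf("association file is empty: %s", path), call. = FALSE)
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop(sprintf("parse error in %s, line %d: expected 2 tab-separated fields, found %d",
                 path, rows[bad[1]], lengths(fields)[bad[1]]), call. = FALSE)
  }
  mir <- vapply(fields, `[[`, "", 1L)
  dis <- vapply(fields, `[[`, "", 2L)
  mn <- unique(mir)
  dn <- unique(dis)
  if (sortNames) {
    mn <- sort(mn)
    dn <- sort(dn)
  }
  a <- matrix(0, length(mn), length(dn), dimnames = list(mn, dn))
  a[cbind(match(mir, mn), match(dis, dn))] <- 1
  if (!quiet) {
    message(sprintf("read %d association pairs (%d distinct): %d miRNAs x %d diseases",
                    length(mir), sum(a), length(mn), length(dn)))
  }
  AssociationMatrix(a)
}

#' Write associations as a pair list
#'
#' Inverse of [readAssociations()]: emits one `(miRNA, disease)` row per
#' known association, in row-major matrix order so a read round-trips to the
#' identical matrix.
#'
#' @param assoc an [AssociationMatrix-class] (or 0/1 matrix with dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(assoc, path) {
  a <- .asAssocMatrix(assoc)
  idx <- which(t(a) == 1, arr.ind = TRUE) # transpose: row-major pair order
  rows <- sprintf("%s\t%s", rownames(a)[idx[, 2]], colnames(a)[idx[, 1]])
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Read a labeled similarity matrix
#'
#' Reads an `(n+1) x (n+1)` tab-separated grid: a header row of entity
#' names, a first column of the same names in the same order, and numeric or
#' empty cells. Empty cells mean "this pair is not defined by the source"
#' (e.g. a miRNA pair absent from the functional similarity network) and are
#' kept as `NA` — zero is a legal similarity and is never conflated with
#' missing. Defined entries must be symmetric, in `[0, 1]`, with a unit
#' diagonal where defined.
#'
#' @param path path to the TSV grid; `#` comment lines are ignored.
#' @return A [SimilarityMatrix-class].
#' @export
readSimilarity <- function(path) {
  if (!file.exists(path)) stop(sprintf("similarity file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  v <- as.matrix(df)
  if (nrow(v) != ncol(v)) {
    stop(sprintf("similarity matrix in %s is not square (%d x %d)",
                 path, nrow(v), ncol(v)), call. = FALSE)
  }
  if (!identical(rownames(v), colnames(v))) {
    stop(sprintf("similarity matrix in %s: header names and row labels differ", path),
         call. = FALSE)
  }
  v[!nzchar(trimws(v))] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(v), nrow(v), dimnames = dimnames(v)))
  if (any(is.na(num) & !is.na(v))) {
    stop(sprintf("similarity matrix in %s contains non-numeric cells", path), call. = FALSE)
  }
  tol <- 1e-9
  def <- !is.na(num)
  if (any(num[def] < -tol | num[def] > 1 + tol)) {
    stop(sprintf("similarity matrix in %s has defined values outside [0, 1]", path),
         call. = FALSE)
  }
  if (!identical(def, t(def))) {
    stop(sprintf("similarity matrix in %s defines (i,j) without (j,i)", path), call. = FALSE)
  }
  if (any(abs(num[def] - t(num)[def]) > tol)) {
    stop(sprintf("similarity matrix in %s is asymmetric beyond 1e-9", path), call. = FALSE)
  }
  SimilarityMatrix(num)
}

#' Write a labeled similarity matrix
#'
#' Inverse of [readSimilarity()]. Undefined entries are written as empty
#' cells; defined values are printed at 17 significant digits so the read
#' reproduces them bit-exactly.
#'
#' @param sim a [SimilarityMatrix-class] (or numeric matrix with dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimilarity <- function(sim, path) {
  v <- .asSimMatrix(sim)
  chr <- matrix(fmtNum(v), nrow(v))
  chr[is.na(v)] <- ""
  header <- paste(c("", colnames(v)), collapse = "\t")
  body <- vapply(seq_len(nrow(v)),
                 function(i) paste(c(rownames(v)[i], chr[i, ]), collapse = "\t"), "")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read per-disease ancestor DAGs
#'
#' Reads a three-column TSV of `(disease, child_term, parent_term)` rows.
#' Rows with parent `-` declare a node without adding an edge (used for root
#' terms). Each disease's rows must form an acyclic graph, every parent term
#' must itself be declared (as a `-` row or as some edge's child), and node
#' sets are closed under the listed parents.
#'
#' @param path path to the TSV; `#` comment lines are ignored.
#' @return A named list of [DiseaseDAG-class] objects, one per distinct
#'   disease, in first-appearance order.
#' @export
readDiseaseDAGs <- function(path) {
  if (!file.exists(path)) stop(sprintf("DAG file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  rows <- which(!grepl("^#", lines) & nzchar(lines))
  if (!length(rows)) stop(sprintf("DAG file is empty: %s", path), call. = FALSE)
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop(sprintf("parse error in %s, line %d: expected 3 tab-separated fields",
                 path, rows[bad[1]]), call. = FALSE)
  }
  dis <- vapply(fields, `[[`, "", 1L)
  child <- vapply(fields, `[[`, "", 2L)
  parent <- vapply(fields, `[[`, "", 3L)
  out <- list()
  for (d in unique(dis)) {
    sel <- dis == d
    isEdge <- parent[sel] != "-"
    ch <- child[sel]
    pa <- parent[sel]
    declared <- unique(c(ch, ch[isEdge]))
    undeclared <- setdiff(pa[isEdge], declared)
    if (length(undeclared)) {
      stop(sprintf("DAG of disease '%s' references undeclared term '%s'",
                   d, undeclared[1]), call. = FALSE)
    }
    edges <- cbind(ch[isEdge], pa[isEdge])
    nodes <- unique(c(ch, pa[isEdge]))
    if (nrow(edges)) {
      g <- igraph::graph_from_edgelist(edges, directed = TRUE)
      if (!igraph::is_dag(g)) {
        stop(sprintf("cycle detected in DAG of disease '%s'", d), call. = FALSE)
      }
    }
    out[[d]] <- DiseaseDAG(d, nodes, edges)
  }
  out
}

#' Write per-disease ancestor DAGs
#'
#' Inverse of [readDiseaseDAGs()]: per disease, one declaration row per
#' node (`disease<TAB>term<TAB>-`) followed by one row per edge.
#'
#' @param dags a list of [DiseaseDAG-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDiseaseDAGs <- function(dags, path) {
  rows <- unlist(lapply(dags, function(dag) {
    c(sprintf("%s\t%s\t-", dag@disease, dag@nodes),
      if (nrow(dag@edges)) {
        sprintf("%s\t%s\t%s", dag@disease, dag@edges[, 1], dag@edges[, 2])
      })
  }))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Write predicted association scores
#'
#' Emits a four-column TSV `(miRNA, disease, score, rank)`, sorted by
#' disease (column order) then descending score; `rank` is the within-
#' disease position (ties broken by miRNA index). Scores are printed at 17
#' significant digits so [readScores()] reproduces them bit-exactly.
#'
#' @param scores a [ScoreMatrix-class] (or finite numeric matrix with
#'   dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  s <- if (is(scores, "ScoreMatrix")) scores@scores else as.matrix(scores)
  if (any(!is.finite(s))) stop("scores contain non-finite values", call. = FALSE)
  out <- character(0)
  for (j in seq_len(ncol(s))) {
    ord <- order(-s[, j], seq_len(nrow(s)))
    out <- c(out, sprintf("%s\t%s\t%s\t%d", rownames(s)[ord], colnames(s)[j],
                          fmtNum(s[ord, j]), seq_along(ord)))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("miRNA\tdisease\tscore\trank", out), con, useBytes = TRUE)
  invisible(path)
}

#' Read a score table back into a matrix
#'
#' @param path a file written by [writeScores()].
#' @return A [ScoreMatrix-class] with miRNAs and diseases in
#'   first-appearance order.
#' @export
readScores <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE,
                          colClasses = c("character", "character", "numeric", "integer"))
  mn <- unique(df[[1]])
  dn <- unique(df[[2]])
  s <- matrix(NA_real_, length(mn), length(dn), dimnames = list(mn, dn))
  s[cbind(match(df[[1]], mn), match(df[[2]], dn))] <- df[[3]]
  ScoreMatrix(s, provenance = "final")
}
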