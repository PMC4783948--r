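#' @describeIn PPIEdgeList-class number of undirected edges
#' @param x object.
#' @export
setMethod("numEdges", "PPIEdgeList", function(x) nrow(x@edges))

#' Edge pairs of a PPI edge list
#'
#' @param x a [PPIEdgeList-class] object.
#' @return Two-column character matrix of sorted protein pairs.
#' @export
edgePairs <- function(x) {
  stopifnot(is(x, "PPIEdgeList"))
  e <- x@edges
  colnames(e) <- c("protein_a", "protein_b")
  e
}

setMethod("show", "PPIEdgeList", function(object) {
  cat("PPIEdgeList with", nrow(object@edges), "undirected edges,",
      length(unique(as.vector(object@edges))), "proteins\n")
  cat("  dialect:", object@dialect,
      if (length(object@organism) && !is.na(object@organism))
        paste0("; organism: ", object@organism) else "", "\n")
})

#' @describeIn CandidateNetwork-class node ids in matrix-index order
#' @param x object.
#' @export
setMethod("networkNodes", "CandidateNetwork", function(x) x@nodes)

#' @describeIn CandidateNetwork-class number of induced undirected edges
#' @export
setMethod("numEdges", "CandidateNetwork",
  function(x) as.integer(sum(x@adjacency) / 2L))

#' @describeIn CandidateNetwork-class per-protein interactor counts
#' @export
setMethod("interactorCounts", "CandidateNetwork", function(x) {
  counts <- as.integer(Matrix::rowSums(x@adjacency))
  names(counts) <- x@nodes
  counts
})

#' @describeIn CandidateNetwork-class named neighbor lists
#' @export
setMethod("neighborList", "CandidateNetwork", function(x) {
  idx <- .neighbor_indices(x@adjacency)
  out <- lapply(idx, function(i) x@nodes[i])
  names(out) <- x@nodes
  out
})

## column indices of TRUE entries per row of a symmetric lgCMatrix
.neighbor_indices <- function(adj) {
  tadj <- as(adj, "CsparseMatrix")  # columns of the symmetric matrix = rows
  p <- tadj@p
  lapply(seq_len(ncol(tadj)), function(j) {
    if (p[j + 1L] > p[j]) sort(tadj@i[(p[j] + 1L):p[j + 1L]] + 1L) else integer(0)
  })
}

setMethod("show", "CandidateNetwork", function(object) {
  cat("CandidateNetwork with", length(object@nodes), "proteins and",
      numEdges(object), "edges\n")
  m <- interactorCounts(object)
  cat("  interactor counts: min", min(m), "/ median", stats::median(m),
      "/ max", max(m), "\n")
})

#' @describeIn InteractionMatrix-class node ids in matrix-index order
#' @param x object.
#' @export
setMethod("networkNodes", "InteractionMatrix", function(x) x@nodes)

#' @describeIn InteractionMatrix-class sparse coefficient matrix \eqn{A}
#' @export
setMethod("coefficientMatrix", "InteractionMatrix", function(x) {
  a <- x@coefficients
  dimnames(a) <- list(x@nodes, x@nodes)
  a
})

#' @describeIn InteractionMatrix-class condition tag
#' @export
setMethod("networkCondition", "InteractionMatrix", function(x) x@condition)

#' @describeIn InteractionMatrix-class time-point label
#' @export
setMethod("timePoint", "InteractionMatrix", function(x) x@timePoint)

#' @describeIn InteractionMatrix-class per-protein fit diagnostics
#' @export
setMethod("proteinFits", "InteractionMatrix", function(x) x@fits)

setMethod("show", "InteractionMatrix", function(object) {
  cat("InteractionMatrix (", object@condition,
      if (!is.na(object@timePoint)) paste0(", ", object@timePoint) else "",
      "): ", length(object@nodes), " proteins, ",
      length(object@coefficients@x), " retained coefficients\n", sep = "")
})

#' @describeIn DifferenceMatrix-class node ids in matrix-index order
#' @param x object.
#' @export
setMethod("networkNodes", "DifferenceMatrix", function(x) x@nodes)

#' @describeIn DifferenceMatrix-class sparse difference matrix \eqn{D}
#' @export
setMethod("coefficientMatrix", "DifferenceMatrix", function(x) {
  d <- x@d
  dimnames(d) <- list(x@nodes, x@nodes)
  d
})

#' @describeIn DifferenceMatrix-class time-point label
#' @export
setMethod("timePoint", "DifferenceMatrix", function(x) x@timePoint)

setMethod("show", "DifferenceMatrix", function(object) {
  cat("DifferenceMatrix (", if (!is.na(object@timePoint)) object@timePoint
      else "unlabelled", "): ", length(object@nodes), " proteins, ",
      sum(object@d@x != 0), " nonzero differences\n", sep = "")
})

#' @describeIn DifferenceMatrix-class per-protein relevance values
#' @param d object.
#' @export
setMethod("computeTRV", "DifferenceMatrix", function(d) {
  trv <- Matrix::rowSums(abs(d@d))
  names(trv) <- d@nodes
  trv
})
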