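#' Node identifiers of a network object
#'
#' @param x a [CandidateNetwork-class], [InteractionMatrix-class] or
#'   [DifferenceMatrix-class] object.
#' @return Character vector of protein ids in matrix-index order.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Number of undirected edges
#'
#' @param x a [PPIEdgeList-class] or [CandidateNetwork-class] object.
#' @return Integer edge count.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Per-protein interactor counts
#'
#' The number of candidate interactors \eqn{M_i} of every node.
#'
#' @param x a [CandidateNetwork-class] object.
#' @return Named integer vector.
#' @export
setGeneric("interactorCounts", function(x) standardGeneric("interactorCounts"))

#' Neighbor lists of a candidate network
#'
#' @param x a [CandidateNetwork-class] object.
#' @return Named list; element `i` holds the ordered interactor ids of
#'   protein `i` within the node set.
#' @export
setGeneric("neighborList", function(x) standardGeneric("neighborList"))

#' Extract the coefficient / difference matrix
#'
#' @param x an [InteractionMatrix-class] or [DifferenceMatrix-class] object.
#' @return A sparse `dgCMatrix` with protein ids as dimnames.
#' @export
setGeneric("coefficientMatrix", function(x) standardGeneric("coefficientMatrix"))

#' Condition tag of an interaction matrix
#'
#' @param x an [InteractionMatrix-class] object.
#' @return `"case"` or `"control"`.
#' @export
setGeneric("networkCondition", function(x) standardGeneric("networkCondition"))

#' Time-point label of a network object
#'
#' @param x an [InteractionMatrix-class] or [DifferenceMatrix-class] object.
#' @return Character label, possibly `NA` (pooled / not applicable).
#' @export
setGeneric("timePoint", function(x) standardGeneric("timePoint"))

#' Per-protein fit diagnostics
#'
#' @param x an [InteractionMatrix-class] object.
#' @return Named list of per-target fit records (see [fitProteinModel()]).
#' @export
setGeneric("proteinFits", function(x) standardGeneric("proteinFits"))

#' Network relevance values (row sums of absolute coefficient differences)
#'
#' For a difference matrix \eqn{D} the relevance value of protein \eqn{i}
#' is \eqn{TRV_i = \sum_j |d_{ij}|}: the total absolute change in its
#' outgoing association coefficients between the two conditions.
#'
#' @param d a [DifferenceMatrix-class] object.
#' @return Named non-negative numeric vector over the nodes of `d`.
#' @examples
#' m <- rbind(c(0, 1, -2), c(0, 0, 3), c(0, 0, 0))
#' d <- new("DifferenceMatrix", nodes = c("A", "B", "C"),
#'          d = dppin:::.as_dgc(m), timePoint = NA_character_)
#' computeTRV(d)  # A: 3, B: 3, C: 0
#' @export
setGeneric("computeTRV", function(d) standardGeneric("computeTRV"))
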