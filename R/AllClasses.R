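#' @import methods
#' @importFrom Matrix Matrix sparseMatrix drop0 t isSymmetric rowSums colSums
#' @importClassesFrom Matrix lgCMatrix dgCMatrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData
#' @importFrom S4Vectors metadata DataFrame
NULL

.CONDITIONS <- c("case", "control")

## coerce any numeric matrix to a general column-sparse (dgC) form,
## regardless of the special (triangular/symmetric) class Matrix detects
.as_dgc <- function(m) {
  m <- Matrix::drop0(Matrix::Matrix(m, sparse = TRUE))
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Expression matrix with a case/control, time-point sample design
#'
#' `PPINExpression` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a fixed sample
#' design: every sample carries a `condition` (`"case"` or `"control"`), a
#' `time_point` label drawn from the ordered set stored in
#' `metadata(x)$time_levels`, and a `replicate` index.  The single assay
#' `"exprs"` holds expression intensities (genes in rows, samples in
#' columns); `metadata(x)$linear_scale` records whether values are declared
#' to be on the linear intensity scale, in which case they must be
#' non-negative.
#'
#' @seealso [ppinExpression()], [quantileNormalize()], [groupMeans()]
#' @export
setClass("PPINExpression", contains = "SummarizedExperiment")

setValidity("PPINExpression", function(object) {
  msg <- character(0)
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("condition", "time_point", "replicate"))
    if (!(col %in% colnames(cd))) msg <- c(msg, sprintf("colData column '%s' is required", col))
  if (length(msg)) return(msg)
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (!all(cd$condition %in% .CONDITIONS))
    msg <- c(msg, "condition must be 'case' or 'control'")
  lev <- S4Vectors::metadata(object)$time_levels
  if (!is.null(lev) && !all(cd$time_point %in% lev))
    msg <- c(msg, "time_point labels must be drawn from metadata time_levels")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (!all(is.finite(v)))
    msg <- c(msg, "expression values must all be finite")
  lin <- S4Vectors::metadata(object)$linear_scale
  if (isTRUE(lin) && length(v) && min(v) < 0)
    msg <- c(msg, "linear-scale expression values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Undirected protein-protein interaction edge list
#'
#' A deduplicated, self-loop-free set of unordered protein pairs.  The
#' `edges` slot is a two-column character matrix with each pair stored in
#' lexicographic order; `dialect` records the source format and `organism`
#' an optional taxon filter that was applied on ingestion.
#'
#' @seealso [ppiEdgeList()], [readPPIEdges()], [buildCandidateNetwork()]
#' @export
setClass("PPIEdgeList",
  representation(edges = "matrix", dialect = "character", organism = "character"))

setValidity("PPIEdgeList", function(object) {
  e <- object@edges
  msg <- character(0)
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a two-column character matrix")
  if (any(!nzchar(e))) msg <- c(msg, "protein ids must be non-empty")
  if (nrow(e)) {
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) msg <- c(msg, "pairs must be stored in sorted order")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      msg <- c(msg, "duplicate pairs are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Candidate protein interaction network
#'
#' The induced, isolate-free subgraph of a PPI edge list on a protein set.
#' `nodes` fixes a deterministic (lexicographic) matrix index and
#' `adjacency` is the symmetric logical adjacency matrix on that index.
#' The per-protein interactor count \eqn{M_i} is the number of candidate
#' regressors available when protein \eqn{i}'s association model is fitted.
#'
#' @seealso [buildCandidateNetwork()], [fitConditionNetwork()]
#' @export
setClass("CandidateNetwork",
  representation(nodes = "character", adjacency = "lgCMatrix"))

setValidity("CandidateNetwork", function(object) {
  a <- object@adjacency
  msg <- character(0)
  if (nrow(a) != length(object@nodes) || ncol(a) != length(object@nodes))
    return("adjacency dimensions must match the node set")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node ids must be unique")
  if (nrow(a)) {
    if (!Matrix::isSymmetric(a)) msg <- c(msg, "adjacency must be symmetric")
    if (any(Matrix::diag(a))) msg <- c(msg, "adjacency must have an empty diagonal")
    if (any(Matrix::rowSums(a) == 0)) msg <- c(msg, "isolated nodes are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Condition-specific interaction strength matrix
#'
#' The assembled sparse coefficient matrix \eqn{A} for one condition (and,
#' for case networks, one time point): entry \eqn{(i, j)} is the retained
#' association coefficient of interactor \eqn{j} in target \eqn{i}'s pruned
#' regression.  Rows are regressions, so the matrix is generally
#' asymmetric.  The `fits` slot keeps one per-protein diagnostic record
#' (ranking, AIC trace, chosen order, t statistics, residual variance).
#'
#' @seealso [fitConditionNetwork()], [differenceMatrix()]
#' @export
setClass("InteractionMatrix",
  representation(nodes = "character", coefficients = "dgCMatrix",
                 condition = "character", timePoint = "character",
                 fits = "list"))

setValidity("InteractionMatrix", function(object) {
  msg <- character(0)
  m <- length(object@nodes)
  if (nrow(object@coefficients) != m || ncol(object@coefficients) != m)
    return("coefficient matrix dimensions must match the node set")
  if (length(object@condition) != 1L || !(object@condition %in% .CONDITIONS))
    msg <- c(msg, "condition must be 'case' or 'control'")
  if (m && any(Matrix::diag(object@coefficients) != 0))
    msg <- c(msg, "diagonal entries must be zero")
  if (length(msg)) msg else TRUE
})

#' Differential network (difference of interaction matrices)
#'
#' Entrywise difference of a case and a control [InteractionMatrix-class]
#' on the union node index: \eqn{d_{ij} =
#' \hat\alpha_{ij,case} - \hat\alpha_{ij,control}}.  Row sums of absolute
#' values of this matrix are the per-protein network relevance values.
#'
#' @seealso [differenceMatrix()], [computeTRV()], [classifyEdges()]
#' @export
setClass("DifferenceMatrix",
  representation(nodes = "character", d = "dgCMatrix", timePoint = "character"))

setValidity("DifferenceMatrix", function(object) {
  m <- length(object@nodes)
  if (nrow(object@d) != m || ncol(object@d) != m)
    return("difference matrix dimensions must match the node set")
  if (m && !all(is.finite(object@d@x)))
    return("difference matrix entries must be finite")
  TRUE
})
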