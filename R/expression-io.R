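#' Construct a PPINExpression object
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#'   Row names are gene ids; column names, if present, must agree with
#'   `design$sample_id`.
#' @param design `data.frame` with columns `sample_id`, `condition`
#'   (`"case"`/`"control"`), `time_point` and `replicate`, one row per
#'   column of `values` in column order.
#' @param timeLevels ordered set of admissible time-point labels; defaults
#'   to the labels present, in order of first appearance.
#' @param linearScale declare values to be linear-scale intensities
#'   (enforces non-negativity).
#' @return A [PPINExpression-class] object.
#' @examples
#' v <- matrix(1:6, 2, 3, dimnames = list(c("G1", "G2"), c("s1", "s2", "s3")))
#' d <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                 condition = c("case", "case", "control"),
#'                 time_point = "4h", replicate = c(1, 2, 1))
#' ppinExpression(v, d)
#' @export
ppinExpression <- function(values, design, timeLevels = NULL, linearScale = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  design <- as.data.frame(design)
  need <- c("sample_id", "condition", "time_point", "replicate")
  if (!all(need %in% colnames(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (ncol(values) != nrow(design))
    stop("design rows (", nrow(design), ") must match sample columns (",
         ncol(values), ")")
  if (anyDuplicated(design$sample_id)) stop("sample ids must be unique")
  if (!is.null(colnames(values)) && !identical(colnames(values), as.character(design$sample_id)))
    stop("column names of 'values' disagree with design sample ids")
  colnames(values) <- design$sample_id
  if (is.null(timeLevels)) timeLevels <- unique(as.character(design$time_point))
  cd <- S4Vectors::DataFrame(condition = as.character(design$condition),
                             time_point = as.character(design$time_point),
                             replicate = as.integer(design$replicate),
                             row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd,
    metadata = list(time_levels = timeLevels, linear_scale = linearScale))
  new("PPINExpression", se)
}

#' Expression values of a PPINExpression object
#'
#' @param x a [PPINExpression-class] object.
#' @return Numeric matrix, genes x samples.
#' @export
exprsValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' Sample design of a PPINExpression object
#'
#' @param x a [PPINExpression-class] object.
#' @return `data.frame` with columns `sample_id`, `condition`,
#'   `time_point`, `replicate`.
#' @export
sampleDesign <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = rownames(cd), condition = cd$condition,
             time_point = cd$time_point, replicate = cd$replicate,
             row.names = NULL)
}

#' Read a sample design table
#'
#' Expects a delimited table with columns `sample_id`, `condition`,
#' `time_point` and `replicate`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return `data.frame` suitable for [ppinExpression()] /
#'   [readExpressionTable()].
#' @export
readSampleDesign <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "condition", "time_point", "replicate")
  if (!all(need %in% colnames(d)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  d[need]
}

#' Read an expression table against a sample design
#'
#' Reads a delimited table whose header row names the samples and whose
#' first column holds gene ids, reorders the columns to the design order,
#' collapses duplicate gene ids, and applies the configured missing-value
#' policy.
#'
#' @param path file path.
#' @param design sample design `data.frame` (see [readSampleDesign()]);
#'   its `sample_id` values must all appear in the table header.
#' @param sep field separator (tab by default, `","` for CSV).
#' @param collapse rule for duplicate gene ids: keep the duplicate row
#'   with the largest mean (`"max_mean"`, default) or take the per-cell
#'   median of the duplicates (`"median"`).
#' @param missing `"error"` rejects any missing cell (default);
#'   `"drop"` removes rows containing missing values.
#' @param timeLevels,linearScale passed to [ppinExpression()].
#' @return A [PPINExpression-class] object with columns in design order.
#' @export
readExpressionTable <- function(path, design, sep = "\t",
                                collapse = c("max_mean", "median"),
                                missing = c("error", "drop"),
                                timeLevels = NULL, linearScale = TRUE) {
  collapse <- match.arg(collapse)
  missing <- match.arg(missing)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA, comment.char = "")
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("empty expression table: ", path)
  gene_ids <- as.character(tab[[1L]])
  absent <- setdiff(design$sample_id, colnames(tab)[-1L])
  if (length(absent))
    stop("design sample id(s) missing from table header: ",
         paste(absent, collapse = ", "))
  vals <- tab[, as.character(design$sample_id), drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric expression values in column(s): ",
         paste(colnames(vals)[!num], collapse = ", "))
  m <- as.matrix(vals)
  if (anyNA(m)) {
    if (missing == "error")
      stop("missing expression values present and missing policy is 'error'")
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
    if (nrow(m) == 0L) stop("all rows dropped by missing-value policy")
  }
  if (anyDuplicated(gene_ids)) {
    m <- .collapse_duplicates(m, gene_ids, collapse)
    gene_ids <- rownames(m)
  }
  rownames(m) <- gene_ids
  ppinExpression(m, design, timeLevels = timeLevels, linearScale = linearScale)
}

.collapse_duplicates <- function(m, gene_ids, collapse) {
  groups <- split(seq_along(gene_ids), gene_ids)
  rows <- lapply(groups, function(idx) {
    if (length(idx) == 1L) return(m[idx, , drop = TRUE])
    sub <- m[idx, , drop = FALSE]
    if (collapse == "max_mean") sub[which.max(rowMeans(sub)), ]
    else apply(sub, 2, stats::median)
  })
  out <- do.call(rbind, rows)
  # preserve first-appearance order of gene ids
  out[order(vapply(groups, min, 1L)), , drop = FALSE]
}

#' Write an expression table
#'
#' Writes the matrix in the same dialect [readExpressionTable()] consumes
#' (header of sample ids, first column `gene_id`), at 12 significant
#' digits so normalized matrices round-trip losslessly.
#'
#' @param x a [PPINExpression-class] object.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(x, path, sep = "\t") {
  m <- exprsValues(x)
  df <- data.frame(gene_id = rownames(m),
                   signif(m, 12L), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile normalization
#'
#' Forces every sample column to share the empirical distribution of
#' across-column rank means; ties within a column receive the mean of the
#' quantile values they span.  With `scope = "per_time_point"` the
#' normalization is applied separately within each time point's columns.
#'
#' @param x a [PPINExpression-class] object with at least two columns
#'   (a single column is returned unchanged with a warning).
#' @param scope `"all"` (default) pools all samples; `"per_time_point"`
#'   normalizes each time point independently.
#' @return A [PPINExpression-class] object with normalized values.
#' @export
quantileNormalize <- function(x, scope = c("all", "per_time_point")) {
  scope <- match.arg(scope)
  m <- exprsValues(x)
  if (!all(is.finite(m))) stop("non-finite expression values")
  if (ncol(m) < 2L) {
    warning("fewer than two samples; quantile normalization is a no-op")
    return(x)
  }
  if (scope == "all") {
    norm <- limma::normalizeQuantiles(m, ties = TRUE)
  } else {
    norm <- m
    for (tp in unique(sampleDesign(x)$time_point)) {
      cols <- which(sampleDesign(x)$time_point == tp)
      if (length(cols) >= 2L)
        norm[, cols] <- limma::normalizeQuantiles(m[, cols, drop = FALSE],
                                                  ties = TRUE)
    }
  }
  dimnames(norm) <- dimnames(m)
  out <- x
  SummarizedExperiment::assay(out, "exprs") <- norm
  out
}

#' Per-gene case and control group means at a time point
#'
#' Arithmetic means over replicate columns on the linear scale, the
#' quantities reported as case and control average expression.
#'
#' @param x a [PPINExpression-class] object.
#' @param time_point time-point label; case columns are taken at this time
#'   point.
#' @param pooledControl average control columns from all time points
#'   (default `FALSE`: controls at `time_point` only).
#' @return `data.frame` with columns `gene_id`, `case_mean`,
#'   `control_mean`.
#' @export
groupMeans <- function(x, time_point, pooledControl = FALSE) {
  d <- sampleDesign(x)
  caseCols <- which(d$condition == "case" & d$time_point == time_point)
  ctlCols <- if (pooledControl) which(d$condition == "control")
             else which(d$condition == "control" & d$time_point == time_point)
  if (!length(caseCols)) stop("no case samples at time point ", time_point)
  if (!length(ctlCols)) stop("no control samples at time point ", time_point)
  m <- exprsValues(x)
  data.frame(gene_id = rownames(m),
             case_mean = rowMeans(m[, caseCols, drop = FALSE]),
             control_mean = rowMeans(m[, ctlCols, drop = FALSE]),
             row.names = NULL)
}

#' Log2 fold change of case over control means
#'
#' @param case_mean,control_mean positive group means (vectorized).
#' @param pseudocount optional non-negative constant added to both means;
#'   with the default `0`, non-positive means raise an error.
#' @return `log2((case_mean + pseudocount) / (control_mean + pseudocount))`.
#' @examples
#' log2FoldChange(9545, 20349)  # -1.09 at two decimals
#' @export
log2FoldChange <- function(case_mean, control_mean, pseudocount = 0) {
  a <- case_mean + pseudocount
  b <- control_mean + pseudocount
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("group means must be finite")
  if (any(a <= 0) || any(b <= 0))
    stop("group means must be positive (or enable a pseudocount)")
  log2(a / b)
}
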