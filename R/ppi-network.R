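#' Construct a PPI edge list from protein pairs
#'
#' Pairs are case-normalized to upper case, self-loops removed and
#' duplicates collapsed order-insensitively.
#'
#' @param pairs two-column character matrix or data.frame of protein pairs.
#' @param dialect source dialect tag.
#' @param organism optional taxon label the list was filtered to.
#' @param upperCase normalize ids to upper case (default `TRUE`; symbols
#'   are the join key between expression and PPI data and case mismatch is
#'   the dominant join failure).
#' @return A [PPIEdgeList-class] object.
#' @export
ppiEdgeList <- function(pairs, dialect = "plain_tsv", organism = NA_character_,
                        upperCase = TRUE) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  mode(pairs) <- "character"
  pairs <- pairs[nzchar(pairs[, 1L]) & nzchar(pairs[, 2L]), , drop = FALSE]
  if (upperCase) pairs[] <- toupper(pairs)
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs)) {
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, c(2L, 1L)]
    pairs <- pairs[!duplicated(paste(pairs[, 1L], pairs[, 2L], sep = "\r")), ,
                   drop = FALSE]
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  dimnames(pairs) <- NULL
  new("PPIEdgeList", edges = pairs, dialect = dialect,
      organism = as.character(organism))
}

#' Read a PPI edge list
#'
#' Supports plain two-column TSV (optional header) and BioGRID TAB 2.0/3.0
#' dumps, using the official symbol interactor columns and, when an
#' organism filter is given, the organism interactor columns (names for
#' TAB 2.0, names or taxonomy ids for TAB 3.0).
#'
#' @param path file path.
#' @param dialect `"plain_tsv"` or `"biogrid_tab"`.
#' @param organism optional organism filter: both interactors must match
#'   this organism name (or taxid, for TAB 3.0 dumps).
#' @return A [PPIEdgeList-class] object.
#' @export
readPPIEdges <- function(path, dialect = c("plain_tsv", "biogrid_tab"),
                         organism = NULL) {
  dialect <- match.arg(dialect)
  pairs <- switch(dialect,
    plain_tsv = .read_plain_pairs(path),
    biogrid_tab = .read_biogrid(path, organism))
  out <- ppiEdgeList(pairs, dialect = dialect,
                     organism = if (is.null(organism)) NA_character_ else organism)
  if (numEdges(out) == 0L)
    stop("no edges remain after parsing/filtering: ", path)
  out
}

.read_plain_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PPI file: ", path)
  fields <- strsplit(lines, "[\t ]+")
  if (any(lengths(fields) < 2L)) stop("malformed PPI line(s) in ", path)
  pairs <- t(vapply(fields, function(f) f[1:2], character(2)))
  # tolerate a header row
  if (nrow(pairs) > 1L &&
      any(tolower(pairs[1L, ]) %in% c("protein_a", "proteina", "a", "source")))
    pairs <- pairs[-1L, , drop = FALSE]
  pairs
}

.read_biogrid <- function(path, organism) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  symA <- grep("^Official Symbol Interactor A$", colnames(tab))
  symB <- grep("^Official Symbol Interactor B$", colnames(tab))
  if (!length(symA) || !length(symB))
    stop("not a BioGRID TAB file (official symbol columns missing): ", path)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(organism)) {
    sideMatch <- function(side) {
      nms <- grep(paste0("^Organism (Name |ID )?Interactor ", side, "$"),
                  colnames(tab), value = TRUE)
      if (!length(nms)) stop("organism columns missing in BioGRID file")
      # a row matches if any organism column (name or taxid) agrees
      Reduce(`|`, lapply(nms, function(nm)
        tolower(as.character(tab[[nm]])) == tolower(as.character(organism))))
    }
    keep <- sideMatch("A") & sideMatch("B")
  }
  cbind(tab[[symA]], tab[[symB]])[keep, , drop = FALSE]
}

#' Write a protein set as one id per line
#'
#' @param proteins character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProteinSet <- function(proteins, path) {
  writeLines(sort(unique(proteins)), path)
  invisible(path)
}

#' Select the differential protein group
#'
#' Screens genes at one time point either by a classical one-way
#' fixed-effects ANOVA across the case/control groups or by fold change of
#' group means.
#'
#' @param x a [PPINExpression-class] object.
#' @param time_point time-point label.
#' @param method `"fold_change"` (default, genes with
#'   `|log2 FC| > log2(threshold)`) or `"anova"` (genes with one-way
#'   ANOVA p-value below `threshold`; requires >= 2 replicates per group).
#' @param threshold screening threshold: a fold-change ratio (default 1.5)
#'   or an ANOVA p-value cutoff (default 0.05 when `method = "anova"`).
#' @param pooledControl use control columns from all time points.
#' @return Character vector of selected gene ids.
#' @export
selectDifferentialProteins <- function(x, time_point,
                                       method = c("fold_change", "anova"),
                                       threshold = NULL,
                                       pooledControl = FALSE) {
  method <- match.arg(method)
  if (is.null(threshold)) threshold <- if (method == "fold_change") 1.5 else 0.05
  d <- sampleDesign(x)
  caseCols <- which(d$condition == "case" & d$time_point == time_point)
  ctlCols <- if (pooledControl) which(d$condition == "control")
             else which(d$condition == "control" & d$time_point == time_point)
  if (!length(caseCols) || !length(ctlCols))
    stop("both conditions must be present at time point ", time_point)
  m <- exprsValues(x)
  if (method == "fold_change") {
    gm <- groupMeans(x, time_point, pooledControl = pooledControl)
    ok <- gm$case_mean > 0 & gm$control_mean > 0
    lfc <- rep(0, nrow(gm))
    lfc[ok] <- log2(gm$case_mean[ok] / gm$control_mean[ok])
    rownames(m)[ok & abs(lfc) > log2(threshold)]
  } else {
    if (length(caseCols) < 2L || length(ctlCols) < 2L)
      stop("ANOVA screening needs >= 2 replicates per group")
    grp <- factor(c(rep("case", length(caseCols)), rep("control", length(ctlCols))))
    cols <- c(caseCols, ctlCols)
    p <- apply(m[, cols, drop = FALSE], 1L, function(v) {
      if (stats::sd(v) == 0) return(1)
      stats::oneway.test(v ~ grp, var.equal = TRUE)$p.value
    })
    p[is.na(p)] <- 1
    rownames(m)[p < threshold]
  }
}

#' Augment a protein group with highly connected PPI neighbors
#'
#' Adds proteins outside the core group whose number of PPI edges into the
#' core strictly exceeds `minLinks`.  A single augmentation pass is
#' performed (no transitive closure); core proteins are always retained.
#'
#' @param core character vector of core protein ids.
#' @param edges a [PPIEdgeList-class] object.
#' @param minLinks link-count threshold (strict inequality; default 5).
#' @return Character vector: `core` plus the admitted neighbors, sorted.
#' @export
augmentWithNeighbors <- function(core, edges, minLinks = 5L) {
  stopifnot(is(edges, "PPIEdgeList"), minLinks >= 1L)
  core <- toupper(unique(as.character(core)))
  if (!length(core)) return(character(0))
  e <- edges@edges
  inA <- e[, 1L] %in% core
  inB <- e[, 2L] %in% core
  # links from an outside protein into the core
  outside <- c(e[inB & !inA, 1L], e[inA & !inB, 2L])
  counts <- table(outside)
  sort(unique(c(core, names(counts)[counts > minLinks])))
}

#' Build the candidate network
#'
#' Induced subgraph of the PPI edge list on a protein set, with isolated
#' proteins removed and nodes in deterministic lexicographic order.
#'
#' @param proteins character vector of protein ids.
#' @param edges a [PPIEdgeList-class] object.
#' @return A [CandidateNetwork-class] object.
#' @export
buildCandidateNetwork <- function(proteins, edges) {
  stopifnot(is(edges, "PPIEdgeList"))
  proteins <- toupper(unique(as.character(proteins)))
  if (!length(proteins)) stop("empty protein set")
  e <- edges@edges
  keep <- e[, 1L] %in% proteins & e[, 2L] %in% proteins
  e <- e[keep, , drop = FALSE]
  nodes <- sort(unique(as.vector(e)))
  if (!length(nodes))
    stop("all proteins are isolated; no candidate network can be built")
  i <- match(e[, 1L], nodes)
  j <- match(e[, 2L], nodes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = TRUE,
                              dims = c(length(nodes), length(nodes)))
  new("CandidateNetwork", nodes = nodes, adjacency = as(adj, "lMatrix"))
}
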