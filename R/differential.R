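#' Difference matrix of two interaction networks
#'
#' Entrywise case minus control coefficients on the union node index;
#' edges retained in only one condition contribute their full coefficient
#' (the absent side counts as zero).  Disjoint node sets produce a signed
#' block union with a warning, not an error.
#'
#' @param a_case,a_control [InteractionMatrix-class] objects.
#' @return A [DifferenceMatrix-class] object tagged with the case
#'   network's time point.
#' @export
differenceMatrix <- function(a_case, a_control) {
  stopifnot(is(a_case, "InteractionMatrix"), is(a_control, "InteractionMatrix"))
  nodes <- sort(union(a_case@nodes, a_control@nodes))
  if (!length(intersect(a_case@nodes, a_control@nodes)))
    warning("node sets are disjoint; difference is a signed block union")
  expand <- function(a) {
    m <- Matrix::Matrix(0, length(nodes), length(nodes), sparse = TRUE)
    idx <- match(a@nodes, nodes)
    m[idx, idx] <- a@coefficients
    m
  }
  d <- expand(a_case) - expand(a_control)
  new("DifferenceMatrix", nodes = nodes, d = .as_dgc(d),
      timePoint = a_case@timePoint)
}

#' Permutation p-values for the network relevance values
#'
#' Builds the null distribution of each protein's relevance value by
#' randomly permuting the case/control labels of the pooled samples,
#' refitting both networks and recomputing the relevance values `b`
#' times.  P-values use the add-one empirical estimator
#' \eqn{p_i = (1 + \#\{TRV^*_i \ge TRV_i\}) / (1 + b)}, so they lie in
#' \eqn{(0, 1]}.  Identical seed and settings give identical p-values.
#'
#' @param x a [PPINExpression-class] object.
#' @param net a [CandidateNetwork-class] object.
#' @param time_point time-point label of the case slice.
#' @param b number of permutations (>= 1).
#' @param seed integer seed for the permutation draw.
#' @param settings see [inferenceSettings()]; controls pooling of control
#'   samples and the fit parameters, which are held fixed across
#'   permutations.
#' @return `data.frame` with columns `protein`, `trv`, `p_value`.
#' @export
trvPValues <- function(x, net, time_point, b = 100L, seed = 1L,
                       settings = inferenceSettings()) {
  if (b < 1L) stop("b must be >= 1")
  stopifnot(is(x, "PPINExpression"), is(net, "CandidateNetwork"))
  d <- sampleDesign(x)
  caseCols <- which(d$condition == "case" & d$time_point == time_point)
  ctlCols <- if (isTRUE(settings$pooledControl)) which(d$condition == "control")
             else which(d$condition == "control" & d$time_point == time_point)
  nPool <- length(caseCols) + length(ctlCols)
  if (nPool < 4L) stop("need at least 4 pooled samples at time point ", time_point)
  nCase <- length(caseCols)
  if (choose(nPool, nCase) < b)
    warning("fewer distinct label assignments (", choose(nPool, nCase),
            ") than permutations requested; sampling with replacement")
  nodes <- networkNodes(net)
  Xall <- t(exprsValues(x)[nodes, c(caseCols, ctlCols), drop = FALSE])
  nbIdx <- .neighbor_indices(net@adjacency)
  trv_of <- function(caseIdx) {
    Ac <- .fit_network_matrix(Xall[caseIdx, , drop = FALSE], nbIdx,
                              alpha = settings$alpha, orderCap = settings$orderCap,
                              intercept = isTRUE(settings$intercept))$A
    An <- .fit_network_matrix(Xall[-caseIdx, , drop = FALSE], nbIdx,
                              alpha = settings$alpha, orderCap = settings$orderCap,
                              intercept = isTRUE(settings$intercept))$A
    rowSums(abs(Ac - An))
  }
  obs <- trv_of(seq_len(nCase))
  exceed <- integer(length(nodes))
  rs <- .with_seed(seed, {
    for (perm in seq_len(b)) {
      idx <- sample.int(nPool, nCase)
      exceed <- exceed + (trv_of(idx) >= obs)
    }
    exceed
  })
  data.frame(protein = nodes, trv = obs,
             p_value = (1 + rs) / (1 + b), row.names = NULL)
}

## evaluate expr under a local RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Assemble the per-protein relevance table
#'
#' One row per network node in the reporting schema: protein id,
#' relevance value, permutation p-value, case and control average
#' expression, and log2 fold change (two decimals are conventional for
#' display; values are kept at full precision here).
#'
#' @param d a [DifferenceMatrix-class] object.
#' @param pvalues output of [trvPValues()] (matched by protein id).
#' @param means output of [groupMeans()] (matched by gene id).
#' @return `data.frame` with columns `protein`, `trv`, `p_value`,
#'   `case_avg_exp`, `control_avg_exp`, `log2_fc`, ordered by decreasing
#'   `trv` with ties broken by protein id.
#' @export
trvTable <- function(d, pvalues, means) {
  trv <- computeTRV(d)
  prot <- names(trv)
  pv <- pvalues$p_value[match(prot, pvalues$protein)]
  mi <- match(prot, means$gene_id)
  cm <- means$case_mean[mi]
  nm <- means$control_mean[mi]
  lfc <- rep(NA_real_, length(prot))
  ok <- !is.na(cm) & !is.na(nm) & cm > 0 & nm > 0
  lfc[ok] <- log2(cm[ok] / nm[ok])
  out <- data.frame(protein = prot, trv = as.numeric(trv), p_value = pv,
                    case_avg_exp = cm, control_avg_exp = nm, log2_fc = lfc,
                    row.names = NULL)
  out[order(-out$trv, out$protein), , drop = FALSE]
}

#' Screen significant proteins by p-value and fold change
#'
#' Proteins with `p_value < p_threshold`, intersected (by default) with
#' `|log2_fc| > log2(fc_threshold)`.
#'
#' @param records `data.frame` with columns `protein`, `p_value` and
#'   `log2_fc` (see [trvTable()]).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param fc_threshold fold-change ratio cutoff (default 1.5).
#' @param require_fc apply the fold-change filter (default `TRUE`;
#'   `FALSE` reproduces p-value-only screening).
#' @return Character vector of significant protein ids, sorted.
#' @export
screenSignificant <- function(records, p_threshold = 0.05, fc_threshold = 1.5,
                              require_fc = TRUE) {
  if (!nrow(records)) return(character(0))
  keep <- records$p_value < p_threshold
  if (require_fc)
    keep <- keep & !is.na(records$log2_fc) &
      abs(records$log2_fc) > log2(fc_threshold)
  sort(records$protein[keep & !is.na(keep)])
}

#' Core network biomarkers across time points
#'
#' @param sets named list of per-time-point significant protein sets
#'   (>= 2 sets), in time order.
#' @param mode `"all"` intersects every set; `"adjacent"` intersects each
#'   consecutive pair.
#' @return For `"all"` a character vector; for `"adjacent"` a named list
#'   of pairwise intersections (`"tp1-tp2"`, ...).
#' @export
coreBiomarkers <- function(sets, mode = c("all", "adjacent")) {
  mode <- match.arg(mode)
  if (length(sets) < 2L) stop("need at least two significant sets")
  if (mode == "all") return(sort(Reduce(intersect, sets)))
  nm <- names(sets)
  if (is.null(nm)) nm <- as.character(seq_along(sets))
  out <- lapply(seq_len(length(sets) - 1L), function(i)
    sort(intersect(sets[[i]], sets[[i + 1L]])))
  names(out) <- paste(nm[-length(nm)], nm[-1L], sep = "-")
  out
}

#' Classify differential edges by spread around the mean
#'
#' Mean and population (divide-by-N) standard deviation are computed over
#' the nonzero entries of the difference matrix; entries `>= mean + STD`
#' are `"red"`, entries `<= mean - STD` are `"blue"`, the rest
#' `"neutral"`.  With fewer than two nonzero entries, or zero spread
#' (where both rules would fire at once), every edge is neutral.
#'
#' @param d a [DifferenceMatrix-class] object.
#' @return `data.frame` with columns `source`, `target`, `d` and `label`,
#'   one row per nonzero entry, ordered by `source` then `target`.
#' @export
classifyEdges <- function(d) {
  stopifnot(is(d, "DifferenceMatrix"))
  trip <- Matrix::summary(d@d)
  trip <- trip[trip$x != 0, , drop = FALSE]
  out <- data.frame(source = d@nodes[trip$i], target = d@nodes[trip$j],
                    d = trip$x, label = rep("neutral", nrow(trip)),
                    stringsAsFactors = FALSE)
  if (nrow(out) >= 2L) {
    mu <- mean(out$d)
    std <- sqrt(mean((out$d - mu)^2))
    if (std > 0) {
      out$label[out$d >= mu + std] <- "red"
      out$label[out$d <= mu - std] <- "blue"
    }
  }
  out[order(out$source, out$target), , drop = FALSE]
}

#' Export a differential network for Cytoscape
#'
#' Writes `<prefix>.sif` (edge file), `<prefix>-edges.tsv` (difference
#' value and color label per edge), `<prefix>-nodes.tsv` (relevance value,
#' p-value, log2 fold change, and a node size attribute proportional to
#' the relevance value) and `<prefix>.graphml` with the same attributes.
#'
#' @param d a [DifferenceMatrix-class] object.
#' @param trv relevance values over the nodes of `d`
#'   (default `computeTRV(d)`).
#' @param labels edge classification (default `classifyEdges(d)`).
#' @param out_prefix output path prefix.
#' @param p_values,log2_fc optional named per-node attributes.
#' @return Character vector of the written paths, invisibly.
#' @export
exportNetwork <- function(d, trv = computeTRV(d), labels = classifyEdges(d),
                          out_prefix, p_values = NULL, log2_fc = NULL) {
  stopifnot(is(d, "DifferenceMatrix"))
  sif <- paste0(out_prefix, ".sif")
  edgeTsv <- paste0(out_prefix, "-edges.tsv")
  nodeTsv <- paste0(out_prefix, "-nodes.tsv")
  gml <- paste0(out_prefix, ".graphml")
  if (nrow(labels)) {
    writeLines(paste(labels$source, "interacts", labels$target), sif)
  } else writeLines(character(0), sif)
  utils::write.table(labels, edgeTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  att <- function(v) if (is.null(v)) rep(NA_real_, length(d@nodes))
                     else as.numeric(v[d@nodes])
  maxTrv <- max(trv, 0)
  nodeDf <- data.frame(protein = d@nodes, trv = as.numeric(trv[d@nodes]),
                       p_value = att(p_values), log2_fc = att(log2_fc),
                       node_size = if (maxTrv > 0)
                         10 + 40 * as.numeric(trv[d@nodes]) / maxTrv
                       else rep(10, length(d@nodes)))
  utils::write.table(nodeDf, nodeTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    labels[, c("source", "target", "d", "label")],
    directed = TRUE,
    vertices = nodeDf)
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(sif, edgeTsv, nodeTsv, gml))
}
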