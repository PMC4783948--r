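#' Define a synthetic network scenario
#'
#' Parameters of the ground-truth generator.  Coefficients live on an
#' undirected support sampled at `edgeDensity`; the two directed
#' coefficients of an edge share a sign but have independent magnitudes
#' drawn uniformly from `couplingRange`; case matrices copy the control
#' matrix and then shift a recorded fraction of edges by `deltaAlpha`;
#' all matrices are jointly rescaled so the largest spectral radius is at
#' most 0.8 (the fixed-point simulation requires spectral radius < 1).
#' The PPI list offered to the pipeline is the true support plus
#' `falseEdgeFraction` spurious edges.
#'
#' @param nProteins number of proteins `M`.
#' @param edgeDensity fraction of the `M(M-1)/2` pairs that carry a true
#'   edge, in (0, 1).
#' @param couplingRange interval for true coefficient magnitudes.
#' @param perturbedFraction fraction of true edges whose coefficients
#'   differ between case and control, in [0, 1].
#' @param deltaAlpha perturbation size added (with a random shared sign)
#'   to both directed coefficients of a perturbed edge.
#' @param nCase,nControl sample counts per condition (per time point).
#' @param noiseSd standard deviation of the structural noise `w`.
#' @param nTimePoints number of case time points.
#' @param falseEdgeFraction spurious PPI edges, as a fraction of the true
#'   edge count.
#' @param seed integer seed; identical seeds give identical scenarios.
#' @return A named list of class `"SyntheticScenario"`.
#' @export
syntheticScenario <- function(nProteins = 20L, edgeDensity = 0.08,
                              couplingRange = c(0.6, 0.9),
                              perturbedFraction = 0.2, deltaAlpha = 1,
                              nCase = 40L, nControl = 40L, noiseSd = 0.1,
                              nTimePoints = 1L, falseEdgeFraction = 0.25,
                              seed = 1L) {
  stopifnot(nProteins >= 2L, edgeDensity > 0, edgeDensity < 1,
            length(couplingRange) == 2L, couplingRange[1L] > 0,
            couplingRange[2L] >= couplingRange[1L],
            perturbedFraction >= 0, perturbedFraction <= 1,
            nCase >= 1L, nControl >= 1L, noiseSd > 0, nTimePoints >= 1L,
            falseEdgeFraction >= 0)
  structure(list(nProteins = as.integer(nProteins), edgeDensity = edgeDensity,
                 couplingRange = couplingRange,
                 perturbedFraction = perturbedFraction,
                 deltaAlpha = deltaAlpha, nCase = as.integer(nCase),
                 nControl = as.integer(nControl), noiseSd = noiseSd,
                 nTimePoints = as.integer(nTimePoints),
                 falseEdgeFraction = falseEdgeFraction,
                 seed = as.integer(seed)),
            class = "SyntheticScenario")
}

#' Generate ground-truth interaction matrices
#'
#' @param scenario a [syntheticScenario()].
#' @return List with `nodes` (protein ids), `a_control` (true control
#'   matrix), `a_case` (list of per-time-point true case matrices),
#'   `perturbed_edges` (two-column matrix of perturbed pairs, per time
#'   point), `ppi` (a [PPIEdgeList-class]: true support plus false
#'   edges) and `scale` (the applied spectral rescale factor).
#' @export
generateGroundTruth <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  .with_seed(scenario$seed, .generate_truth(scenario))
}

.generate_truth <- function(sc) {
  M <- sc$nProteins
  nodes <- sprintf("P%03d", seq_len(M))
  pairs <- t(utils::combn(M, 2L))
  ne <- round(sc$edgeDensity * nrow(pairs))
  if (ne < 1L) stop("edge density too low: empty graph")
  sel <- sample.int(nrow(pairs), ne)
  E <- pairs[sel, , drop = FALSE]
  Actl <- matrix(0, M, M, dimnames = list(nodes, nodes))
  for (r in seq_len(ne)) {
    i <- E[r, 1L]; j <- E[r, 2L]
    sgn <- sample(c(-1, 1), 1L)
    Actl[i, j] <- sgn * stats::runif(1L, sc$couplingRange[1L], sc$couplingRange[2L])
    Actl[j, i] <- sgn * stats::runif(1L, sc$couplingRange[1L], sc$couplingRange[2L])
  }
  np <- round(sc$perturbedFraction * ne)
  aCase <- vector("list", sc$nTimePoints)
  pertList <- vector("list", sc$nTimePoints)
  for (tp in seq_len(sc$nTimePoints)) {
    pert <- if (np >= 1L) sample.int(ne, np) else integer(0)
    Ak <- Actl
    for (r in pert) {
      i <- E[r, 1L]; j <- E[r, 2L]
      sgn <- sample(c(-1, 1), 1L)
      Ak[i, j] <- Ak[i, j] + sgn * sc$deltaAlpha
      Ak[j, i] <- Ak[j, i] + sgn * sc$deltaAlpha
    }
    aCase[[tp]] <- Ak
    pertList[[tp]] <- cbind(nodes[E[pert, 1L]], nodes[E[pert, 2L]])
  }
  rho <- max(vapply(c(list(Actl), aCase), .spectral_radius, 0))
  scale <- if (rho > 0.8) 0.8 / rho else 1
  Actl <- Actl * scale
  aCase <- lapply(aCase, `*`, scale)
  stopifnot(all(vapply(c(list(Actl), aCase), .spectral_radius, 0) <= 0.8 + 1e-8))
  nf <- round(sc$falseEdgeFraction * ne)
  rest <- setdiff(seq_len(nrow(pairs)), sel)
  fsel <- if (nf >= 1L && length(rest)) sample(rest, min(nf, length(rest)))
          else integer(0)
  ppiPairs <- rbind(E, pairs[fsel, , drop = FALSE])
  ppi <- ppiEdgeList(cbind(nodes[ppiPairs[, 1L]], nodes[ppiPairs[, 2L]]),
                     dialect = "plain_tsv")
  list(nodes = nodes, a_control = Actl, a_case = aCase,
       perturbed_edges = pertList, ppi = ppi, scale = scale)
}

.spectral_radius <- function(a)
  max(Mod(eigen(a, only.values = TRUE)$values))

#' Simulate expression from a true interaction matrix
#'
#' The default generator solves the self-consistent fixed point of the
#' linear association model: per sample, structural noise
#' \eqn{w \sim N(\mu_{base}, \sigma^2)} is drawn i.i.d. per protein and
#' \eqn{x = (I - A)^{-1} w}, so \eqn{x = A x + w} holds exactly (requires
#' spectral radius of `A` below 1).  `method = "acyclic"` instead
#' generates proteins in a random order, each from its already-generated
#' neighbors only (a sensitivity variant; coefficients toward
#' later-generated neighbors are then inactive).  With
#' `positive = TRUE` an affine shift to minimum intensity 1 is applied
#' and recorded in the metadata.
#'
#' @param a_true square coefficient matrix with protein dimnames.
#' @param n_samples number of samples to draw.
#' @param noise_sd standard deviation of `w`.
#' @param seed integer seed.
#' @param mu_base mean of `w` (default 0).
#' @param condition,time_point,replicate_offset design annotation of the
#'   generated samples.
#' @param positive shift intensities to be >= 1 (default `FALSE`:
#'   inference operates on untransformed values since the association
#'   model has no intercept).
#' @param method `"fixed_point"` (default) or `"acyclic"`.
#' @return A [PPINExpression-class] object (proteins x samples);
#'   `metadata(x)$transform` records the applied affine shift.
#' @export
simulateExpression <- function(a_true, n_samples, noise_sd, seed = 1L,
                               mu_base = 0, condition = "case",
                               time_point = "t1", replicate_offset = 0L,
                               positive = FALSE,
                               method = c("fixed_point", "acyclic")) {
  method <- match.arg(method)
  a_true <- as.matrix(a_true)
  M <- nrow(a_true)
  stopifnot(ncol(a_true) == M, n_samples >= 1L, noise_sd > 0)
  nodes <- rownames(a_true)
  if (is.null(nodes)) nodes <- sprintf("P%03d", seq_len(M))
  if (method == "fixed_point" && .spectral_radius(a_true) >= 1)
    stop("spectral radius of a_true must be < 1 for the fixed-point model")
  X <- .with_seed(seed, {
    W <- matrix(stats::rnorm(M * n_samples, mu_base, noise_sd), M, n_samples)
    if (method == "fixed_point") {
      solve(diag(M) - a_true, W)
    } else {
      ord <- sample.int(M)
      X <- matrix(0, M, n_samples)
      done <- logical(M)
      for (i in ord) {
        nb <- which(a_true[i, ] != 0 & done)
        X[i, ] <- W[i, ] + if (length(nb))
          drop(a_true[i, nb, drop = FALSE] %*% X[nb, , drop = FALSE]) else 0
        done[i] <- TRUE
      }
      X
    }
  })
  shift <- 0
  if (positive) {
    shift <- 1 - min(X)
    X <- X + shift
  }
  rownames(X) <- nodes
  ids <- sprintf("%s_%s_%d", condition, time_point,
                 seq_len(n_samples) + replicate_offset)
  colnames(X) <- ids
  design <- data.frame(sample_id = ids, condition = condition,
                       time_point = time_point,
                       replicate = seq_len(n_samples) + replicate_offset)
  out <- ppinExpression(X, design, linearScale = positive)
  S4Vectors::metadata(out)$transform <- c(shift = shift, scale = 1)
  out
}

#' Emit a complete on-disk fixture bundle emulating the study design
#'
#' Writes, under `dir`: `design.tsv` (default: four time points with
#' three case and two control samples each, twenty samples in all),
#' `expression.tsv`, `ppi.tsv` and `truth.json` (true matrices, perturbed
#' edges, scenario parameters, transform) — the exact input dialects the
#' pipeline consumes.  Control samples at every time point are drawn from
#' the single control matrix, matching one pooled normal network.
#' Identical seeds give identical bundles.
#'
#' @param dir output directory (created if needed).
#' @param scenario a [syntheticScenario()]; its `nTimePoints`, `nCase`
#'   and `nControl` define the design (use `nCase = 3, nControl = 2,
#'   nTimePoints = 4` for the historical study layout, or larger counts
#'   for a well-posed estimation benchmark).
#' @param timePoints time-point labels (recycled/truncated to
#'   `scenario$nTimePoints`).
#' @param positive shift intensities to be positive (see
#'   [simulateExpression()]).
#' @return Invisibly, a list with the file paths, the truth object and
#'   the assembled [PPINExpression-class].
#' @export
simulateStudyBundle <- function(dir, scenario = syntheticScenario(
                                  nProteins = 20L, nCase = 3L, nControl = 2L,
                                  nTimePoints = 4L),
                                timePoints = c("4h", "8h", "24h", "72h"),
                                positive = FALSE) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tps <- rep_len(timePoints, scenario$nTimePoints)
  truth <- generateGroundTruth(scenario)
  slices <- list()
  for (k in seq_along(tps)) {
    slices[[length(slices) + 1L]] <-
      simulateExpression(truth$a_case[[k]], scenario$nCase, scenario$noiseSd,
                         seed = scenario$seed + 101L + 7L * k,
                         condition = "case", time_point = tps[k],
                         positive = FALSE)
    slices[[length(slices) + 1L]] <-
      simulateExpression(truth$a_control, scenario$nControl, scenario$noiseSd,
                         seed = scenario$seed + 211L + 7L * k,
                         condition = "control", time_point = tps[k],
                         positive = FALSE)
  }
  vals <- do.call(cbind, lapply(slices, exprsValues))
  design <- do.call(rbind, lapply(slices, sampleDesign))
  shift <- 0
  if (positive) {
    shift <- 1 - min(vals)
    vals <- vals + shift
  }
  x <- ppinExpression(vals, design, timeLevels = unique(tps),
                      linearScale = positive)
  S4Vectors::metadata(x)$transform <- c(shift = shift, scale = 1)
  designPath <- file.path(dir, "design.tsv")
  exprPath <- file.path(dir, "expression.tsv")
  ppiPath <- file.path(dir, "ppi.tsv")
  truthPath <- file.path(dir, "truth.json")
  utils::write.table(design, designPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeExpressionTable(x, exprPath)
  utils::write.table(edgePairs(truth$ppi), ppiPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(scenario = unclass(scenario), nodes = truth$nodes,
         time_points = tps, scale = truth$scale,
         transform = c(shift = shift, scale = 1),
         a_control = truth$a_control,
         a_case = truth$a_case,
         perturbed_edges = lapply(truth$perturbed_edges, function(m)
           apply(m, 1L, paste, collapse = "|"))),
    truthPath, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(list(paths = list(design = designPath, expression = exprPath,
                              ppi = ppiPath, truth = truthPath),
                 truth = truth, expression = x, time_points = tps))
}

#' Recovery metrics of an estimated interaction matrix
#'
#' Edge precision and recall compare the off-diagonal nonzero supports of
#' the estimate and the truth; the coefficient RMSE is taken over the
#' true-support entries.  When relevance values and the perturbed node
#' set are supplied, the rank-AUC of the relevance values for perturbed
#' versus unperturbed nodes is added.
#'
#' @param a_true,a_hat square matrices on the same node index (dimnames
#'   are used to align when present).
#' @param trv optional named relevance-value vector.
#' @param perturbed_nodes optional character vector of perturbed node ids.
#' @return Named list: `edge_precision`, `edge_recall`,
#'   `coefficient_rmse`, `trv_rank_auc` (`NA` when not computable).
#' @export
recoveryMetrics <- function(a_true, a_hat, trv = NULL, perturbed_nodes = NULL) {
  a_true <- as.matrix(a_true)
  a_hat <- as.matrix(a_hat)
  if (!is.null(rownames(a_true)) && !is.null(rownames(a_hat))) {
    common <- intersect(rownames(a_true), rownames(a_hat))
    a_true <- a_true[common, common, drop = FALSE]
    a_hat <- a_hat[common, common, drop = FALSE]
  }
  stopifnot(all(dim(a_true) == dim(a_hat)))
  off <- !diag(TRUE, nrow(a_true))
  st <- a_true != 0 & off
  sh <- a_hat != 0 & off
  tp <- sum(st & sh)
  prec <- if (sum(sh)) tp / sum(sh) else NA_real_
  rec <- if (sum(st)) tp / sum(st) else NA_real_
  rmse <- if (sum(st)) sqrt(mean((a_hat[st] - a_true[st])^2)) else NA_real_
  auc <- NA_real_
  if (!is.null(trv) && !is.null(perturbed_nodes)) {
    pos <- names(trv) %in% perturbed_nodes
    if (any(pos) && any(!pos)) {
      r <- rank(trv)
      auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
        (sum(pos) * sum(!pos))
    }
  }
  list(edge_precision = prec, edge_recall = rec, coefficient_rmse = rmse,
       trv_rank_auc = auc)
}
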