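#' Least-squares fit without intercept
#'
#' Minimizes \eqn{\|y - X\beta\|^2}.  On rank-deficient designs the
#' minimum-norm minimizer is returned (singular-value pseudo-inverse with
#' small singular values zeroed at the conventional relative tolerance).
#' With zero regressors the fit is empty and `rss = sum(y^2)`.
#'
#' @param y numeric response vector, length `n`.
#' @param x numeric regressor matrix, `n` rows (may have zero columns).
#' @return List with `coefficients` (length `ncol(x)`) and `rss`, the
#'   attained minimum.
#' @examples
#' x <- cbind(a = c(1, 2, 3))
#' fitLeastSquares(2 * x[, 1], x)  # coefficient 2, rss 0
#' @export
fitLeastSquares <- function(y, x) {
  y <- as.numeric(y)
  if (is.null(x) || NCOL(x) == 0L || length(x) == 0L)
    return(list(coefficients = numeric(0), rss = sum(y^2)))
  x <- as.matrix(x)
  if (!all(is.finite(y)) || !all(is.finite(x)))
    stop("non-finite values in regression inputs")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  s <- svd(x)
  tol <- max(dim(x)) * max(s$d, 0) * .Machine$double.eps
  pos <- s$d > tol
  beta <- if (any(pos))
    drop(s$v[, pos, drop = FALSE] %*%
           ((crossprod(s$u[, pos, drop = FALSE], y)) / s$d[pos]))
  else rep(0, ncol(x))
  names(beta) <- colnames(x)
  list(coefficients = beta, rss = sum((y - drop(x %*% beta))^2))
}

#' Akaike information criterion for a regression of order k
#'
#' The Gaussian-likelihood form for order selection,
#' \eqn{n \log(\max(RSS, \epsilon)/n) + 2k} with \eqn{\epsilon = 10^{-12}}
#' guarding exact fits.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n number of samples (> 0).
#' @param k number of regressors (>= 0).
#' @return The AIC score (vectorized over `rss`/`k`).
#' @examples
#' aicScore(2, 8, 3)  # 8 * log(0.25) + 6
#' @export
aicScore <- function(rss, n, k) {
  if (any(n <= 0)) stop("n must be positive")
  n * log(pmax(rss, 1e-12) / n) + 2 * k
}

#' Rank candidate interactors by absolute correlation with the target
#'
#' Candidates are sorted by descending `|Pearson r|` with the target,
#' ties broken lexicographically by candidate id; zero-variance candidates
#' get correlation 0 and sort last.
#'
#' @param y target expression vector.
#' @param x candidate matrix, one column per candidate (colnames are the
#'   candidate ids).
#' @return Character vector of candidate ids in rank order (column indices
#'   as character when `x` has no colnames).
#' @export
rankCandidates <- function(y, x) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("at least one candidate is required")
  ids <- colnames(x)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(x)))
  r <- .safe_cor(y, x)
  ids[order(-abs(r), ids)]
}

.safe_cor <- function(y, x) {
  sy <- stats::sd(y)
  sx <- apply(x, 2L, stats::sd)
  r <- rep(0, ncol(x))
  ok <- sx > 0 & sy > 0
  if (any(ok)) r[ok] <- drop(stats::cor(y, x[, ok, drop = FALSE]))
  r[!is.finite(r)] <- 0
  r
}

#' Select the model order by AIC over the ranked candidate prefix
#'
#' Fits the nested models over the prefix of the `|r|`-ranked candidates
#' for orders `k = 0 .. min(ncol(x), n - 2)` (the cap keeps the residual
#' degrees of freedom of the subsequent t-test positive) and returns the
#' order minimizing [aicScore()]; ties go to the smaller order.
#'
#' @param y target expression vector.
#' @param x candidate matrix (zero columns allowed: order 0).
#' @param ranking optional precomputed candidate ranking
#'   (see [rankCandidates()]).
#' @param orderCap optional additional cap on the maximum order.
#' @return List with `order` (the chosen `k*`), `ranking`, `rss` and
#'   `aic` (traces over `k = 0 .. K`).
#' @export
selectModelOrder <- function(y, x, ranking = NULL, orderCap = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  x <- as.matrix(x)
  if (ncol(x) == 0L)
    return(list(order = 0L, ranking = character(0),
                rss = sum(y^2), aic = aicScore(sum(y^2), n, 0L)))
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  if (is.null(ranking)) ranking <- rankCandidates(y, x)
  K <- min(length(ranking), n - 2L)
  if (!is.null(orderCap)) K <- min(K, orderCap)
  K <- max(K, 0L)
  ranking <- ranking[seq_len(K)]
  rss <- c(sum(y^2), .nested_rss(y, x[, ranking, drop = FALSE]))
  aic <- aicScore(rss, n, 0:K)
  list(order = which.min(aic) - 1L, ranking = ranking, rss = rss, aic = aic)
}

## rss of the nested models over the column prefix (monotone non-increasing)
.nested_rss <- function(y, x) {
  K <- ncol(x)
  if (K == 0L) return(numeric(0))
  qrx <- qr(x)
  if (qrx$rank == K && all(qrx$pivot == seq_len(K))) {
    qty <- qr.qty(qrx, y)[seq_len(K)]
    rss <- sum(y^2) - cumsum(qty^2)
  } else {
    rss <- vapply(seq_len(K), function(k)
      fitLeastSquares(y, x[, seq_len(k), drop = FALSE])$rss, 0)
  }
  pmax(rss, 0)
}

#' Prune regression coefficients by Student's t-test
#'
#' Computes classical OLS inference for the chosen-order regression
#' (standard errors from \eqn{\hat\sigma^2 (X^T X)^{-1}} with
#' \eqn{\hat\sigma^2 = RSS/(n-k)}, two-sided p-values on \eqn{n-k}
#' degrees of freedom), removes coefficients with `p > alpha`, and refits
#' once on the survivors.  If \eqn{X^T X} is singular the regressors drop
#' to the largest full-rank prefix first; with zero residual degrees of
#' freedom pruning is skipped with a warning and all coefficients are
#' retained and flagged.
#'
#' @param y target expression vector.
#' @param x chosen-order regressor matrix (columns named by candidate id).
#' @param alpha two-sided pruning level (default 0.05).
#' @return List with `retained` (ids), `coefficients` (refit on the
#'   survivors), `t_stats`, `p_values`, `sigma2`, `df`, `rss` (of the
#'   refit model) and `flagged` (`TRUE` when pruning was skipped).
#' @export
pruneByTtest <- function(y, x, alpha = 0.05) {
  y <- as.numeric(y)
  n <- length(y)
  x <- as.matrix(x)
  if (ncol(x) == 0L)
    return(list(retained = character(0), coefficients = numeric(0),
                t_stats = numeric(0), p_values = numeric(0),
                sigma2 = sum(y^2) / max(n, 1L), df = n, rss = sum(y^2),
                flagged = FALSE))
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  rank <- qr(x)$rank
  if (rank < ncol(x)) {
    # largest full-rank prefix
    k <- 0L
    for (j in seq_len(ncol(x))) {
      if (qr(x[, seq_len(j), drop = FALSE])$rank == j) k <- j else break
    }
    x <- x[, seq_len(max(k, 1L)), drop = FALSE]
  }
  k <- ncol(x)
  df <- n - k
  fit <- fitLeastSquares(y, x)
  if (df <= 0L) {
    warning("zero residual degrees of freedom; t-test pruning skipped")
    return(list(retained = colnames(x), coefficients = fit$coefficients,
                t_stats = rep(NA_real_, k), p_values = rep(NA_real_, k),
                sigma2 = NA_real_, df = df, rss = fit$rss, flagged = TRUE))
  }
  sigma2 <- fit$rss / df
  xtxi <- tryCatch(chol2inv(chol(crossprod(x))), error = function(e) NULL)
  if (is.null(xtxi)) xtxi <- solve(crossprod(x) + diag(1e-10, k))
  se <- sqrt(pmax(sigma2 * diag(xtxi), 0))
  tstat <- ifelse(se > 0, fit$coefficients / se,
                  ifelse(fit$coefficients == 0, 0, Inf))
  pval <- 2 * stats::pt(-abs(tstat), df)
  keep <- pval <= alpha
  names(tstat) <- names(pval) <- colnames(x)
  if (!any(keep))
    return(list(retained = character(0), coefficients = numeric(0),
                t_stats = tstat, p_values = pval, sigma2 = sigma2, df = df,
                rss = sum(y^2), flagged = FALSE))
  refit <- fitLeastSquares(y, x[, keep, drop = FALSE])
  list(retained = colnames(x)[keep], coefficients = refit$coefficients,
       t_stats = tstat, p_values = pval, sigma2 = sigma2, df = df,
       rss = refit$rss, flagged = FALSE)
}

#' Fit one protein's association model
#'
#' The full per-target path: rank candidates by `|Pearson r|`, choose the
#' model order by AIC over the ranked prefix ([selectModelOrder()]), prune
#' the chosen-order coefficients by Student's t-test and refit once on the
#' survivors ([pruneByTtest()]).
#'
#' @param y target expression vector.
#' @param x candidate interactor matrix (columns named by interactor id).
#' @param alpha t-test pruning level.
#' @param orderCap optional cap on the AIC-searched order.
#' @return A `list` fit record: `candidates`, `ranking`, `aic_trace`,
#'   `rss_trace`, `chosen_order`, `t_stats`, `p_values`, `retained`,
#'   `alpha_hat` (named coefficients of the retained interactors),
#'   `sigma2_hat`, `df` and `flagged`.
#' @export
fitProteinModel <- function(y, x, alpha = 0.05, orderCap = NULL) {
  x <- as.matrix(x)
  if (ncol(x) && is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  sel <- selectModelOrder(y, x, orderCap = orderCap)
  k <- sel$order
  if (k == 0L) {
    pr <- pruneByTtest(y, x[, integer(0), drop = FALSE], alpha)
  } else {
    pr <- pruneByTtest(y, x[, sel$ranking[seq_len(k)], drop = FALSE], alpha)
  }
  list(candidates = colnames(x), ranking = sel$ranking,
       aic_trace = sel$aic, rss_trace = sel$rss, chosen_order = k,
       t_stats = pr$t_stats, p_values = pr$p_values,
       retained = pr$retained, alpha_hat = pr$coefficients,
       sigma2_hat = if (is.na(pr$sigma2)) pr$rss / max(length(y), 1L)
                    else pr$rss / max(pr$df + (pr$df <= 0), 1L),
       df = pr$df, flagged = pr$flagged)
}

#' Inference settings
#'
#' @param alpha two-sided t-test pruning level.
#' @param orderCap optional cap on the AIC-searched model order (on top of
#'   the built-in `n - 2` cap).
#' @param intercept include an intercept by mean-centering target and
#'   regressors within the fitted sample slice (default `FALSE`: the
#'   association model has no intercept).
#' @param pooledControl estimate one control network from all control
#'   samples across time points (default `TRUE`; per-time-point control
#'   fitting when `FALSE`).
#' @param allowDegenerate allow condition slices with fewer than 3 samples
#'   (the order cap `n - 2` then limits, possibly to zero, what can be
#'   fitted) instead of raising an error.
#' @return A named list of settings.
#' @export
inferenceSettings <- function(alpha = 0.05, orderCap = NULL, intercept = FALSE,
                              pooledControl = TRUE, allowDegenerate = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  list(alpha = alpha, orderCap = orderCap, intercept = intercept,
       pooledControl = pooledControl, allowDegenerate = allowDegenerate)
}

## one protein's rank -> AIC order -> t-prune -> refit path on plain indices.
## y: response; Xc: candidate columns (in candidate-index order, which for
## network fits is the lexicographic node order, the documented tie-break).
## Returns integer positions into Xc of the retained candidates + their
## refit coefficients.  Must agree numerically with fitProteinModel().
.fit_protein_fast <- function(y, Xc, alpha, orderCap = NULL) {
  n <- length(y)
  p <- ncol(Xc)
  sy <- sqrt(sum((y - mean(y))^2))
  r <- if (sy > 0) suppressWarnings(drop(stats::cor(y, Xc))) else rep(0, p)
  r[!is.finite(r)] <- 0
  ord <- order(-abs(r))
  K <- min(p, n - 2L)
  if (!is.null(orderCap)) K <- min(K, orderCap)
  if (K < 1L) return(list(idx = integer(0), beta = numeric(0)))
  ord <- ord[seq_len(K)]
  Xr <- Xc[, ord, drop = FALSE]
  qrx <- qr(Xr)
  if (qrx$rank < K || !all(qrx$pivot == seq_len(K))) {
    # rare rank-deficient case: fall back to the reference path
    colnames(Xc) <- sprintf("c%06d", seq_len(p))
    fit <- fitProteinModel(y, Xc, alpha = alpha, orderCap = orderCap)
    return(list(idx = as.integer(sub("^c", "", fit$retained)),
                beta = fit$alpha_hat))
  }
  qty <- qr.qty(qrx, y)
  rssTot <- sum(y^2)
  rss <- pmax(rssTot - cumsum(qty[seq_len(K)]^2), 0)
  aic <- aicScore(c(rssTot, rss), n, 0:K)
  k <- which.min(aic) - 1L
  if (k == 0L) return(list(idx = integer(0), beta = numeric(0)))
  R1 <- qr.R(qrx)[seq_len(k), seq_len(k), drop = FALSE]
  beta <- backsolve(R1, qty[seq_len(k)])
  df <- n - k
  sigma2 <- rss[k] / df
  Rinv <- backsolve(R1, diag(k))
  se <- sqrt(pmax(sigma2 * rowSums(Rinv^2), 0))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  pval <- 2 * stats::pt(-abs(tstat), df)
  keep <- pval <= alpha
  if (!any(keep)) return(list(idx = integer(0), beta = numeric(0)))
  Xk <- Xr[, which(keep), drop = FALSE]
  refit <- qr.coef(qr(Xk), y)
  refit[is.na(refit)] <- 0
  list(idx = ord[which(keep)], beta = as.numeric(refit))
}

## fast internal fitter: X is samples x proteins (all nodes of the network),
## nbIdx the per-node candidate index list; returns dense M x M coefficient
## matrix (and optionally the per-node diagnostic records from the
## reference per-protein path)
.fit_network_matrix <- function(X, nbIdx, alpha = 0.05, orderCap = NULL,
                                intercept = FALSE, diagnostics = FALSE) {
  M <- ncol(X)
  n <- nrow(X)
  if (intercept) X <- scale(X, center = TRUE, scale = FALSE)
  A <- matrix(0, M, M)
  fits <- if (diagnostics) vector("list", M) else NULL
  for (i in seq_len(M)) {
    cand <- nbIdx[[i]]
    if (!length(cand)) {
      if (diagnostics)
        fits[[i]] <- list(candidates = character(0), chosen_order = 0L,
                          retained = character(0), alpha_hat = numeric(0),
                          sigma2_hat = sum(X[, i]^2) / n, df = n, flagged = FALSE)
      next
    }
    if (diagnostics) {
      xc <- X[, cand, drop = FALSE]
      colnames(xc) <- colnames(X)[cand]
      fit <- fitProteinModel(X[, i], xc, alpha = alpha, orderCap = orderCap)
      if (length(fit$retained))
        A[i, cand[match(fit$retained, colnames(xc))]] <- fit$alpha_hat
      fits[[i]] <- fit
    } else {
      fit <- .fit_protein_fast(X[, i], X[, cand, drop = FALSE], alpha, orderCap)
      if (length(fit$idx)) A[i, cand[fit$idx]] <- fit$beta
    }
  }
  if (diagnostics) names(fits) <- colnames(X)
  list(A = A, fits = fits)
}

#' Fit a condition-specific interaction network
#'
#' Restricts the expression matrix to one condition (and, for case
#' networks, one time point), then runs the per-protein association fit
#' ([fitProteinModel()]) for every node of the candidate network and
#' assembles the retained coefficients \eqn{\hat\alpha_{ij}} into a sparse
#' interaction matrix.
#'
#' @param x a [PPINExpression-class] object; its gene set must cover the
#'   network nodes.
#' @param net a [CandidateNetwork-class] object.
#' @param condition `"case"` or `"control"`.
#' @param time_point time-point label; required for `condition = "case"`,
#'   and for `condition = "control"` when `settings$pooledControl` is
#'   `FALSE`.
#' @param settings see [inferenceSettings()].
#' @return An [InteractionMatrix-class] object with per-node diagnostics.
#' @export
fitConditionNetwork <- function(x, net, condition = c("case", "control"),
                                time_point = NULL,
                                settings = inferenceSettings()) {
  condition <- match.arg(condition)
  stopifnot(is(x, "PPINExpression"), is(net, "CandidateNetwork"))
  nodes <- networkNodes(net)
  if (!length(nodes)) stop("empty candidate network")
  missingGenes <- setdiff(nodes, rownames(x))
  if (length(missingGenes))
    stop("network nodes absent from expression matrix: ",
         paste(utils::head(missingGenes, 5L), collapse = ", "))
  d <- sampleDesign(x)
  cols <- if (condition == "case") {
    if (is.null(time_point)) stop("time_point is required for the case network")
    which(d$condition == "case" & d$time_point == time_point)
  } else if (isTRUE(settings$pooledControl)) {
    which(d$condition == "control")
  } else {
    if (is.null(time_point))
      stop("time_point is required for per-time-point control fitting")
    which(d$condition == "control" & d$time_point == time_point)
  }
  if (length(cols) < 3L && !isTRUE(settings$allowDegenerate))
    stop("degenerate design: only ", length(cols), " sample(s) in the ",
         condition, " slice (set allowDegenerate to fit anyway)")
  X <- t(exprsValues(x)[nodes, cols, drop = FALSE])
  res <- .fit_network_matrix(X, .neighbor_indices(net@adjacency),
                             alpha = settings$alpha,
                             orderCap = settings$orderCap,
                             intercept = isTRUE(settings$intercept),
                             diagnostics = TRUE)
  new("InteractionMatrix", nodes = nodes,
      coefficients = .as_dgc(res$A),
      condition = condition,
      timePoint = if (is.null(time_point)) NA_character_ else time_point,
      fits = res$fits)
}

#' Write an interaction matrix with its fit diagnostics
#'
#' Writes a three-column TSV (`source`, `target`, `alpha_hat`; `source` is
#' the regression target row) and a JSON sidecar (`<path>.json`) with the
#' per-node chosen order, residual variance and degrees of freedom.
#'
#' @param a an [InteractionMatrix-class] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeInteractionMatrix <- function(a, path) {
  trip <- Matrix::summary(a@coefficients)
  df <- data.frame(source = a@nodes[trip$i], target = a@nodes[trip$j],
                   alpha_hat = trip$x)
  df <- df[df$alpha_hat != 0, , drop = FALSE]
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  diag <- lapply(a@fits, function(f)
    list(chosen_order = f$chosen_order, n_retained = length(f$retained),
         sigma2 = f$sigma2_hat, df = f$df,
         flagged = isTRUE(f$flagged)))
  jsonlite::write_json(
    list(condition = a@condition, time_point = a@timePoint, nodes = diag),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
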