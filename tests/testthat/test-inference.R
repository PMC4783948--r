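test_that("least squares matches the normal-equations oracle", {
  x <- cbind(a = c(1, 2, 3, 4))
  f <- fitLeastSquares(2 * x[, 1], x)
  expect_equal(unname(f$coefficients), 2)
  expect_equal(f$rss, 0)
  expect_equal(fitLeastSquares(c(1, 2), NULL)$rss, 5)

  set.seed(42)
  for (r in 1:50) {
    n <- sample(3:10, 1)
    k <- sample(1:min(4, n - 1), 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n)
    beta <- fitLeastSquares(y, X)$coefficients
    oracle <- solve(t(X) %*% X, t(X) %*% y)  # normal equations
    expect_equal(unname(beta), drop(oracle), tolerance = 1e-8)
  }
  expect_error(fitLeastSquares(c(1, NA), cbind(1:2)), "finite")
})

test_that("rank-deficient designs give the minimum-norm solution", {
  set.seed(7)
  X <- matrix(rnorm(12), 6, 2)
  Xd <- cbind(X, X[, 1])  # duplicated regressor
  y <- rnorm(6)
  f <- fitLeastSquares(y, Xd)
  pinv <- MASS::ginv(Xd)   # independent pseudo-inverse oracle
  betaOracle <- drop(pinv %*% y)
  expect_equal(drop(Xd %*% f$coefficients), drop(Xd %*% betaOracle),
               tolerance = 1e-8)
  expect_equal(unname(f$coefficients), betaOracle, tolerance = 1e-8)
  # any other minimizer has no smaller norm
  alt <- f$coefficients + c(1, 0, -1)  # same fitted values (null-space move)
  expect_equal(drop(Xd %*% alt), drop(Xd %*% f$coefficients), tolerance = 1e-10)
  expect_lt(sum(f$coefficients^2), sum(alt^2))
})

test_that("AIC scoring follows n*log(rss/n) + 2k", {
  expect_lt(aicScore(3, 10, 1), aicScore(3, 10, 2))
  expect_equal(aicScore(8, 8, 5), 10)           # rss/n = 1
  expect_equal(aicScore(2, 8, 3), 8 * log(0.25) + 6)
  expect_error(aicScore(1, 0, 0), "positive")
  # exact fits are guarded, not -Inf
  expect_true(is.finite(aicScore(0, 10, 2)))
})

test_that("candidates rank by |Pearson r| with deterministic ties", {
  expect_equal(rankCandidates(rnorm(5), cbind(only = rnorm(5))), "only")
  set.seed(1)
  x1 <- rnorm(20); noise <- rnorm(20)
  expect_equal(rankCandidates(x1, cbind(a = noise, b = x1))[1], "b")
  # hand-computed correlations on a 5-sample fixture
  y <- c(1, 2, 3, 4, 5)
  xs <- cbind(c1 = c(1.1, 2.3, 2.9, 3.6, 5.2),
              c2 = -c(0.9, 2.1, 3.0, 4.2, 4.9),
              c3 = c(3, 1, 4, 1, 5))
  r <- apply(xs, 2, function(v)
    sum((v - mean(v)) * (y - mean(y))) /
      sqrt(sum((v - mean(v))^2) * sum((y - mean(y))^2)))
  expect_equal(rankCandidates(y, xs), names(sort(-abs(r))))
  # zero-variance candidate sorts last with r = 0
  xz <- cbind(z = rep(2, 5), good = y + 0.1)
  expect_equal(rankCandidates(y, xz), c("good", "z"))
})

test_that("model order selection caps at n-2 and nests rss monotonically", {
  set.seed(9)
  n <- 12
  X <- matrix(rnorm(n * 15), n, 15)
  colnames(X) <- sprintf("c%02d", 1:15)
  y <- rnorm(n)
  sel <- selectModelOrder(y, X)
  expect_lte(sel$order, n - 2)
  expect_equal(length(sel$rss), min(15, n - 2) + 1)
  expect_true(all(diff(sel$rss) <= 1e-10))          # non-increasing
  expect_equal(sel$order, which.min(sel$aic) - 1)
  expect_equal(selectModelOrder(y, X[, integer(0)])$order, 0L)

  # a dominant true regressor always enters the chosen model
  for (s in 1:20) {
    set.seed(100 + s)
    Xs <- matrix(rnorm(30 * 6), 30, 6,
                 dimnames = list(NULL, sprintf("v%d", 1:6)))
    ys <- 1.5 * Xs[, 1] + rnorm(30, 0, 0.01)
    sels <- selectModelOrder(ys, Xs)
    expect_equal(sels$ranking[1], "v1")
    expect_gte(sels$order, 1L)
    fit <- fitProteinModel(ys, Xs)
    expect_true("v1" %in% fit$retained)
  }
})

test_that("t-test pruning matches classical OLS inference", {
  set.seed(4)
  n <- 30
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("s", "d1", "d2")))
  y <- 2 * X[, "s"] + rnorm(n)
  pr <- pruneByTtest(y, X, alpha = 0.05)
  # independent oracle: stats::lm with no intercept
  lmfit <- summary(lm(y ~ 0 + X))$coefficients
  expect_equal(unname(pr$t_stats), unname(lmfit[, "t value"]), tolerance = 1e-8)
  expect_equal(unname(pr$p_values), unname(lmfit[, "Pr(>|t|)"]), tolerance = 1e-8)
  expect_true("s" %in% pr$retained)
  expect_false("d1" %in% pr$retained && "d2" %in% pr$retained)
  # refit happened once: coefficients are the survivors-only fit
  refit <- fitLeastSquares(y, X[, pr$retained, drop = FALSE])
  expect_equal(pr$coefficients, refit$coefficients)

  # k = 0 is legal and empty
  pr0 <- pruneByTtest(y, X[, integer(0)])
  expect_identical(pr0$retained, character(0))
})

test_that("exogenous-regressor coefficient recovery is accurate at n = 200", {
  # per-target reading of the association model: y = X beta + w with
  # noise sd set to 0.1x the signal sd
  set.seed(77)
  errs <- replicate(10, {
    X <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(NULL, sprintf("g%d", 1:4)))
    beta <- runif(4, 0.5, 1) * sample(c(-1, 1), 4, TRUE)
    signal <- drop(X %*% beta)
    y <- signal + rnorm(200, 0, 0.1 * sd(signal))
    fit <- fitProteinModel(y, X)
    est <- setNames(rep(0, 4), colnames(X))
    est[fit$retained] <- fit$alpha_hat
    sqrt(mean((est - beta)^2))
  })
  expect_lte(mean(errs), 0.05)
})

test_that("condition networks are deterministic and scale-equivariant", {
  sc <- syntheticScenario(nProteins = 15, seed = 6)
  tr <- generateGroundTruth(sc)
  net <- buildCandidateNetwork(tr$nodes, tr$ppi)
  x <- truth_expression(tr, 20, 20, seed = 30)
  a1 <- fitConditionNetwork(x, net, "case", "4h")
  a2 <- fitConditionNetwork(x, net, "case", "4h")
  expect_identical(as.matrix(coefficientMatrix(a1)),
                   as.matrix(coefficientMatrix(a2)))
  # multiplying all expression by c > 0 leaves alpha-hat unchanged
  xs <- ppinExpression(exprsValues(x) * 3.7, sampleDesign(x),
                       linearScale = FALSE)
  a3 <- fitConditionNetwork(xs, net, "case", "4h")
  expect_equal(as.matrix(coefficientMatrix(a3)),
               as.matrix(coefficientMatrix(a1)), tolerance = 1e-9)
  # coefficients live only on candidate edges, diagonal empty
  A <- as.matrix(coefficientMatrix(a1))
  expect_true(all(A[!as.matrix(net@adjacency)] == 0))
  expect_true(all(diag(A) == 0))
})

test_that("degenerate condition slices error unless explicitly allowed", {
  sc <- syntheticScenario(nProteins = 10, seed = 13)
  tr <- generateGroundTruth(sc)
  net <- buildCandidateNetwork(tr$nodes, tr$ppi)
  x <- truth_expression(tr, 2, 8, seed = 14)
  expect_error(fitConditionNetwork(x, net, "case", "4h"), "degenerate")
  a <- fitConditionNetwork(x, net, "case", "4h",
                           inferenceSettings(allowDegenerate = TRUE))
  expect_s4_class(a, "InteractionMatrix")  # order capped at n - 2 = 0
  expect_equal(length(a@coefficients@x), 0L)
})

test_that("interaction matrices serialize with diagnostics sidecar", {
  sc <- syntheticScenario(nProteins = 12, seed = 19)
  tr <- generateGroundTruth(sc)
  net <- buildCandidateNetwork(tr$nodes, tr$ppi)
  x <- truth_expression(tr, 20, 20, seed = 20)
  a <- fitConditionNetwork(x, net, "case", "4h")
  path <- tempfile(fileext = ".tsv")
  writeInteractionMatrix(a, path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  A <- as.matrix(coefficientMatrix(a))
  expect_equal(nrow(tab), sum(A != 0))
  for (r in seq_len(nrow(tab)))
    expect_equal(A[tab$source[r], tab$target[r]], tab$alpha_hat[r])
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$condition, "case")
  expect_equal(length(side$nodes), length(networkNodes(net)))
})
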