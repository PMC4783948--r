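test_that("difference matrices subtract entrywise on the union index", {
  a <- make_interaction(list(list("A", "B", 0.5)), c("A", "B"))
  b <- make_interaction(list(list("A", "B", 0.2), list("B", "A", 0.1)),
                        c("A", "B"), "control", NA_character_)
  d <- differenceMatrix(a, b)
  dm <- as.matrix(coefficientMatrix(d))
  expect_equal(dm["A", "B"], 0.3)
  expect_equal(dm["B", "A"], -0.1)
  # identical networks give the zero matrix
  dz <- differenceMatrix(a, a)
  expect_equal(sum(abs(coefficientMatrix(dz))), 0)
  # antisymmetry
  drev <- differenceMatrix(b, a)
  expect_equal(as.matrix(coefficientMatrix(drev)), -dm)
  # one-sided nodes keep their full coefficient against an implicit zero
  cOnly <- make_interaction(list(list("C", "D", 0.7)), c("C", "D"))
  expect_warning(du <- differenceMatrix(cOnly, b), "disjoint")
  expect_equal(as.matrix(coefficientMatrix(du))["C", "D"], 0.7)
})

test_that("relevance values are row sums of absolute differences", {
  expect_equal(unname(computeTRV(diff_matrix_from(matrix(0, 3, 3)))),
               rep(0, 3))
  d <- diff_matrix_from(rbind(c(0, 1, -2), c(0, 0, 3), c(0, 0, 0)))
  expect_equal(computeTRV(d), c(A = 3, B = 3, C = 0))
  # relabeling invariance: permuting rows+columns permutes TRV identically
  set.seed(15)
  m <- matrix(rnorm(25) * rbinom(25, 1, 0.4), 5, 5); diag(m) <- 0
  p <- sample(5)
  t1 <- computeTRV(diff_matrix_from(m))[p]
  t2 <- computeTRV(diff_matrix_from(m[p, p], nodes = LETTERS[1:5][p]))
  expect_equal(unname(t1), unname(t2))
  # non-negativity, and zero iff the row is all zero
  trv <- computeTRV(diff_matrix_from(m))
  expect_true(all(trv >= 0))
  expect_equal(unname(trv == 0), unname(rowSums(abs(m)) == 0))
})

test_that("relevance values obey the triangle bound", {
  set.seed(33)
  for (r in 1:10) {
    A <- matrix(rnorm(16), 4, 4); B <- matrix(rnorm(16), 4, 4)
    C <- matrix(rnorm(16), 4, 4)
    tAC <- computeTRV(diff_matrix_from(A - C))
    tAB <- computeTRV(diff_matrix_from(A - B))
    tBC <- computeTRV(diff_matrix_from(B - C))
    expect_true(all(tAC <= tAB + tBC + 1e-12))
  }
})

test_that("permutation p-values are valid, deterministic and powered", {
  sc <- syntheticScenario(nProteins = 12, seed = 51)
  tr <- generateGroundTruth(sc)
  net <- buildCandidateNetwork(tr$nodes, tr$ppi)
  x <- truth_expression(tr, 40, 40, seed = 52)
  pv <- trvPValues(x, net, "4h", b = 50, seed = 5)
  expect_true(all(pv$p_value > 0 & pv$p_value <= 1))
  pv2 <- trvPValues(x, net, "4h", b = 50, seed = 5)
  expect_identical(pv, pv2)
  expect_error(trvPValues(x, net, "4h", b = 0), "b must be")

  # a node with strongly perturbed couplings reaches p <= 0.05
  pert <- unique(as.vector(tr$perturbed_edges[[1]]))
  pert <- intersect(pert, pv$protein)
  expect_true(length(pert) >= 1)
  best <- min(pv$p_value[pv$protein %in% pert])
  expect_lte(best, 0.05)

  # tiny pools warn about exhausted label assignments
  xs <- truth_expression(tr, 2, 2, seed = 53)
  expect_warning(trvPValues(xs, net, "4h", b = 50, seed = 1,
                            settings = inferenceSettings(allowDegenerate = TRUE)),
                 "label assignments")
})

test_that("significance screening combines p-value and fold-change filters", {
  empty <- data.frame(protein = character(0), p_value = numeric(0),
                      log2_fc = numeric(0))
  expect_identical(screenSignificant(empty), character(0))
  rec <- data.frame(protein = c("A", "B", "C"),
                    p_value = c(0.01, 0.01, 0.2),
                    log2_fc = c(1.0, 0.3, 2.0))
  expect_identical(screenSignificant(rec), "A")      # 1.0 > log2(1.5)
  expect_setequal(screenSignificant(rec, require_fc = FALSE), c("A", "B"))
  # monotone: relaxing either threshold never shrinks the set
  s0 <- screenSignificant(rec)
  expect_true(all(s0 %in% screenSignificant(rec, p_threshold = 0.2)))
  expect_true(all(s0 %in% screenSignificant(rec, fc_threshold = 1.1)))
})

test_that("core biomarkers intersect across and between time points", {
  four <- c("UBC", "SUMO1", "CDKN1A", "MYC")
  sets <- list(`4h` = c(four, "EZH2"), `8h` = c(four, "RELA"),
               `24h` = c(four, "CDK2", "FN1"), `72h` = c(four, "APP"))
  expect_setequal(coreBiomarkers(sets, "all"), four)
  adj <- coreBiomarkers(sets, "adjacent")
  expect_named(adj, c("4h-8h", "8h-24h", "24h-72h"))
  expect_setequal(adj[["8h-24h"]], four)
  same <- list(c("A", "B"), c("A", "B"))
  expect_setequal(coreBiomarkers(same, "all"), c("A", "B"))
  expect_identical(coreBiomarkers(list("A", "B"), "all"), character(0))
  expect_error(coreBiomarkers(list("A")), "two")
})

test_that("edges classify against mean +/- population SD of nonzero entries", {
  # {1,1,1,5}: mean 2, population SD sqrt(3) -> only the 5 is red
  m <- matrix(0, 3, 3)
  m[1, 2] <- 1; m[1, 3] <- 1; m[2, 3] <- 1; m[3, 1] <- 5
  lab <- classifyEdges(diff_matrix_from(m))
  expect_equal(sort(lab$label), c("neutral", "neutral", "neutral", "red"))
  expect_equal(lab$label[lab$d == 5], "red")
  # sign flip swaps red and blue
  labNeg <- classifyEdges(diff_matrix_from(-m))
  expect_equal(labNeg$label[labNeg$d == -5], "blue")
  expect_equal(sum(labNeg$label == "red"), 0)
  # zero spread: every nonzero entry is neutral by the tie rule
  eq <- matrix(0, 2, 2); eq[1, 2] <- 2; eq[2, 1] <- 2
  expect_equal(unique(classifyEdges(diff_matrix_from(eq))$label), "neutral")
})

test_that("network exports round-trip through GraphML", {
  # empty matrix: valid empty files
  prefix0 <- tempfile()
  files0 <- exportNetwork(diff_matrix_from(matrix(0, 2, 2)),
                          out_prefix = prefix0)
  expect_true(all(file.exists(paste0(prefix0, c(".sif", ".graphml")))))
  expect_equal(length(readLines(paste0(prefix0, ".sif"))), 0L)

  m <- matrix(0, 2, 2); m[1, 2] <- 0.4
  d <- diff_matrix_from(m)
  prefix <- tempfile()
  exportNetwork(d, out_prefix = prefix,
                p_values = c(A = 0.01, B = 0.2), log2_fc = c(A = 1, B = -1))
  expect_equal(length(readLines(paste0(prefix, ".sif"))), 1L)
  g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$d, 0.4)
  expect_equal(sort(igraph::V(g)$trv, decreasing = TRUE)[1], 0.4)
  nodeTab <- read.table(paste0(prefix, "-nodes.tsv"), header = TRUE, sep = "\t")
  expect_equal(nodeTab$node_size[nodeTab$protein == "A"], 50)  # max TRV
})
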