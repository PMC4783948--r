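small_config <- function(dir, ...) {
  defaultRunConfig(
    simulate = list(dir = file.path(dir, "bundle"), n_proteins = 15,
                    n_case = 25, n_control = 25, n_timepoints = 2,
                    time_points = c("4h", "8h"), seed = 7),
    paths = list(expression = file.path(dir, "bundle", "expression.tsv"),
                 design = file.path(dir, "bundle", "design.tsv"),
                 ppi = file.path(dir, "bundle", "ppi.tsv"),
                 out_dir = file.path(dir, "results")),
    screening = list(method = "none"),
    permutation = list(b = 25, seed = 11),
    ...)
}

test_that("configurations validate and round-trip through YAML", {
  cfg <- defaultRunConfig(permutation = list(b = 42))
  path <- tempfile(fileext = ".yaml")
  writeRunConfig(cfg, path)
  back <- readRunConfig(path)
  expect_equal(back, cfg)
  expect_error(validateRunConfig(
    defaultRunConfig(simulate = list(edge_density = 1.5))),
    "simulate.edge_density")
  expect_error(validateRunConfig(
    defaultRunConfig(significance = list(p_threshold = 2))),
    "significance.p_threshold")
  expect_error(validateRunConfig(
    defaultRunConfig(screening = list(method = "magic"))),
    "screening.method")
  expect_error(readRunConfig(tempfile()), "not found")
})

test_that("the pipeline produces a complete, deterministic result directory", {
  dir <- tempfile("wf")
  cfg <- small_config(dir)
  runSimulate(cfg)
  expect_true(all(file.exists(unlist(cfg$paths[c("expression", "design", "ppi")]))))
  suppressMessages(runPipeline(cfg))
  out <- cfg$paths$out_dir
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "normalized_expression.tsv")))
  expect_true(file.exists(file.path(out, "core_all.txt")))
  expect_true(file.exists(file.path(out, "core_adjacent.tsv")))
  for (tp in c("4h", "8h")) {
    td <- file.path(out, paste0("timepoint_", tp))
    for (f in c("candidate_nodes.txt", "a_case.tsv", "a_case.tsv.json",
                "a_control.tsv", "trv_table.tsv", "significant.txt",
                "network.sif", "network.graphml", "network-nodes.tsv",
                "difference_edges.tsv"))
      expect_true(file.exists(file.path(td, f)), label = file.path(td, f))
    tab <- read.table(file.path(td, "trv_table.tsv"), header = TRUE, sep = "\t")
    expect_named(tab, c("protein", "trv", "p_value", "case_avg_exp",
                        "control_avg_exp", "log2_fc"))
    expect_true(all(diff(tab$trv) <= 0))
  }
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 11)
  expect_equal(man$permutations, 25)
  expect_length(man$input_md5, 3)

  # identical config + seed: identical relevance tables
  cfg2 <- small_config(dir)
  cfg2$paths$out_dir <- file.path(dir, "results2")
  suppressMessages(runPipeline(cfg2))
  for (tp in c("4h", "8h"))
    expect_identical(
      readLines(file.path(out, paste0("timepoint_", tp), "trv_table.tsv")),
      readLines(file.path(cfg2$paths$out_dir, paste0("timepoint_", tp),
                          "trv_table.tsv")))
})

test_that("perturbed nodes rise to the top of the pipeline's relevance table", {
  dir <- tempfile("wf")
  cfg <- small_config(dir)
  b <- runSimulate(cfg)
  suppressMessages(runPipeline(cfg))
  aucs <- vapply(seq_along(b$time_points), function(k) {
    tp <- b$time_points[k]
    tab <- read.table(file.path(cfg$paths$out_dir, paste0("timepoint_", tp),
                                "trv_table.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    pert <- unique(as.vector(b$truth$perturbed_edges[[k]]))
    rank_auc(tab$trv, tab$protein %in% pert)
  }, 0)
  expect_gte(mean(aucs), 0.85)
})

test_that("reports list top proteins and core biomarkers stably", {
  dir <- tempfile("wf")
  cfg <- small_config(dir)
  runSimulate(cfg)
  suppressMessages(runPipeline(cfg))
  reportResults(cfg$paths$out_dir, top_n = 5)
  top <- read.table(file.path(cfg$paths$out_dir, "report_4h.tsv"),
                    header = TRUE, sep = "\t")
  expect_lte(nrow(top), 5)
  expect_true(all(diff(top$trv) <= 0))
  # top_n larger than the table: full table, no padding
  reportResults(cfg$paths$out_dir, top_n = 10000)
  full <- read.table(file.path(cfg$paths$out_dir, "report_4h.tsv"),
                     header = TRUE, sep = "\t")
  tab <- read.table(file.path(cfg$paths$out_dir, "timepoint_4h",
                              "trv_table.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(full), nrow(tab))
  expect_true(file.exists(file.path(cfg$paths$out_dir, "core_table.tsv")))
  expect_true(file.exists(file.path(cfg$paths$out_dir, "report.txt")))
  expect_error(reportResults(tempfile()), "timepoint")
})

test_that("the command-line driver maps error classes to exit codes", {
  cli <- system.file("cli", "dppin.R", package = "dppin")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  # invalid config -> exit 2
  bad <- tempfile(fileext = ".yaml")
  writeRunConfig(defaultRunConfig(simulate = list(edge_density = 1.5)), bad)
  st <- system2(rscript, c(cli, "simulate", "--config", bad),
                stdout = FALSE, stderr = FALSE)
  expect_equal(st, 2L)
  # missing inputs -> exit 3
  cfgPath <- tempfile(fileext = ".yaml")
  writeRunConfig(defaultRunConfig(
    paths = list(expression = "/nonexistent.tsv", design = "/nonexistent.tsv",
                 ppi = "/nonexistent.tsv", out_dir = tempfile())), cfgPath)
  st3 <- system2(rscript, c(cli, "run", "--config", cfgPath),
                 stdout = FALSE, stderr = FALSE)
  expect_equal(st3, 3L)
  # simulate happy path -> exit 0 and a bundle on disk
  dir <- tempfile("clib")
  okCfg <- tempfile(fileext = ".yaml")
  writeRunConfig(defaultRunConfig(
    simulate = list(dir = dir, n_proteins = 10, n_timepoints = 1,
                    time_points = "4h", seed = 2)), okCfg)
  st0 <- system2(rscript, c(cli, "simulate", "--config", okCfg),
                 stdout = FALSE, stderr = FALSE)
  expect_equal(st0, 0L)
  expect_true(file.exists(file.path(dir, "expression.tsv")))
})
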