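## condition classes used to map errors to CLI exit codes
.stop_validation <- function(...)
  stop(structure(class = c("dppin_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
.stop_data <- function(...)
  stop(structure(class = c("dppin_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))

#' Default run configuration
#'
#' A nested list mirroring the YAML configuration file of the workflow
#' driver.  Sections: `paths` (expression, design, ppi, out_dir),
#' `ingestion` (sep, collapse, missing, linear_scale), `normalization`
#' (method, scope), `screening` (differential-group method, threshold,
#' min_links), `inference` (alpha, order_cap, intercept, pooled_control,
#' allow_degenerate), `permutation` (b, seed), `significance`
#' (p_threshold, fc_threshold, require_fc), `report` (top_n) and
#' `simulate` (scenario parameters for [runSimulate()]).
#'
#' @param ... named overrides, e.g. `paths = list(out_dir = "res")`
#'   (merged recursively into the defaults).
#' @return Configuration list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    paths = list(expression = NULL, design = NULL, ppi = NULL,
                 out_dir = "dppin_results"),
    ingestion = list(sep = "\t", collapse = "max_mean", missing = "error",
                     linear_scale = FALSE),
    normalization = list(method = "quantile", scope = "all"),
    screening = list(method = "fold_change", threshold = 1.5, min_links = 5),
    inference = list(alpha = 0.05, order_cap = NULL, intercept = FALSE,
                     pooled_control = TRUE, allow_degenerate = FALSE),
    permutation = list(b = 100, seed = 1),
    significance = list(p_threshold = 0.05, fc_threshold = 1.5,
                        require_fc = TRUE),
    report = list(top_n = 20),
    simulate = list(dir = "dppin_bundle", n_proteins = 20, edge_density = 0.08,
                    coupling_min = 0.6, coupling_max = 0.9,
                    perturbed_fraction = 0.2, delta_alpha = 1,
                    n_case = 3, n_control = 2, noise_sd = 0.1,
                    n_timepoints = 4, false_edge_fraction = 0.25, seed = 1,
                    time_points = c("4h", "8h", "24h", "72h")))
  .merge_config(cfg, list(...))
}

.merge_config <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], upd[[nm]])
    else base[nm] <- list(upd[[nm]])  # [<- keeps explicit NULLs
  }
  base
}

#' Read / write a run configuration
#'
#' The YAML file holds any subset of the sections of
#' [defaultRunConfig()]; unspecified fields take the defaults, so a
#' config round-trips losslessly through its file form.
#'
#' @param path YAML file path.
#' @return [readRunConfig()]: validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stop_validation("config file not found: ", path)
  cfg <- .merge_config(defaultRunConfig(), yaml::read_yaml(path))
  validateRunConfig(cfg)
  cfg
}

#' @rdname readRunConfig
#' @param config configuration list.
#' @return [writeRunConfig()]: `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks threshold ranges (p-value thresholds in (0,1), fold-change
#' thresholds > 1, permutation count >= 1, scenario densities in (0,1))
#' and enum fields, raising a validation error naming the offending
#' field.
#'
#' @param config configuration list.
#' @return `config`, invisibly, when valid.
#' @export
validateRunConfig <- function(config) {
  chk <- function(ok, field, what)
    if (!isTRUE(ok)) .stop_validation("invalid config field '", field, "': ", what)
  sg <- config$significance
  chk(sg$p_threshold > 0 && sg$p_threshold < 1, "significance.p_threshold",
      "must be in (0, 1)")
  chk(sg$fc_threshold > 1, "significance.fc_threshold", "must be > 1")
  chk(config$permutation$b >= 1, "permutation.b", "must be >= 1")
  inf <- config$inference
  chk(inf$alpha > 0 && inf$alpha < 1, "inference.alpha", "must be in (0, 1)")
  chk(config$screening$method %in% c("fold_change", "anova", "none"),
      "screening.method", "must be fold_change, anova or none")
  chk(config$normalization$method %in% c("quantile", "none"),
      "normalization.method", "must be quantile or none")
  chk(config$normalization$scope %in% c("all", "per_time_point"),
      "normalization.scope", "must be all or per_time_point")
  if (config$screening$method == "fold_change")
    chk(config$screening$threshold > 1, "screening.threshold",
        "must be > 1 for fold_change")
  sim <- config$simulate
  chk(sim$edge_density > 0 && sim$edge_density < 1, "simulate.edge_density",
      "must be in (0, 1)")
  chk(sim$perturbed_fraction >= 0 && sim$perturbed_fraction <= 1,
      "simulate.perturbed_fraction", "must be in [0, 1]")
  chk(sim$noise_sd > 0, "simulate.noise_sd", "must be > 0")
  invisible(config)
}

.scenario_from_config <- function(sim)
  syntheticScenario(nProteins = sim$n_proteins, edgeDensity = sim$edge_density,
                    couplingRange = c(sim$coupling_min, sim$coupling_max),
                    perturbedFraction = sim$perturbed_fraction,
                    deltaAlpha = sim$delta_alpha, nCase = sim$n_case,
                    nControl = sim$n_control, noiseSd = sim$noise_sd,
                    nTimePoints = sim$n_timepoints,
                    falseEdgeFraction = sim$false_edge_fraction,
                    seed = sim$seed)

#' Simulate a fixture bundle from a configuration
#'
#' @param config configuration list (see [defaultRunConfig()]); the
#'   `simulate` section defines the scenario and output directory.
#' @return The [simulateStudyBundle()] result, invisibly.
#' @export
runSimulate <- function(config = defaultRunConfig()) {
  validateRunConfig(config)
  sim <- config$simulate
  invisible(simulateStudyBundle(sim$dir, .scenario_from_config(sim),
                                timePoints = sim$time_points))
}

#' Run the full differential-network pipeline
#'
#' Reads the expression, design and PPI inputs, normalizes, and per time
#' point: selects the differential protein group, augments it with
#' highly connected PPI neighbors, builds the candidate network, fits the
#' case and (pooled) control interaction matrices, forms the difference
#' matrix, computes relevance values with permutation p-values, screens
#' significant proteins, and writes all tables and network exports plus a
#' JSON reproducibility manifest.  Per-time-point permutation seeds are
#' `seed + index - 1`.
#'
#' @param config configuration list (see [defaultRunConfig()]); the
#'   `paths` section must name the expression, design and ppi inputs and
#'   the output directory.
#' @return The output directory path, invisibly.
#' @export
runPipeline <- function(config) {
  validateRunConfig(config)
  p <- config$paths
  for (f in c("expression", "design", "ppi"))
    if (is.null(p[[f]]) || !file.exists(p[[f]]))
      .stop_data("input file for '", f, "' not found: ",
                 if (is.null(p[[f]])) "(unset)" else p[[f]])
  outDir <- p$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ing <- config$ingestion
  design <- readSampleDesign(p$design, sep = ing$sep)
  x <- readExpressionTable(p$expression, design, sep = ing$sep,
                           collapse = ing$collapse, missing = ing$missing,
                           linearScale = isTRUE(ing$linear_scale))
  ppi <- readPPIEdges(p$ppi, dialect = "plain_tsv")
  message("stage ingest: ", nrow(x), " genes x ", ncol(x), " samples; ",
          numEdges(ppi), " PPI edges")
  if (config$normalization$method == "quantile") {
    x <- quantileNormalize(x, scope = config$normalization$scope)
    message("stage normalize: quantile (", config$normalization$scope, ")")
  }
  rownames(x) <- toupper(rownames(x))
  inf <- config$inference
  settings <- inferenceSettings(alpha = inf$alpha, orderCap = inf$order_cap,
                                intercept = isTRUE(inf$intercept),
                                pooledControl = isTRUE(inf$pooled_control),
                                allowDegenerate = isTRUE(inf$allow_degenerate))
  tps <- unique(design$time_point[design$condition == "case"])
  scr <- config$screening
  sg <- config$significance
  perm <- config$permutation
  writeExpressionTable(x, file.path(outDir, "normalized_expression.tsv"))
  sigSets <- list()
  for (k in seq_along(tps)) {
    tp <- tps[k]
    core <- switch(scr$method,
      none = intersect(rownames(x), unique(as.vector(edgePairs(ppi)))),
      fold_change = selectDifferentialProteins(
        x, tp, "fold_change", scr$threshold,
        pooledControl = isTRUE(inf$pooled_control)),
      anova = selectDifferentialProteins(
        x, tp, "anova", scr$threshold,
        pooledControl = isTRUE(inf$pooled_control)))
    if (!length(core)) .stop_data("time point ", tp,
                                  ": no proteins pass screening")
    group <- augmentWithNeighbors(core, ppi, minLinks = scr$min_links)
    net <- tryCatch(buildCandidateNetwork(intersect(group, rownames(x)), ppi),
                    error = function(e) .stop_data("time point ", tp, ": ",
                                                   conditionMessage(e)))
    message("stage network [", tp, "]: ", length(networkNodes(net)),
            " nodes, ", numEdges(net), " edges")
    aCase <- fitConditionNetwork(x, net, "case", tp, settings)
    aCtl <- fitConditionNetwork(x, net, "control",
                                time_point = if (isTRUE(inf$pooled_control))
                                  NULL else tp,
                                settings = settings)
    d <- differenceMatrix(aCase, aCtl)
    pv <- trvPValues(x, net, tp, b = perm$b, seed = perm$seed + k - 1L,
                     settings = settings)
    means <- groupMeans(x, tp, pooledControl = isTRUE(inf$pooled_control))
    tab <- trvTable(d, pv, means)
    sig <- screenSignificant(tab, p_threshold = sg$p_threshold,
                             fc_threshold = sg$fc_threshold,
                             require_fc = isTRUE(sg$require_fc))
    sigSets[[tp]] <- sig
    tpDir <- file.path(outDir, paste0("timepoint_", tp))
    dir.create(tpDir, showWarnings = FALSE)
    writeProteinSet(networkNodes(net), file.path(tpDir, "candidate_nodes.txt"))
    writeInteractionMatrix(aCase, file.path(tpDir, "a_case.tsv"))
    writeInteractionMatrix(aCtl, file.path(tpDir, "a_control.tsv"))
    utils::write.table(
      classifyEdges(d), file.path(tpDir, "difference_edges.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tab, file.path(tpDir, "trv_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeProteinSet(sig, file.path(tpDir, "significant.txt"))
    trv <- computeTRV(d)
    exportNetwork(d, trv, classifyEdges(d), file.path(tpDir, "network"),
                  p_values = stats::setNames(tab$p_value, tab$protein),
                  log2_fc = stats::setNames(tab$log2_fc, tab$protein))
    message("stage relevance [", tp, "]: ", length(sig),
            " significant proteins")
  }
  if (length(sigSets) >= 2L) {
    writeProteinSet(coreBiomarkers(sigSets, "all"),
                    file.path(outDir, "core_all.txt"))
    adj <- coreBiomarkers(sigSets, "adjacent")
    adjDf <- do.call(rbind, lapply(names(adj), function(nm)
      if (length(adj[[nm]])) data.frame(pair = nm, protein = adj[[nm]])
      else NULL))
    if (is.null(adjDf)) adjDf <- data.frame(pair = character(0),
                                            protein = character(0))
    utils::write.table(adjDf, file.path(outDir, "core_adjacent.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("dppin")),
    r_version = as.character(getRversion()),
    seed = perm$seed, permutations = perm$b,
    thresholds = config$significance, screening = config$screening,
    inference = config$inference, normalization = config$normalization,
    time_points = as.list(tps),
    input_md5 = as.list(tools::md5sum(c(p$expression, p$design, p$ppi))),
    config_hash = .config_hash(config))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Summarize a result directory
#'
#' Writes, per time point, the top-`top_n` rows of the relevance table
#' (`report_<tp>.tsv`), a combined plain-text report (`report.txt`), and
#' a core-biomarker table with one row per protein and time point
#' (`core_table.tsv`).
#'
#' @param dir a [runPipeline()] output directory.
#' @param top_n rows to report per time point (default 20; short tables
#'   are reported whole).
#' @return Path of the plain-text report, invisibly.
#' @export
reportResults <- function(dir, top_n = 20L) {
  tpDirs <- list.files(dir, pattern = "^timepoint_", full.names = TRUE)
  if (!length(tpDirs)) .stop_data("no timepoint_* directories under ", dir)
  txt <- character(0)
  coreFile <- file.path(dir, "core_all.txt")
  core <- if (file.exists(coreFile)) readLines(coreFile) else character(0)
  coreRows <- list()
  for (td in tpDirs) {
    tp <- sub("^timepoint_", "", basename(td))
    tabFile <- file.path(td, "trv_table.tsv")
    if (!file.exists(tabFile)) .stop_data("missing file: ", tabFile)
    tab <- utils::read.table(tabFile, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    tab <- tab[order(-tab$trv, tab$protein), , drop = FALSE]
    top <- utils::head(tab, top_n)
    utils::write.table(top, file.path(dir, paste0("report_", tp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    txt <- c(txt, paste0("== time point ", tp, " (top ", nrow(top), ") =="),
             utils::capture.output(print(top, row.names = FALSE)), "")
    hit <- tab[tab$protein %in% core, , drop = FALSE]
    if (nrow(hit)) coreRows[[tp]] <- cbind(time_point = tp, hit)
  }
  coreTab <- if (length(coreRows)) do.call(rbind, coreRows)
             else data.frame(time_point = character(0))
  utils::write.table(coreTab, file.path(dir, "core_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  txt <- c(txt, "== core biomarkers (all time points) ==",
           if (length(core)) core else "(none)")
  reportPath <- file.path(dir, "report.txt")
  writeLines(txt, reportPath)
  invisible(reportPath)
}
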