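# shared fixture builders (all data generated in code)

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# minimal two-condition design at one time point
toy_design <- function(nCase = 2, nControl = 2, tp = "4h") {
  data.frame(
    sample_id = c(sprintf("case_%s_%d", tp, seq_len(nCase)),
                  sprintf("ctl_%s_%d", tp, seq_len(nControl))),
    condition = c(rep("case", nCase), rep("control", nControl)),
    time_point = tp,
    replicate = c(seq_len(nCase), seq_len(nControl)))
}

toy_expression <- function(values, nCase = 2, nControl = 2, tp = "4h",
                           genes = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(m)))
  rownames(m) <- genes
  d <- toy_design(nCase, nControl, tp)
  colnames(m) <- d$sample_id
  ppinExpression(m, d, linearScale = all(m >= 0))
}

# case/control expression object drawn from a ground truth
truth_expression <- function(truth, nCase, nControl, noiseSd = 0.1,
                             seed = 1, tp = "4h") {
  xc <- simulateExpression(truth$a_case[[1]], nCase, noiseSd, seed = seed,
                           condition = "case", time_point = tp)
  xn <- simulateExpression(truth$a_control, nControl, noiseSd, seed = seed + 1,
                           condition = "control", time_point = tp)
  ppinExpression(cbind(exprsValues(xc), exprsValues(xn)),
                 rbind(sampleDesign(xc), sampleDesign(xn)),
                 linearScale = FALSE)
}

rank_auc <- function(score, positive) {
  r <- rank(score)
  np <- sum(positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * sum(!positive))
}

diff_matrix_from <- function(m, nodes = NULL, tp = NA_character_) {
  m <- as.matrix(m)
  if (is.null(nodes)) nodes <- LETTERS[seq_len(nrow(m))]
  new("DifferenceMatrix", nodes = nodes,
      d = dppin:::.as_dgc(m),
      timePoint = tp)
}

make_interaction <- function(entries, nodes, condition = "case", tp = "4h") {
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (e in entries) m[e[[1]], e[[2]]] <- e[[3]]
  new("InteractionMatrix", nodes = nodes,
      coefficients = dppin:::.as_dgc(m),
      condition = condition, timePoint = tp, fits = list())
}
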