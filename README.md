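# dppin: differential protein–protein interaction network biomarkers

`dppin` identifies *network* biomarkers of a perturbed biological state —
proteins whose interaction behaviour, not necessarily their abundance,
changes between case and control samples. It was built for the classic
injury-model design in which a handful of microarrays are collected per
condition at several post-injury time points (e.g. controlled cortical
impact vs sham surgery at 4, 8, 24 and 72 h), but any two-condition
expression study with a protein–protein interaction (PPI) catalogue fits.

## The model

For every target protein *i*, its expression across samples *n* is modelled
as a linear combination of its candidate interactors drawn from a PPI edge
list (BioGRID or plain TSV), with no intercept:

```
x_i(n) = Σ_{j=1..M_i} α_ij · x_j(n) + ω_i(n)
```

where `α_ij` is the association ability between proteins *i* and *j*, `M_i`
the number of candidate interactors, and `ω_i` stochastic noise. Per
protein, `dppin`:

1. ranks candidates by `|Pearson r|` with the target,
2. chooses the model order by AIC (`n·ln(RSS/n) + 2k`) over the ranked
   prefix, capped at `n − 2`,
3. estimates `α̂_ij` by least squares and prunes coefficients with
   two-sided Student-*t* p-values above 0.05, refitting once on the
   survivors.

The retained coefficients form condition-specific interaction matrices
`A_case` (per time point) and `A_control` (pooled across control samples).
Their entrywise difference `D = A_case − A_control` is the differential
network, and each protein is scored by its **relevance value**

```
TRV_i = Σ_j | d_ij |
```

— the total absolute change in its outgoing association coefficients.
Significance is assessed by permuting the case/control labels of the pooled
samples, refitting both networks each time, with add-one empirical
p-values. Screening combines the permutation p-value (< 0.05) with a fold
change filter (FC > 1.5 on group means); proteins significant at every time
point are the core network biomarkers.

A synthetic-data generator built on the same linear model (fixed point
`x = (I − A)⁻¹ w`, spectral radius ≤ 0.8) provides ground-truth networks
with known perturbed edges, so every stage is testable end to end.

## Worked example

Simulate a 20-protein network in which a fifth of the edges change their
coupling between conditions (Δα = 1), fit both networks from 40 + 40
samples, and rank proteins by relevance value:

```r
library(dppin)

scenario <- syntheticScenario(nProteins = 20, nCase = 40, nControl = 40,
                              seed = 11)
truth <- generateGroundTruth(scenario)
net <- buildCandidateNetwork(truth$nodes, truth$ppi)
net
#> CandidateNetwork with 19 proteins and 19 edges
#>   interactor counts: min 1 / median 2 / max 4

case <- simulateExpression(truth$a_case[[1]], 40, 0.1, seed = 1,
                           condition = "case", time_point = "4h")
ctrl <- simulateExpression(truth$a_control, 40, 0.1, seed = 2,
                           condition = "control", time_point = "4h")
x <- ppinExpression(cbind(exprsValues(case), exprsValues(ctrl)),
                    rbind(sampleDesign(case), sampleDesign(ctrl)),
                    linearScale = FALSE)

aCase <- fitConditionNetwork(x, net, "case", "4h")
aCase
#> InteractionMatrix (case, 4h): 19 proteins, 27 retained coefficients
aCtrl <- fitConditionNetwork(x, net, "control")

d <- differenceMatrix(aCase, aCtrl)
pv <- trvPValues(x, net, "4h", b = 100, seed = 3)
tab <- trvTable(d, pv, groupMeans(x, "4h", pooledControl = TRUE))
head(tab[, c("protein", "trv", "p_value")], 5)
#>  protein       trv    p_value
#>     P020 1.2367382 0.01980198
#>     P010 0.9485326 0.02970297
#>     P014 0.8180858 0.03960396
#>     P016 0.7263522 0.00990099
#>     P002 0.6234418 0.08910891
```

The four highest-relevance proteins (P020, P010, P014, P016) are all nodes
whose true couplings were perturbed (`truth$perturbed_edges[[1]]` covers
P004, P006, P010, P014, P016, P020), with permutation p-values below 0.05;
`recoveryMetrics()` reports edge precision 1.00, recall 0.90 and a
TRV rank-AUC of 0.94 for this draw. A protein's `trv` is on the scale of
the association coefficients: P020's outgoing couplings changed by 1.24 in
total absolute value between conditions.

The same analysis runs from the shell over on-disk inputs:

```sh
Rscript inst/cli/dppin.R simulate --config config.yaml
Rscript inst/cli/dppin.R run      --config config.yaml
Rscript inst/cli/dppin.R report   --dir dppin_results
```

producing per-time-point relevance tables, significant sets, core
intersections, Cytoscape-ready SIF/GraphML exports and a JSON manifest.
See `vignettes/differential-ppin-methods.Rmd` for the full methods account.

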