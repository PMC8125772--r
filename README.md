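# sigclaud

Derivation, scoring and survival stratification of an **extended
M1-like macrophage gene signature**, the transcriptional footprint of
proinflammatory tumor-associated macrophages that marks claudin-low
breast tumors and other mesenchymal carcinomas.

## What it computes

Three cytokines — GM-CSF (*CSF2*), MCP-1 (*CCL2*) and RANTES (*CCL5*) —
seed the analysis. Over their protein-interaction neighbourhood,
`sigclaud`:

1. builds a Pearson correlation matrix against the seeds and retains the
   positively co-expressed genes at *p* < 0.01 (the **extended
   signature**), flagging significant negative correlates such as
   *STAT3*;
2. scores the signature per sample with a from-scratch **ssGSEA**
   statistic — with per-sample ranks `r`, walk positions `pos` (1 =
   highest rank) and `w = r^tau`, `v = N − pos + 1`:

   ```
   ES = Σ_{g∈S} w_g v_g / Σ_{g∈S} w_g  −  Σ_{g∉S} v_g / (N − |S|)
   NES = ES / (max ES − min ES)          (global range over the result)
   ```

3. validates subtype enrichment against **permutation nulls** — NES of
   1000 size-matched gene sets sampled from all genes or from an
   immune-restricted universe, normalized jointly with the observed
   signature, compared per subtype with a Mann–Whitney rank-sum test;
4. classifies samples **positive / intermediate / negative** by the
   median ± 1 SD rule on NES; and
5. links positivity to overall survival with its own product-limit,
   log-rank and Cox partial-likelihood implementations (Breslow ties,
   Wald CI, 120-month administrative horizon), plus subtype-structure
   summaries (composition tables, cytokine PCA, 2-means clustering,
   correlation-sorted heatmap orderings).

A synthetic-cohort generator (`generateCohort()`) plants a one-factor
co-expression program (pairwise `r = lambda^2`), a z-shift in a target
"claudin-low" subtype, a negatively loaded *STAT3* analogue, decoy gene
sets, a seed-anchored interaction graph and exponential survival with a
configurable hazard ratio — so every stage is testable offline with
known ground truth.

## Worked example

```r
library(sigclaud)

co   <- generateCohort(cohortConfig(seed = 1))
expr <- zscores(co); clin <- clinicalTable(co)

corr  <- pearsonMatrix(expr,
    union(seedCytokines(), igraph::V(interactionGraph(co))$name))
deriv <- deriveExtendedSignature(corr, seedCytokines())
deriv
#> SignatureDerivation
#>   seeds:       CSF2, CCL2, CCL5
#>   positive set: 24 genes ( 21 beyond the seeds )
#>   negative set: 1 genes: STAT3
#>   p threshold:  0.01

enr  <- ssgseaScore(expr,
    c(list(M1_extended_derived = positiveSet(deriv)), cohortGeneSets(co)))
null <- nullNES(expr, positiveSet(deriv), n_perm = 1000, seed = 2)
mw   <- compareSubtypeToNull(null = null,
    subtype_mask = clin$subtype == "claudin-low")
mw$p          # 9.42e-29, direction "enriched"

call <- classifyByNES(nes(enr)["M1_extended_derived", ])
call
#> PositivityCall: median = 0.08681 , SD = 0.224 , k = 1
#>    positive=79, intermediate=316, negative=105

labs <- positivityLabels(call); keep <- labs != "intermediate"
cs   <- applyHorizon(clin$os_months, clin$os_status, 120)
cmp  <- compareSurvival(cs$months[keep], cs$status[keep],
    (labs == "positive")[keep])
cmp$cox$hr    # 1.10 (95% CI 0.74-1.62), log-rank p = 0.643
```

Reading the numbers: the derivation recovers the full planted 24-gene
program and its anti-correlated *STAT3* analogue; the claudin-low
analogue subtype is overwhelmingly enriched for the signature relative
to 1000 random size-matched sets; the NES-positivity rule then marks 79
of 500 samples positive. The survival contrast between NES-positive and
NES-negative samples is attenuated (HR 1.10 here) because positivity is
a noisy proxy for the planted program under the generator's default
conditions — see the methods vignette
(`vignettes/m1-signature-methods.Rmd`) for why, and for every model
assumption and default.

One call runs everything end to end, with per-stage artifacts and a
checksum manifest:

```r
report <- runPipeline(runConfig(simulate = list(), seed = 1,
                                outdir = "run1"))
```

A thin command-line wrapper over the same functions is included:

```sh
Rscript inst/scripts/sigclaud.R run --config run.yaml
Rscript inst/scripts/sigclaud.R simulate --outdir fixtures/ --seed 1
```

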