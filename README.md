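# flcpipe

Estimating the incidence of a rare cancer from routine clinical data,
and characterizing one of its metabolic complications — as a tested,
reusable R pipeline.

Fibrolamellar liver cancer (FLC) is a rare primary liver cancer of
adolescents and young adults. Registries undercount it: there is no
FLC-specific ICD code and the disease is routinely misfiled under
conventional hepatocellular carcinoma (HCC). `flcpipe` implements a
tiered strategy for exactly this situation:

* **Incidence arm.** Chart-validated FLC/HCC labels from one
  institution give age-specific subtype proportions with a conjugate
  beta-binomial model — per decade bin *b*,
  `p_b | data ~ Beta(a0 + y_b, b0 + n_b − y_b)` — and a Monte Carlo
  simulation propagates those posteriors onto age-binned national
  claims counts (`N_b ~ Normal(μ_b, σ_b)`, `F_b ~ Binomial(N_b, p_b)`),
  reporting the mean ± SD of annual national cases and a per-100,000
  rate. A referral-distance sweep (haversine distance between zip3
  centroids, Earth radius 3958.8 mi) probes tertiary-center referral
  bias, renormalizing for patients with missing zip data.
* **Biochemistry arm.** Hyperammonemia encounters (peak ammonia ≥ 50)
  are assembled into an 11-analyte matrix (peak ammonia + the 10
  complete-metabolic-panel analytes, each temporally matched to the
  peak draw within 7 days), z-scored, embedded in a k-nearest-neighbour
  graph (k = 5) and partitioned with Leiden clustering
  (resolution 0.2). Fisher's exact test with a multiplicative
  multiple-testing correction then asks which diagnoses concentrate in
  which biochemical clusters.
* **Synthetic-data module.** The real inputs are restricted patient
  data, so the package generates EMR-style cohorts, claims counts,
  zip geography and mixture-model lab panels with the structure the
  models assume; all guarantees are demonstrated on these.

The central containers follow Bioconductor conventions: encounters
live in a `LabPanelExperiment` (a `SummarizedExperiment`), incidence
results in an S4 `IncidenceEstimate` with accessors
(`meanCases()`, `sdCases()`, `per100k()`).

## Worked example

```r
library(flcpipe)

## synthetic institutional cohort, ICD filtering, age-bin tallies
cohort <- generateEmrCohort(cohortSimParams(nPatients = 3000, seed = 7))
filt <- applyCodePolicy(cohort, codePolicy(
  exclude = c("K74.60", "B18.2", "K70.30", "K75.4", "E83.110")))
filt$audit
#> $n_input: 3000   $n_no_include: 0   $n_excluded: 1795   $n_retained: 1205
counts <- binCounts(filt$retained)
counts
#>       bin lower upper n_flc n_total
#> 1  [0,10)     0    10    30      35
#> 2 [10,20)    10    20   117     139
#> 3 [20,30)    20    30   157     227
#> 4 [30,40)    30    40   111     327
#> 5 [40,50)    40    50    57     477

## Bayesian Monte Carlo extrapolation onto synthetic claims counts
claims <- generateClaimsCounts(claimsSimParams(seed = 8))
est <- simulateIncidence(fitPosterior(counts),
                         claimsStats(claims, 2017:2019),
                         nReps = 10000, coverageFactor = 1,
                         population = 325e6, seed = 9)
est
#> IncidenceEstimate
#>   annual cases : 3293.3 +/- 178.9 (mean +/- SD, 10000 reps)
#>   rate         : 1.013 per 100,000 (population 3.25e+08)
#>   coverage     : x1, seed 9
```

The mean ± SD is the empirical distribution of coverage-scaled
replicate totals: annual national cases of the rare subtype implied by
the institutional proportions and the claims counts. The per-100k rate
divides the mean by the configured population. (These are synthetic
inputs with a high planted FLC fraction — the numbers illustrate the
mechanics, not the disease.)

```r
## hyperammonemia encounters: assemble, cluster, test enrichment
labs <- generateLabEncounters(labSimParams(nEncounters = 800, seed = 10))
asm  <- assembleEncounters(labs$events, ammoniaThreshold = 50, windowDays = 7)
lpe  <- clusterEncounters(asm$experiment, seed = 11)
table(clusterLabels(lpe))
#>   1   2   3   4   5   6   7   8
#> 145 130 129 101  87  75  67  66
head(enrichAll(as.integer(clusterLabels(lpe)), diagnosisGroup(lpe)), 2)
#>   diagnosis clusters  a  b  c   d odds_ratio      p_value correction_factor   p_adjusted
#> 1       UCD        1 69 76 51 604   10.75232 3.528784e-27                 8 2.823027e-26
#> 2      HCC1        2 36 94 24 646   10.30851 6.589737e-16                 8 5.271789e-15
```

Eight biochemical clusters are recovered from the eight-component
synthetic mixture, and the planted concentration of urea-cycle-disorder
(UCD) encounters in the near-normal-CMP cluster surfaces as the top
enrichment (odds ratio 10.8, corrected p ≈ 3e−26).

`runPipeline(runConfig(seed = 1), "outdir")` chains all stages
(simulate → cohort → incidence → sweep → cluster → enrich) with
per-stage derived seeds and writes CSV/JSON artifacts plus a
deterministic `report.json`. A thin command-line wrapper lives at
`inst/scripts/flcpipe.R`.

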