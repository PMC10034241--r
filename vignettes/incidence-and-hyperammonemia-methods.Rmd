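---
title: "Methods: rare-cancer incidence estimation and hyperammonemia lab-panel clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-cancer incidence estimation and hyperammonemia lab-panel clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcpipe)
```

# The problem

Fibrolamellar liver cancer (FLC) is a rare primary liver cancer of
adolescents and young adults. Registry-based incidence figures for such
diseases are unreliable: there is no FLC-specific ICD code, and
misclassification against conventional hepatocellular carcinoma (HCC)
is common. `flcpipe` implements a two-arm computational strategy for
this setting:

1. **Incidence arm.** Validated subtype labels from a single
   institution's EMR provide age-specific FLC/HCC proportions; a
   national claims-style dataset provides age-binned liver-cancer
   counts. Bayesian inference carries the institutional sampling
   uncertainty into a Monte Carlo extrapolation of annual national
   cases, with a referral-distance sensitivity analysis for tertiary
   center bias.
2. **Biochemistry arm.** Hyperammonemia encounters are assembled into a
   complete metabolic-panel (CMP) matrix and partitioned with the graph
   workflow familiar from single-cell analysis (z-score, PCA, kNN
   graph, Leiden); Fisher's exact test then asks which diagnoses are
   enriched in which clusters.

The real inputs are restricted-access patient data, so the package
ships a synthetic-data module that generates all inputs with the
statistical structure the models assume. Every quantitative guarantee
of the pipeline is exercised on that synthetic data.

# The incidence model

Within each decade age bin $b$ of $[0, 50)$, the number of validated
FLC cases among $n_b$ comorbidity-excluded liver-cancer patients is
modelled binomially with proportion $p_b$. With a $\mathrm{Beta}(a_0,
b_0)$ prior, the posterior is

$$p_b \mid \text{data} \sim \mathrm{Beta}(a_0 + y_b,\; b_0 + n_b - y_b),$$

so sparse bins keep wide posteriors. The prior defaults to the uniform
$\mathrm{Beta}(1,1)$; the Jeffreys $\mathrm{Beta}(0.5,0.5)$ is one
argument away (`fitPosterior(counts, 0.5, 0.5)`). No stronger prior is
defensible without external subtype data.

Each of the (by default) 10,000 Monte Carlo replicates then draws, per
bin,

* a national claims count $N_b \sim \mathrm{Normal}(\mu_b, \sigma_b)$,
  truncated at zero and rounded, where $\mu_b$ and $\sigma_b$ are the
  sample mean and sample SD (denominator $n-1$) of annual counts over
  the configured reference years (2017–2019 by default; years with
  known confounding, such as pandemic years, are simply excluded from
  the list);
* a proportion $p_b$ from the bin's Beta posterior;
* an FLC count $F_b \sim \mathrm{Binomial}(N_b, p_b)$.

The replicate total $\sum_b F_b$, multiplied by a coverage factor
taking the claims population to the national scale, yields the
empirical incidence distribution whose mean and SD are reported, plus a
per-100,000 rate against a configured national population. Choices
worth stating explicitly:

* **Truncation and rounding of the Normal count draw** are our
  convention; the count source is only characterized by mean and SD,
  and a Normal with CV around 0.1 essentially never truncates.
* **Binomial draws vs. expectation.** Drawing
  $F_b \sim \mathrm{Binomial}(N_b, p_b)$ is fully generative and is the
  default; `mode = "expectation"` uses $N_b p_b$ instead, which is
  useful to decompose how much of the reported SD is binomial noise
  versus parameter uncertainty.
* **The reported SD** is the spread of the coverage-scaled replicate
  totals — it mixes claims-count variability, posterior uncertainty
  and binomial noise, and should be read as the model's total
  uncertainty, not as a pure Monte Carlo error.
* **The coverage factor is a required input.** Synthetic runs set it
  to 1 so planted parameters are recovered on their own scale.

`simulateIncidence` scales exactly linearly in the coverage factor
(same seed), is monotone in the validated case counts under common
random numbers, and recovers $\sum_b \mu_b p_b$ within Monte Carlo
error when run on a synthetic cohort with known $p_b$ — all asserted
in the test suite.

# Referral-distance sensitivity

A tertiary center draws rare-disease referrals from further away than
its common-disease controls, inflating the subtype proportion. The
sweep (`incidenceDistanceSweep`) restricts the cohort to patients whose
zip3 centroid lies strictly within $x$ miles of the center (haversine
distance, Earth radius 3958.8 mi), renormalizes, refits the posteriors
and reruns the simulation for a grid of thresholds (default 2000, 1000,
500, 250, 100 miles — a stand-in grid, configurable).

Patients with missing or unmappable zip3 are never silently dropped.
For each bin, the fraction of mappable patients surviving the cut is
applied to the lost patients and added back to the bin total
(real-valued); the conjugate update accepts real totals (generalized
conjugacy) rather than rounding. The validated FLC count is not
adjusted by default — in the motivating study no zip-missing patient
carried the rare diagnosis, and the synthetic generator reproduces that
condition (`missingZipFractionFlc = 0`) — but `renormalizeMissing`
accepts an `flcLost` term for data where that does not hold. Computing
the surviving fraction per age bin is the default ("weighted by the age
distribution"); a pooled fraction is available as a sensitivity mode
since the exact weighting convention is a judgment call. With
strict-inequality restriction at a threshold beyond the farthest
patient and a shared seed, the sweep reproduces the unrestricted
estimate bit for bit — an invariant in the test suite.

`distanceMiles` works on a direct zip3-to-centroid lookup table.
Resolving a zip3 to the nearest five-digit zip centroid requires an
external gazetteer; the table interface is compatible with one, and the
synthetic geography (`generateZip3Centroids`, a deterministic spiral)
stands in for it.

# Encounter assembly and clustering

`assembleEncounters` scans a long lab-event stream. Per encounter it
takes the **maximum** ammonia value; encounters below the
hyperammonemia screen (default 50, assumed µmol/L — the threshold is
configurable because units conventions vary) are excluded. For each of
the 10 CMP analytes (sodium, potassium, chloride, bicarbonate, BUN,
creatinine, ALT, AST, total bilirubin, alkaline phosphatase) the
measurement **temporally closest** to the peak-ammonia draw is taken;
an exact tie in absolute time difference goes to the earlier draw. An
encounter missing any analyte within the window (default seven days,
boundary inclusive) is excluded with an audit reason. Multiple
encounters per patient are retained by design: the encounter, not the
patient, is the biochemical unit.

The feature matrix is **11 variables**: the 10 matched CMP analytes
plus the peak ammonia. Ammonia can be dropped from the features
(`includeAmmonia = FALSE`) to use it purely as the selection criterion;
we default to including it because the clustering space this workflow
is built around is 11-dimensional and ammonia is the phenotype's
defining analyte.

Clustering follows the single-cell recipe:

* **z-scoring** to zero mean, unit variance per analyte; population SD
  (denominator $n$) by convention, matching the single-cell scaling
  functions this mirrors; the sample convention is a switch. Constant
  columns are an error naming the analyte.
* **PCA** with the component count capped at
  $\min(\texttt{nPcs}, 11, n-1)$. The nominal default of 40 PCs
  therefore keeps all 11 — a full-rank rotation that preserves
  Euclidean geometry exactly, which the tests assert. The cap exists
  because a 40-dimensional projection of 11 variables is not definable.
* **kNN graph** under the Minkowski-$p$ metric (default $p = 2$,
  i.e. Euclidean — the metric family has no canonical exponent, so we
  take the standard one), $k = 5$ neighbours, union-symmetrized,
  unweighted, no self-edges. Unweighted kNN is chosen over fuzzy
  connectivity weights for determinism and transparency; either is a
  defensible neighbourhood definition.
* **Leiden** community detection on the graph, modularity objective at
  resolution 0.2, deterministic given the seed, labels renumbered by
  descending cluster size (1-based, as R factors are). A k-means
  baseline (`kmeansBaseline`) is provided for comparison; the graph
  method is primary.

`clusterProfiles` reports per-cluster medians and quartiles on raw
(unscaled) values, which is what clinical interpretation needs.

# Enrichment testing

For each tracked diagnosis and each cluster (and, optionally, each
pooled pair of clusters) a 2×2 table is built over encounters and
tested with Fisher's exact test. The two-sided p-value follows the
"probability at most that of the observed table" convention — stated
because two-sided exact-test definitions vary — and the odds ratio is
the sample ratio $ad/bc$ (infinite when $bc = 0$ and $ad > 0$). The
implementation is validated against an exhaustive
binomial-coefficient enumeration on *every* 2×2 table with total at
most 40, and against `stats::fisher.test` on random tables.

The correction scheme multiplies each single-cluster p-value by the
number of clusters $k$, and each pair p-value by $\binom{k}{2}$,
capping at 1. This is a Bonferroni-style family-wise correction even
though workflows of this kind often label it FDR; we keep the
multiplicative scheme for fidelity and provide Benjamini–Hochberg
(`method = "bh"`) as a clearly distinguished true-FDR alternative. For
the pair factor we use the mathematically correct $\binom{k}{2}$ (28
for $k = 8$); a `literalFactor` override exists for reproducing
analyses that used another constant. Pairs are tested by pooling the
two clusters into one 2×2 table, the simplest reading of "combined"
enrichment.

# The synthetic-data module

The generators are first-class, tested code — they define the study
conditions under which every guarantee is demonstrated.

* **Cohort** (`generateEmrCohort`): ages from a configurable
  distribution over decade bins; default bin FLC proportions (0.60,
  0.60, 0.50, 0.15, 0.05) and age weights (0.02, 0.08, 0.15, 0.30,
  0.45), chosen so that FLC is roughly a fifth of under-50 liver-cancer
  cases and roughly half of under-30 cases — the regime the method is
  built for. Exclusion (chronic-liver-inflammation) codes are carried
  at rate 0.70 for HCC and 0.18 for FLC, reflecting that comorbidity
  exclusion mostly removes HCC but costs some FLC patients too. zip3 is
  missing for 11% of non-FLC patients and no FLC patients by default.
* **Claims** (`generateClaimsCounts`): counts per year × bin as
  Normal(mean, CV·mean), rounded, floored at 0, CV 0.1 by default. The
  Normal is an assumption — the claims source is characterized only by
  mean and SD — and it is exactly the distribution the downstream
  count model uses, which keeps recovery tests interpretable.
* **Labs** (`generateLabEncounters`): an 8-component diagonal Gaussian
  mixture over the 11 analytes, with clinically motivated centers
  (near-normal CMP, cirrhosis-like, acute liver injury, renal failure,
  extreme hyperammonemia, metabolic acidosis, cholestasis, mixed
  hepatorenal) and 3066 encounters by default. Diagnosis labels are
  assigned *conditionally on cluster* (FLC and urea-cycle-disorder
  encounters preferentially into the near-normal-CMP and
  extreme-ammonia components), so planted enrichment odds ratios are
  analytically computable. Correlated analytes, batch effects, skewed
  or heavy-tailed lab distributions and repeated-measure structure are
  *not* emulated; recovery tests therefore demonstrate correctness of
  the machinery, not robustness to real-EMR messiness.
* **Geography** (`generateZip3Centroids`): a deterministic spiral of
  centroids around the center zip3; synthetic shape, real haversine
  arithmetic.

All generators are bit-reproducible given their seed, and all tables
round-trip losslessly through the CSV writers/readers.

# Problem sizes and numerical choices

The test suite and the acceptance script use 10,000 Monte Carlo
replicates (the analysis default), cohorts of 2,000–5,000 patients, and
lab matrices of 150–3,066 encounters — sizes at which the posterior and
Monte Carlo behaviour of interest is fully expressed while a complete
run stays interactive. Other conventions: strict inequality for the
distance cut; half-open age bins (age exactly 50 is outside the
cohort); per-stage seeds derived deterministically from the global seed
so pipeline stages rerun independently; and the RNG state of the
calling session is always restored.

# Known limitations

* The coverage factor and national population are user inputs; the
  package cannot validate them.
* The Normal claims-count model is an assumption; heavy-tailed annual
  counts would widen the true uncertainty beyond the reported SD.
* Enrichment treats encounters as exchangeable; repeated encounters
  from one patient violate independence and will overstate
  significance for diagnoses dominated by few patients.
* The synthetic geography and lab mixture are deliberately idealized
  (see above); results on them bound what the code does, not what any
  specific EMR will show.
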