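#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#'   assayNames colData colData<-
NULL

## ---------------------------------------------------------------------
## Simulation parameter classes
## ---------------------------------------------------------------------

#' Parameters for the synthetic EMR cohort generator
#'
#' Describes an age-structured two-disease (FLC vs. HCC) liver-cancer
#' cohort with comorbidity coding and coarse zip geography, emulating an
#' institutional EMR extract.
#'
#' @slot nPatients number of patients to draw.
#' @slot ageBinFlcProportions named numeric, probability that a
#'   liver-cancer patient in each age bin is FLC.
#' @slot ageDistribution named numeric over the same bins, summing to 1.
#' @slot comorbidityRateHcc,comorbidityRateFlc probability that a
#'   patient of that label carries at least one exclusion
#'   (chronic-liver-inflammation) code.
#' @slot extraCodeRates named numeric: additional ICD codes (e.g. a
#'   hyperammonemia code) carried independently at the given rate.
#' @slot zip3Pool,zip3Weights candidate 3-digit zip prefixes and their
#'   sampling weights.
#' @slot missingZipFraction,missingZipFractionFlc probability that the
#'   zip3 is missing, for non-FLC and FLC patients respectively. The
#'   FLC default is 0: in the study that motivates the design, none of
#'   the patients with unrecoverable zip data carried an FLC diagnosis.
#' @slot seed RNG seed.
#' @export
setClass("CohortSimParams", representation(
  nPatients = "integer",
  ageBinFlcProportions = "numeric",
  ageDistribution = "numeric",
  comorbidityRateHcc = "numeric",
  comorbidityRateFlc = "numeric",
  extraCodeRates = "numeric",
  zip3Pool = "character",
  zip3Weights = "numeric",
  missingZipFraction = "numeric",
  missingZipFractionFlc = "numeric",
  seed = "integer"
))

setValidity("CohortSimParams", function(object) {
  msg <- character()
  p <- object@ageBinFlcProportions
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    msg <- c(msg, "ageBinFlcProportions must lie in [0, 1]")
  }
  w <- object@ageDistribution
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    msg <- c(msg, "ageDistribution must be non-negative and sum to 1")
  }
  if (!identical(names(p), names(w))) {
    msg <- c(msg, "ageBinFlcProportions and ageDistribution must share bin names")
  }
  for (s in c("comorbidityRateHcc", "comorbidityRateFlc",
              "missingZipFraction", "missingZipFractionFlc")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      msg <- c(msg, paste(s, "must be a probability in [0, 1]"))
    }
  }
  if (object@nPatients < 0L) msg <- c(msg, "nPatients must be >= 0")
  if (length(object@zip3Pool) != length(object@zip3Weights)) {
    msg <- c(msg, "zip3Pool and zip3Weights lengths differ")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters for the synthetic claims-count generator
#'
#' Year-by-age-bin annual liver-cancer counts in a national claims-style
#' population after comorbidity exclusion. Counts are drawn as
#' Normal(mean, cv * mean), rounded and floored at zero — a modeling
#' choice matching the downstream Normal count model; the real claims
#' source publishes no distributional form.
#'
#' @slot years calendar years to simulate.
#' @slot binMeanCounts named numeric, expected annual count per age bin.
#' @slot binDispersion coefficient of variation (scalar, recycled, or
#'   one value per bin).
#' @slot seed RNG seed.
#' @export
setClass("ClaimsSimParams", representation(
  years = "integer",
  binMeanCounts = "numeric",
  binDispersion = "numeric",
  seed = "integer"
))

setValidity("ClaimsSimParams", function(object) {
  msg <- character()
  if (any(object@binMeanCounts < 0)) msg <- c(msg, "bin means must be >= 0")
  if (any(object@binDispersion < 0)) msg <- c(msg, "dispersion must be >= 0")
  if (!length(object@binDispersion) %in% c(1L, length(object@binMeanCounts))) {
    msg <- c(msg, "binDispersion must be scalar or one value per bin")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters for the synthetic lab-encounter generator
#'
#' Hyperammonemia encounters drawn from a Gaussian mixture over the 11
#' analytes (ammonia + 10 CMP analytes), with diagnosis labels assigned
#' conditionally on cluster so planted enrichment odds ratios are
#' analytically computable.
#'
#' @slot nClusters number of mixture components.
#' @slot clusterCenters,clusterScales nClusters x 11 matrices of analyte
#'   means and SDs (columns in [labAnalytes()] order); covariance is
#'   diagonal by construction.
#' @slot clusterWeights mixing proportions for encounters without a
#'   tracked diagnosis; must sum to 1.
#' @slot diagnosisFractions named numeric: fraction of encounters carrying
#'   each tracked diagnosis (remainder labelled "other").
#' @slot diagnosisEnrichment named list: per tracked diagnosis, a
#'   probability vector over clusters (each summing to 1) giving
#'   P(cluster | diagnosis).
#' @slot nEncounters number of encounters.
#' @slot ammoniaFloor lower truncation for generated ammonia values
#'   (micromol/L); all encounters satisfy the hyperammonemia screen.
#' @slot seed RNG seed.
#' @export
setClass("LabSimParams", representation(
  nClusters = "integer",
  clusterCenters = "matrix",
  clusterScales = "matrix",
  clusterWeights = "numeric",
  diagnosisFractions = "numeric",
  diagnosisEnrichment = "list",
  nEncounters = "integer",
  ammoniaFloor = "numeric",
  seed = "integer"
))

setValidity("LabSimParams", function(object) {
  msg <- character()
  k <- object@nClusters
  if (k < 1L) msg <- c(msg, "nClusters must be >= 1")
  for (s in c("clusterCenters", "clusterScales")) {
    m <- slot(object, s)
    if (ncol(m) != 11L) {
      msg <- c(msg, paste0(s, " must have 11 columns (got ", ncol(m), ")"))
    }
    if (nrow(m) != k) msg <- c(msg, paste(s, "must have one row per cluster"))
  }
  if (any(object@clusterScales < 0)) msg <- c(msg, "scales must be >= 0")
  w <- object@clusterWeights
  if (length(w) != k || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    msg <- c(msg, "clusterWeights must be a length-nClusters simplex")
  }
  f <- object@diagnosisFractions
  if (any(f < 0) || sum(f) > 1 + 1e-9) {
    msg <- c(msg, "diagnosisFractions must be >= 0 and sum to <= 1")
  }
  for (d in names(object@diagnosisEnrichment)) {
    e <- object@diagnosisEnrichment[[d]]
    if (length(e) != k || any(e < 0) || abs(sum(e) - 1) > 1e-9) {
      msg <- c(msg, paste0("diagnosisEnrichment[['", d,
                           "']] must be a length-nClusters simplex"))
    }
  }
  if (!all(names(object@diagnosisEnrichment) %in% c(names(f)))) {
    msg <- c(msg, "diagnosisEnrichment names must appear in diagnosisFractions")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------

#' Monte Carlo incidence estimate
#'
#' Posterior-predictive summary of annual national case counts for the
#' rare subtype: per replicate, age-bin claims counts are drawn from a
#' truncated Normal, subtype proportions from the Beta posteriors, and
#' subtype cases binomially; replicate totals are scaled by the
#' claims-to-national coverage factor.
#'
#' @slot meanCases,sdCases mean and SD (sample, ddof = 1) of the
#'   coverage-scaled replicate totals.
#' @slot per100k annual cases per 100,000 population.
#' @slot nReps number of Monte Carlo replicates.
#' @slot coverageFactor national extrapolation multiplier.
#' @slot population reference population size.
#' @slot seed RNG seed used.
#' @slot repTotals coverage-scaled replicate totals (length 0 unless
#'   retained for convergence/sweep diagnostics).
#' @export
setClass("IncidenceEstimate", representation(
  meanCases = "numeric",
  sdCases = "numeric",
  per100k = "numeric",
  nReps = "integer",
  coverageFactor = "numeric",
  population = "numeric",
  seed = "integer",
  repTotals = "numeric"
))

setValidity("IncidenceEstimate", function(object) {
  msg <- character()
  if (object@sdCases < 0) msg <- c(msg, "sdCases must be >= 0")
  if (object@coverageFactor <= 0) msg <- c(msg, "coverageFactor must be > 0")
  if (object@population <= 0) msg <- c(msg, "population must be > 0")
  exp_rate <- 1e5 * object@meanCases / object@population
  if (abs(object@per100k - exp_rate) > 1e-8 * max(1, abs(exp_rate))) {
    msg <- c(msg, "per100k inconsistent with meanCases / population")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "IncidenceEstimate", function(object) {
  cat("IncidenceEstimate\n")
  cat(sprintf("  annual cases : %.1f +/- %.1f (mean +/- SD, %d reps)\n",
              object@meanCases, object@sdCases, object@nReps))
  cat(sprintf("  rate         : %.4g per 100,000 (population %s)\n",
              object@per100k, format(object@population, big.mark = ",")))
  cat(sprintf("  coverage     : x%.4g, seed %d\n",
              object@coverageFactor, object@seed))
  invisible(NULL)
})

#' Hyperammonemia encounter container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the assembled
#' encounter matrix: one column per retained hyperammonemia encounter,
#' one row per analyte ([labAnalytes()]; ammonia row carries the
#' encounter's maximum ammonia, CMP rows the temporally closest values).
#' `colData` carries `patient_id`, `diagnosis`, `max_ammonia` and, after
#' clustering, `cluster`.
#'
#' @export
setClass("LabPanelExperiment", contains = "SummarizedExperiment")

setValidity("LabPanelExperiment", function(object) {
  msg <- character()
  if (!"labs" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'labs' is required")
  } else {
    if (!identical(rownames(object), labAnalytes())) {
      msg <- c(msg, "rows must be labAnalytes() in order")
    }
  }
  need <- c("patient_id", "diagnosis", "max_ammonia")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss)) {
    msg <- c(msg, paste("colData missing:", paste(miss, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabPanelExperiment
#'
#' @param panel 11 x n matrix of analyte values (rows in
#'   [labAnalytes()] order, columns are encounters).
#' @param patientId,diagnosis per-encounter annotation vectors.
#' @param metadata optional list stored in the object metadata.
#' @return a [LabPanelExperiment-class] object.
#' @export
LabPanelExperiment <- function(panel, patientId, diagnosis,
                               metadata = list()) {
  stopifnot(nrow(panel) == 11L)
  rownames(panel) <- labAnalytes()
  se <- SummarizedExperiment(
    assays = list(labs = panel),
    colData = DataFrame(
      patient_id = as.character(patientId),
      diagnosis = as.character(diagnosis),
      max_ammonia = as.numeric(panel["ammonia", ]),
      row.names = colnames(panel)
    ),
    metadata = metadata
  )
  new("LabPanelExperiment", se)
}

setMethod("show", "LabPanelExperiment", function(object) {
  callNextMethod()
  cl <- clusterLabels(object)
  if (!is.null(cl)) {
    cat("clusters:", nlevels(cl), "(sizes",
        paste(tabulate(cl), collapse = ", "), ")\n")
  }
  invisible(NULL)
})
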