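## Synthetic-data generators. These emulate the three restricted inputs
## the analysis consumes — an institutional EMR cohort, national
## claims-style annual counts, and a hyperammonemia lab-event stream —
## with the statistical structure the downstream models assume, so the
## full pipeline can be exercised and tested without patient data.

#' @rdname generateEmrCohort
#' @param nPatients,ageBinFlcProportions,ageDistribution,comorbidityRateHcc,comorbidityRateFlc,extraCodeRates,zip3Pool,zip3Weights,missingZipFraction,missingZipFractionFlc,seed
#'   see [CohortSimParams-class].
#' @export
cohortSimParams <- function(nPatients = 5000L,
                            ageBinFlcProportions = c(
                              "[0,10)" = 0.60, "[10,20)" = 0.60,
                              "[20,30)" = 0.50, "[30,40)" = 0.15,
                              "[40,50)" = 0.05),
                            ageDistribution = c(
                              "[0,10)" = 0.02, "[10,20)" = 0.08,
                              "[20,30)" = 0.15, "[30,40)" = 0.30,
                              "[40,50)" = 0.45),
                            comorbidityRateHcc = 0.70,
                            comorbidityRateFlc = 0.18,
                            extraCodeRates = c("R79.82" = 0.08),
                            zip3Pool = sprintf("9%02d", 41:52),
                            zip3Weights = rep(1, 12),
                            missingZipFraction = 0.11,
                            missingZipFractionFlc = 0,
                            seed = 1L) {
  new("CohortSimParams",
      nPatients = assertCount(nPatients, "nPatients"),
      ageBinFlcProportions = ageBinFlcProportions,
      ageDistribution = ageDistribution,
      comorbidityRateHcc = comorbidityRateHcc,
      comorbidityRateFlc = comorbidityRateFlc,
      extraCodeRates = extraCodeRates,
      zip3Pool = as.character(zip3Pool),
      zip3Weights = as.numeric(zip3Weights),
      missingZipFraction = missingZipFraction,
      missingZipFractionFlc = missingZipFractionFlc,
      seed = as.integer(seed))
}

## Parse "[l,u)" bin labels back to numeric bounds.
parseBinLabels <- function(labels) {
  m <- regmatches(labels, regexec("^\\[([0-9.]+),([0-9.]+)\\)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("unparseable age-bin label(s): ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(label = labels,
             lower = as.numeric(vapply(m, `[`, "", 2L)),
             upper = as.numeric(vapply(m, `[`, "", 3L)))
}

#' Generate a synthetic EMR liver-cancer cohort
#'
#' Draws patients with an age from the configured age distribution over
#' decade bins, a validated label (FLC with the bin-specific proportion,
#' otherwise HCC), a liver-cancer inclusion code (always present), an
#' exclusion (chronic-liver-inflammation) code with the label-specific
#' comorbidity rate, optional extra codes, and a zip3 that is missing
#' with the configured fraction.
#'
#' @param params a [cohortSimParams()] object.
#' @return a `data.frame` with columns `patient_id`, `age`, `codes`
#'   (semicolon-joined ICD strings), `label`, `zip3` (`NA` if missing).
#' @export
generateEmrCohort <- function(params) {
  validObject(params)
  n <- params@nPatients
  bins <- parseBinLabels(names(params@ageDistribution))
  empty <- data.frame(patient_id = character(), age = integer(),
                      codes = character(), label = character(),
                      zip3 = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  withSeed(params@seed, {
    bidx <- sample.int(nrow(bins), n, replace = TRUE,
                       prob = params@ageDistribution)
    age <- bins$lower[bidx] +
      floor(runif(n) * (bins$upper[bidx] - bins$lower[bidx]))
    is_flc <- runif(n) < params@ageBinFlcProportions[bidx]
    label <- ifelse(is_flc, "FLC", "HCC")
    include <- sample(c("C22.0", "C22.7"), n, replace = TRUE)
    excl_rate <- ifelse(is_flc, params@comorbidityRateFlc,
                        params@comorbidityRateHcc)
    excl_pool <- c("K74.60", "B18.2", "K70.30", "K75.4", "E83.110")
    has_excl <- runif(n) < excl_rate
    excl <- ifelse(has_excl, sample(excl_pool, n, replace = TRUE), NA)
    codes <- include
    for (code in names(params@extraCodeRates)) {
      hit <- runif(n) < params@extraCodeRates[[code]]
      codes <- ifelse(hit, paste(codes, code, sep = ";"), codes)
    }
    codes <- ifelse(is.na(excl), codes, paste(codes, excl, sep = ";"))
    zip3 <- if (length(params@zip3Pool)) {
      sample(params@zip3Pool, n, replace = TRUE, prob = params@zip3Weights)
    } else rep(NA_character_, n)
    miss_rate <- ifelse(is_flc, params@missingZipFractionFlc,
                        params@missingZipFraction)
    zip3[runif(n) < miss_rate] <- NA_character_
    data.frame(patient_id = sprintf("P%06d", seq_len(n)),
               age = as.integer(age), codes = codes, label = label,
               zip3 = zip3, stringsAsFactors = FALSE)
  })
}

#' @rdname generateClaimsCounts
#' @param years,binMeanCounts,binDispersion,seed see
#'   [ClaimsSimParams-class].
#' @export
claimsSimParams <- function(years = 2017:2019,
                            binMeanCounts = c(
                              "[0,10)" = 500, "[10,20)" = 800,
                              "[20,30)" = 1500, "[30,40)" = 2500,
                              "[40,50)" = 4000),
                            binDispersion = 0.1,
                            seed = 1L) {
  new("ClaimsSimParams", years = as.integer(years),
      binMeanCounts = binMeanCounts,
      binDispersion = as.numeric(binDispersion),
      seed = as.integer(seed))
}

#' Generate synthetic annual claims counts
#'
#' Annual comorbidity-excluded liver-cancer counts per age bin and year,
#' drawn as Normal(mean, cv * mean), rounded to integers and floored at
#' zero. At dispersion 0 every year's count equals the rounded mean.
#'
#' @param params a [claimsSimParams()] object.
#' @return `data.frame` with columns `year`, `age_bin`, `count`.
#' @export
generateClaimsCounts <- function(params) {
  validObject(params)
  yrs <- params@years
  mu <- params@binMeanCounts
  if (length(yrs) == 0L) {
    return(data.frame(year = integer(), age_bin = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  cv <- rep_len(params@binDispersion, length(mu))
  withSeed(params@seed, {
    grid <- expand.grid(age_bin = names(mu), year = yrs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    m <- mu[grid$age_bin]
    s <- (cv[match(grid$age_bin, names(mu))]) * m
    cnt <- as.integer(pmax(0, round(rnorm(nrow(grid), m, s))))
    data.frame(year = as.integer(grid$year), age_bin = grid$age_bin,
               count = cnt, stringsAsFactors = FALSE)[
                 order(grid$year, match(grid$age_bin, names(mu))), ,
                 drop = FALSE] -> out
    rownames(out) <- NULL
    out
  })
}

## Default mixture: eight clinically motivated hyperammonemia phenotypes
## around a normal-CMP baseline (units: ammonia umol/L, electrolytes
## mmol/L, BUN/creatinine mg/dL, enzymes U/L, bilirubin mg/dL).
defaultLabCenters <- function() {
  base <- c(ammonia = 80, sodium = 138, potassium = 4.0, chloride = 102,
            bicarbonate = 24, BUN = 15, creatinine = 1.0, ALT = 30,
            AST = 35, total_bilirubin = 1.0, alkaline_phosphatase = 90)
  centers <- matrix(rep(base, each = 8), nrow = 8,
                    dimnames = list(NULL, names(base)))
  ## 1 near-normal CMP; 2 cirrhosis-like (low Na/Cl, high bili/ALP);
  ## 3 acute liver injury; 4 renal failure; 5 extreme hyperammonemia;
  ## 6 metabolic acidosis; 7 cholestasis; 8 mixed hepatorenal.
  centers[2, c("sodium", "chloride", "total_bilirubin",
               "alkaline_phosphatase")] <- c(128, 94, 4.5, 220)
  centers[3, c("ALT", "AST", "total_bilirubin")] <- c(900, 1100, 6)
  centers[4, c("BUN", "creatinine", "bicarbonate")] <- c(65, 4.5, 18)
  centers[5, c("ammonia", "ALT", "AST")] <- c(300, 60, 70)
  centers[6, c("bicarbonate", "chloride", "potassium")] <- c(12, 112, 5.5)
  centers[7, c("alkaline_phosphatase", "total_bilirubin")] <- c(450, 8)
  centers[8, c("BUN", "creatinine", "AST", "total_bilirubin",
               "sodium")] <- c(50, 3.0, 300, 5, 130)
  centers
}

defaultLabScales <- function() {
  s <- c(ammonia = 25, sodium = 3, potassium = 0.4, chloride = 3,
         bicarbonate = 2.5, BUN = 6, creatinine = 0.4, ALT = 20,
         AST = 25, total_bilirubin = 0.8, alkaline_phosphatase = 35)
  matrix(rep(s, each = 8), nrow = 8, dimnames = list(NULL, names(s)))
}

#' @rdname generateLabEncounters
#' @param nClusters,clusterCenters,clusterScales,clusterWeights,diagnosisFractions,diagnosisEnrichment,nEncounters,ammoniaFloor,seed
#'   see [LabSimParams-class].
#' @export
labSimParams <- function(nClusters = 8L,
                         clusterCenters = defaultLabCenters(),
                         clusterScales = defaultLabScales(),
                         clusterWeights = rep(1 / 8, 8),
                         diagnosisFractions = c(
                           FLC = 19 / 3066, UCD = 442 / 3066,
                           HCC1 = 200 / 3066, HCC2 = 95 / 3066,
                           CRC = 120 / 3066, breast = 60 / 3066,
                           PDAC = 60 / 3066),
                         diagnosisEnrichment = list(
                           FLC  = c(0.45, 0.02, 0.02, 0.02, 0.45, 0.02, 0.01, 0.01),
                           UCD  = c(0.40, 0.01, 0.01, 0.01, 0.53, 0.02, 0.01, 0.01),
                           HCC1 = c(0.05, 0.55, 0.15, 0.05, 0.02, 0.05, 0.08, 0.05),
                           HCC2 = c(0.15, 0.05, 0.30, 0.10, 0.05, 0.10, 0.15, 0.10),
                           CRC  = c(0.05, 0.45, 0.10, 0.10, 0.02, 0.08, 0.10, 0.10),
                           breast = c(0.10, 0.10, 0.25, 0.15, 0.02, 0.13, 0.15, 0.10),
                           PDAC = c(0.08, 0.12, 0.25, 0.10, 0.02, 0.08, 0.25, 0.10)),
                         nEncounters = 3066L,
                         ammoniaFloor = 50,
                         seed = 1L) {
  if (ncol(clusterCenters) != 11L || ncol(clusterScales) != 11L) {
    stop("clusterCenters and clusterScales must have 11 columns (one per analyte)",
         call. = FALSE)
  }
  new("LabSimParams", nClusters = as.integer(nClusters),
      clusterCenters = clusterCenters, clusterScales = clusterScales,
      clusterWeights = as.numeric(clusterWeights),
      diagnosisFractions = diagnosisFractions,
      diagnosisEnrichment = diagnosisEnrichment,
      nEncounters = assertCount(nEncounters, "nEncounters"),
      ammoniaFloor = as.numeric(ammoniaFloor),
      seed = as.integer(seed))
}

#' Generate synthetic hyperammonemia lab encounters
#'
#' Each encounter's 11 analyte values are drawn from its mixture
#' component (diagonal Gaussian); ammonia is truncated below at
#' `ammoniaFloor` so every encounter passes the hyperammonemia screen.
#' Tracked diagnoses are assigned a cluster from their enrichment
#' probability vector; untracked encounters from the mixing weights.
#' The long-format event stream carries per-analyte timestamps within
#' +/- 24 h of the ammonia draw, so encounter assembly can be exercised
#' end to end.
#'
#' @param params a [labSimParams()] object.
#' @return a list with `events` (long `data.frame`: `encounter_id`,
#'   `patient_id`, `diagnosis`, `analyte`, `value`, `timestamp`
#'   ISO-8601), `truth` (`data.frame`: `encounter_id`, `cluster`,
#'   `diagnosis`), and `panel` (n x 11 matrix of the underlying values).
#' @export
generateLabEncounters <- function(params) {
  validObject(params)
  n <- params@nEncounters
  k <- params@nClusters
  if (n == 0L) {
    return(list(events = data.frame(), truth = data.frame(),
                panel = matrix(numeric(), 0, 11,
                               dimnames = list(NULL, labAnalytes()))))
  }
  withSeed(params@seed, {
    ## diagnosis labels, then cluster | diagnosis
    fr <- params@diagnosisFractions
    diag_lab <- sample(c(names(fr), "other"), n, replace = TRUE,
                       prob = c(fr, 1 - sum(fr)))
    cl <- integer(n)
    untracked <- !(diag_lab %in% names(params@diagnosisEnrichment))
    cl[untracked] <- sample.int(k, sum(untracked), replace = TRUE,
                                prob = params@clusterWeights)
    for (d in names(params@diagnosisEnrichment)) {
      idx <- which(diag_lab == d)
      if (length(idx)) {
        cl[idx] <- sample.int(k, length(idx), replace = TRUE,
                              prob = params@diagnosisEnrichment[[d]])
      }
    }
    panel <- params@clusterCenters[cl, , drop = FALSE] +
      matrix(rnorm(n * 11L), n, 11L) * params@clusterScales[cl, , drop = FALSE]
    colnames(panel) <- labAnalytes()
    panel[, "ammonia"] <- pmax(panel[, "ammonia"], params@ammoniaFloor)
    eid <- sprintf("E%06d", seq_len(n))
    pid <- sprintf("P%06d", sample.int(max(1L, round(n * 0.8)), n,
                                       replace = TRUE))
    ## ammonia at encounter anchor time; CMP draws within +/- 24 h
    t0 <- as.POSIXct("2016-01-01 08:00:00", tz = "UTC") +
      (seq_len(n) - 1L) * 3600 * 30
    offs <- matrix(runif(n * 10L, -86400, 86400), n, 10L)
    events <- data.frame(
      encounter_id = rep(eid, each = 11L),
      patient_id = rep(pid, each = 11L),
      diagnosis = rep(diag_lab, each = 11L),
      analyte = rep(labAnalytes(), times = n),
      value = as.numeric(t(panel)),
      timestamp = format(
        rep(t0, each = 11L) +
          as.numeric(t(cbind(0, offs))),
        "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      stringsAsFactors = FALSE)
    truth <- data.frame(encounter_id = eid, cluster = cl,
                        diagnosis = diag_lab, stringsAsFactors = FALSE)
    rownames(panel) <- eid
    list(events = events, truth = truth, panel = panel)
  })
}

#' Generate deterministic synthetic zip3 centroids
#'
#' Places the designated center zip3 at the given coordinates and the
#' remaining zip3s on a deterministic spiral: the i-th zip sits
#' `ringSpacingMiles * i` miles from the center at golden-angle bearing
#' increments. Purely synthetic geography: the shape is convenient, not
#' a model of any real catchment.
#'
#' @param zip3Pool distinct zip3 strings.
#' @param centerZip3 which entry is the tertiary-center zip3 (added to
#'   the pool if absent).
#' @param centerLat,centerLon coordinates of the center.
#' @param ringSpacingMiles radial spacing of the spiral.
#' @return `data.frame` with columns `zip3`, `lat`, `lon`.
#' @export
generateZip3Centroids <- function(zip3Pool, centerZip3 = zip3Pool[1],
                                  centerLat = 37.763, centerLon = -122.458,
                                  ringSpacingMiles = 150) {
  zip3Pool <- as.character(zip3Pool)
  if (anyDuplicated(zip3Pool)) {
    stop("duplicate zip3 in pool: ",
         paste(unique(zip3Pool[duplicated(zip3Pool)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(zip3Pool) == 0L) {
    return(data.frame(zip3 = character(), lat = numeric(),
                      lon = numeric(), stringsAsFactors = FALSE))
  }
  if (!centerZip3 %in% zip3Pool) {
    stop("centerZip3 '", centerZip3, "' is not in the pool", call. = FALSE)
  }
  others <- setdiff(zip3Pool, centerZip3)
  i <- seq_along(others)
  bearing <- (i * 137.50776405) %% 360
  dist_mi <- ringSpacingMiles * i
  pts <- if (length(others)) {
    geosphere::destPoint(c(centerLon, centerLat), bearing, dist_mi,
                         r = 3958.8)
  } else matrix(numeric(), 0, 2)
  out <- data.frame(
    zip3 = c(centerZip3, others),
    lat = c(centerLat, pts[, 2]),
    lon = c(centerLon, pts[, 1]),
    stringsAsFactors = FALSE)
  out <- out[match(zip3Pool, out$zip3), , drop = FALSE]
  rownames(out) <- NULL
  out
}
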