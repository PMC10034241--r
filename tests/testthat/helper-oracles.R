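# Independent oracles and small fixture builders shared across tests.

suppressPackageStartupMessages({
  library(SummarizedExperiment)  # assay(), colData(), metadata()
})

# Exhaustive hypergeometric enumeration for a 2x2 table, written from
# the binomial-coefficient definition (lchoose) so it shares no code
# path with fisherExact(). Two-sided convention: sum probabilities of
# all tables with the observed margins whose probability is at most
# the observed one.
fisherOracle <- function(a, b, c, d) {
  m <- a + b
  k <- a + c
  n <- a + b + c + d
  support <- max(0, k - (n - m)):min(k, m)
  logp <- lchoose(m, support) + lchoose(n - m, k - support) - lchoose(n, k)
  dens <- exp(logp)
  obs <- dens[support == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Adjusted Rand index between two partitions (independent of any
# clustering code under test).
ari <- function(x, y) mclust::adjustedRandIndex(x, y)

# Long-format lab-event stream builder: `spec` is a list of encounters,
# each a data.frame with analyte, value, hours (offset from a common
# anchor time).
makeLabStream <- function(spec) {
  anchor <- as.POSIXct("2020-06-01 12:00:00", tz = "UTC")
  rows <- lapply(names(spec), function(eid) {
    s <- spec[[eid]]
    data.frame(encounter_id = eid, patient_id = paste0("pt_", eid),
               diagnosis = "other", analyte = s$analyte, value = s$value,
               timestamp = format(anchor + s$hours * 3600,
                                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# A complete 11-analyte encounter: ammonia at hour 0, CMP analytes at
# the given hour offsets (recycled).
completeEncounter <- function(ammonia = 80, cmpHours = 1,
                              cmpValues = seq(10, 100, by = 10)) {
  data.frame(analyte = labAnalytes(),
             value = c(ammonia, cmpValues),
             hours = c(0, rep_len(cmpHours, 10)))
}

# Tiny patient table with explicit code strings.
makePatients <- function(codes, ages = NULL, labels = NULL,
                         zip3 = NULL) {
  n <- length(codes)
  data.frame(patient_id = sprintf("p%03d", seq_len(n)),
             age = if (is.null(ages)) rep(30L, n) else as.integer(ages),
             codes = codes,
             label = if (is.null(labels)) rep("HCC", n) else labels,
             zip3 = if (is.null(zip3)) rep(NA_character_, n) else zip3,
             stringsAsFactors = FALSE)
}

# Well-separated Gaussian mixture in the 11-analyte space: component
# centers offset along distinct axes by `sep` SDs.
separatedLabParams <- function(k, n, sep = 10, seed = 11L) {
  centers <- matrix(100, k, 11)
  for (i in seq_len(k)) centers[i, i] <- 100 + sep * 5
  scales <- matrix(5, k, 11)
  labSimParams(nClusters = k, clusterCenters = centers,
               clusterScales = scales, clusterWeights = rep(1 / k, k),
               diagnosisFractions = c(X = 0.1),
               diagnosisEnrichment = list(X = rep(1 / k, k)),
               nEncounters = n, ammoniaFloor = 0, seed = seed)
}
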