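test_that("cohort generator honours sizes, labels and proportions", {
  expect_equal(nrow(generateEmrCohort(cohortSimParams(nPatients = 0))), 0L)

  all_flc <- cohortSimParams(
    nPatients = 100,
    ageBinFlcProportions = setNames(rep(1, 5), ageBins()$label),
    seed = 3)
  co <- generateEmrCohort(all_flc)
  expect_true(all(co$label == "FLC"))

  # empirical FLC fraction within 3 binomial SDs of the planted rate
  p <- 0.21
  pp <- cohortSimParams(
    nPatients = 20000,
    ageBinFlcProportions = setNames(rep(p, 5), ageBins()$label),
    seed = 42)
  co <- generateEmrCohort(pp)
  expect_lt(abs(mean(co$label == "FLC") - p),
            3 * sqrt(p * (1 - p) / 20000))
})

test_that("cohort generator structural guarantees hold", {
  prm <- cohortSimParams(nPatients = 500, seed = 9)
  co <- generateEmrCohort(prm)
  codes <- strsplit(co$codes, ";")
  expect_true(all(vapply(codes, function(x)
    any(x %in% c("C22.0", "C22.7")), TRUE)))
  expect_true(all(co$age >= 0 & co$age < 50))
  # missing-zip applies to the configured labels only
  expect_false(any(is.na(co$zip3[co$label == "FLC"])))
  expect_gt(sum(is.na(co$zip3[co$label == "HCC"])), 0)
  # determinism: identical params and seed, bit-identical output
  expect_identical(co, generateEmrCohort(prm))
  expect_false(identical(co, generateEmrCohort(
    cohortSimParams(nPatients = 500, seed = 10))))
  expect_error(cohortSimParams(nPatients = 10, missingZipFraction = 1.2),
               "probability")
})

test_that("claims generator matches its zero-noise and 3-SD limits", {
  zero <- claimsSimParams(years = 2017:2019,
                          binMeanCounts = c("[0,50)" = 1234.4),
                          binDispersion = 0, seed = 1)
  out <- generateClaimsCounts(zero)
  expect_true(all(out$count == 1234L))

  one <- claimsSimParams(years = 2017:2019,
                         binMeanCounts = c("[0,50)" = 1000),
                         binDispersion = 0.1, seed = 5)
  out <- generateClaimsCounts(one)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$count >= 700 & out$count <= 1300))

  empty <- claimsSimParams(years = integer(), seed = 1)
  expect_equal(nrow(generateClaimsCounts(empty)), 0L)
  expect_error(claimsSimParams(binMeanCounts = c(a = -5)), "means")
})

test_that("lab generator plants recoverable structure", {
  p1 <- separatedLabParams(1, 50)
  expect_true(all(generateLabEncounters(p1)$truth$cluster == 1L))

  # two components 10 SDs apart: nearest-center oracle and the full
  # scale->graph->Leiden pipeline both recover the partition
  p2 <- separatedLabParams(2, 500, sep = 10, seed = 21)
  g2 <- generateLabEncounters(p2)
  d1 <- sqrt(rowSums(sweep(g2$panel, 2, p2@clusterCenters[1, ])^2))
  d2 <- sqrt(rowSums(sweep(g2$panel, 2, p2@clusterCenters[2, ])^2))
  oracle <- ifelse(d1 < d2, 1L, 2L)
  expect_gte(ari(oracle, g2$truth$cluster), 0.99)
  lab <- clusterGraph(buildGraph(scaleMatrix(g2$panel)), seed = 2)
  expect_gte(ari(lab, g2$truth$cluster), 0.99)

  # planted diagnosis-cluster assignment probability is honoured
  pe <- labSimParams(
    nClusters = 2,
    clusterCenters = matrix(100, 2, 11), clusterScales = matrix(5, 2, 11),
    clusterWeights = c(0.5, 0.5),
    diagnosisFractions = c(UCD = 0.4),
    diagnosisEnrichment = list(UCD = c(0.9, 0.1)),
    nEncounters = 2000, ammoniaFloor = 50, seed = 8)
  ge <- generateLabEncounters(pe)
  ucd <- ge$truth$diagnosis == "UCD"
  frac <- mean(ge$truth$cluster[ucd] == 1L)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / sum(ucd)))
  # ammonia floor enforced on every encounter
  expect_true(all(ge$panel[, "ammonia"] >= 50))
  expect_error(labSimParams(clusterCenters = matrix(1, 8, 10)), "11")
})

test_that("zip3 centroid geometry is deterministic and valid", {
  single <- generateZip3Centroids("941")
  expect_equal(nrow(single), 1L)
  expect_equal(distanceMiles(single$lat, single$lon,
                             single$lat, single$lon), 0)
  z <- generateZip3Centroids(c("941", "945", "900"), centerZip3 = "941")
  expect_identical(z, generateZip3Centroids(c("941", "945", "900"),
                                            centerZip3 = "941"))
  expect_true(all(abs(z$lat) <= 90 & abs(z$lon) <= 180))
  expect_equal(nrow(generateZip3Centroids(character())), 0L)
  expect_error(generateZip3Centroids(c("941", "941")), "duplicate")
})

test_that("generated tables round-trip losslessly through CSV", {
  tmp <- withr::local_tempdir()
  co <- generateEmrCohort(cohortSimParams(nPatients = 200, seed = 4))
  writePatients(co, file.path(tmp, "patients.csv"))
  expect_identical(readPatients(file.path(tmp, "patients.csv")), co)

  cl <- generateClaimsCounts(claimsSimParams(seed = 4))
  writeClaims(cl, file.path(tmp, "claims.csv"))
  expect_identical(readClaims(file.path(tmp, "claims.csv")), cl)

  lb <- generateLabEncounters(labSimParams(nEncounters = 40, seed = 4))
  writeLabs(lb$events, file.path(tmp, "labs.csv"))
  rt <- readLabs(file.path(tmp, "labs.csv"))
  expect_identical(rt[setdiff(names(rt), "value")],
                   lb$events[setdiff(names(lb$events), "value")])
  expect_equal(rt$value, lb$events$value, tolerance = 1e-12)

  zp <- generateZip3Centroids(sprintf("9%02d", 41:46))
  writeZip3Centroids(zp, file.path(tmp, "zips.csv"))
  expect_equal(readZip3Centroids(file.path(tmp, "zips.csv")), zp,
               tolerance = 1e-12)
})
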