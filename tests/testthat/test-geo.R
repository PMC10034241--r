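test_that("haversine distances have metric properties and known values", {
  expect_equal(distanceMiles(37.7, -122.4, 37.7, -122.4), 0)
  # one degree of latitude on the great circle
  expect_equal(distanceMiles(0, 0, 1, 0), 69.09, tolerance = 1e-3)
  withr::with_seed(2, {
    la <- runif(20, -80, 80); lo <- runif(20, -170, 170)
    lb <- runif(20, -80, 80); lob <- runif(20, -170, 170)
    expect_equal(distanceMiles(la, lo, lb, lob),
                 distanceMiles(lb, lob, la, lo))
    expect_true(all(distanceMiles(la, lo, lb, lob) >= 0))
  })
  expect_error(distanceMiles(91, 0, 0, 0), "coordinates")
})

test_that("distance restriction splits the cohort exhaustively", {
  zips <- generateZip3Centroids(sprintf("9%02d", 41:48),
                                centerZip3 = "941",
                                ringSpacingMiles = 100)
  co <- generateEmrCohort(cohortSimParams(nPatients = 400, seed = 6,
                                          zip3Pool = zips$zip3,
                                          zip3Weights = rep(1, 8)))
  r <- restrictByDistance(co, zips, "941", 1e9)
  expect_equal(nrow(r$retained), sum(!is.na(co$zip3)))
  expect_equal(nrow(r$missing), sum(is.na(co$zip3)))

  # threshold below the minimum distance retains nobody
  away <- co[!is.na(co$zip3) & co$zip3 != "941", ]
  rmin <- restrictByDistance(away, zips, "941", 50)
  expect_equal(nrow(rmin$retained), 0L)

  # brute-force check of the strict inequality at a mid threshold
  thr <- 350
  r2 <- restrictByDistance(co, zips, "941", thr)
  ci <- which(zips$zip3 == "941")
  zi <- match(co$zip3, zips$zip3)
  d <- rep(NA_real_, nrow(co))
  d[!is.na(zi)] <- distanceMiles(zips$lat[zi[!is.na(zi)]],
                                 zips$lon[zi[!is.na(zi)]],
                                 zips$lat[ci], zips$lon[ci])
  expect_setequal(r2$retained$patient_id,
                  co$patient_id[!is.na(d) & d < thr])

  # unmappable zip3 is grouped with missing, never dropped
  co$zip3[1] <- "999"
  r3 <- restrictByDistance(co, zips, "941", thr)
  expect_equal(r3$n_unmappable, 1L)
  expect_true(co$patient_id[1] %in% r3$missing$patient_id)
  expect_equal(nrow(r3$retained) + nrow(r3$excluded) + nrow(r3$missing),
               nrow(co))
})

test_that("missing-zip renormalization follows the stated arithmetic", {
  ret <- data.frame(bin = c("a", "b"), lower = c(0, 25), upper = c(25, 50),
                    n_flc = c(3L, 1L), n_total = c(80L, 40L))
  none <- transform(ret, n_flc = 0L, n_total = 0L)
  expect_equal(renormalizeMissing(ret, none, 0.5), ret,
               ignore_attr = TRUE)

  lost <- transform(ret, n_flc = 0L, n_total = c(10L, 6L))
  full <- renormalizeMissing(ret, lost, 1)
  expect_equal(full$n_total, ret$n_total + lost$n_total)
  expect_equal(full$n_flc, ret$n_flc)

  # retained 80 of 100 mappable, 10 lost -> 80 + 0.8 * 10 = 88
  one <- data.frame(bin = "a", n_flc = 2L, n_total = 80L)
  lost1 <- data.frame(bin = "a", n_flc = 0L, n_total = 10L)
  expect_equal(renormalizeMissing(one, lost1, 0.8)$n_total, 88)

  expect_error(renormalizeMissing(one, lost1, 1.4), "probability")
  expect_error(renormalizeMissing(one, transform(lost1, n_total = -1L),
                                  0.5), "negative")
})

test_that("restrict at infinity then renormalize is the identity", {
  zips <- generateZip3Centroids(sprintf("9%02d", 41:52),
                                centerZip3 = "941")
  co <- generateEmrCohort(cohortSimParams(nPatients = 1500, seed = 19))
  r <- restrictByDistance(co, zips, "941", 1e9)
  ret <- binCounts(r$retained)
  lost <- binCounts(r$missing)
  mappable <- binCounts(rbind(r$retained[names(co)], r$excluded[names(co)]))
  frac <- ifelse(mappable$n_total > 0,
                 ret$n_total / mappable$n_total, 0)
  adj <- renormalizeMissing(ret, lost, frac)
  expect_equal(adj$n_total, binCounts(co)$n_total, tolerance = 1e-9)
  expect_equal(adj$n_flc, binCounts(co)$n_flc, tolerance = 1e-9)
})

test_that("distance sweep reruns the simulation per threshold", {
  zips <- generateZip3Centroids(sprintf("9%02d", 41:48),
                                centerZip3 = "941",
                                ringSpacingMiles = 100)
  # constructed referral geometry: HCC local, FLC referred from afar
  n <- 300
  labels <- rep(c("HCC", "FLC"), c(200, 100))
  co <- data.frame(patient_id = sprintf("p%03d", 1:n),
                   age = rep(c(45L, 20L), c(200, 100)),
                   codes = "C22.0", label = labels,
                   zip3 = ifelse(labels == "HCC", "942", "948"),
                   stringsAsFactors = FALSE)
  st <- data.frame(bin = ageBins()$label,
                   mean_count = c(100, 200, 300, 400, 500),
                   sd_count = rep(10, 5))
  sw <- incidenceDistanceSweep(co, zips, "941",
                               thresholds = c(2000, 500, 150),
                               stats = st, nReps = 1500,
                               coverageFactor = 1, population = 1e6,
                               seed = 4, seedMode = "shared")
  expect_equal(nrow(sw$sweep), 3L)
  expect_equal(sw$sweep$threshold_miles, c(2000, 500, 150))
  # distant FLC referrals drop out as the threshold shrinks
  expect_true(all(diff(sw$sweep$mean_cases) <= 0))
  expect_equal(sw$sweep$n_retained[1], n)
})

test_that("a no-op threshold with a shared seed reproduces the unrestricted run", {
  zips <- generateZip3Centroids(sprintf("9%02d", 41:48),
                                centerZip3 = "941",
                                ringSpacingMiles = 100)
  co <- generateEmrCohort(cohortSimParams(nPatients = 800, seed = 21,
                                          zip3Pool = zips$zip3,
                                          zip3Weights = rep(1, 8)))
  st <- data.frame(bin = ageBins()$label,
                   mean_count = c(100, 200, 300, 400, 500),
                   sd_count = rep(20, 5))
  sw <- incidenceDistanceSweep(co, zips, "941", thresholds = 1e9,
                               stats = st, nReps = 2000,
                               coverageFactor = 1, population = 1e6,
                               seed = 77, seedMode = "shared")
  direct <- simulateIncidence(fitPosterior(binCounts(co)), st,
                              nReps = 2000, coverageFactor = 1,
                              population = 1e6, seed = 77)
  expect_identical(meanCases(sw$estimates[[1]]), meanCases(direct))
  expect_identical(sdCases(sw$estimates[[1]]), sdCases(direct))
})
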