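test_that("encounter assembly applies the screen, window and completeness rules", {
  stream <- list(
    ok = completeEncounter(ammonia = 80),
    at_threshold = completeEncounter(ammonia = 50),
    below = completeEncounter(ammonia = 49),
    incomplete = completeEncounter(ammonia = 90)[-2, ],    # drop sodium
    out_of_window = {
      e <- completeEncounter(ammonia = 70)
      e$hours[e$analyte == "chloride"] <- 8 * 24           # beyond 7 d
      e
    },
    no_ammonia = completeEncounter(ammonia = 60)[-1, ]
  )
  res <- assembleEncounters(makeLabStream(stream))
  expect_setequal(colnames(res$experiment), c("ok", "at_threshold"))
  expect_equal(res$audit$reason[res$audit$encounter_id == "below"],
               "below_threshold")
  expect_equal(res$audit$reason[res$audit$encounter_id == "incomplete"],
               "incomplete_panel")
  expect_equal(res$audit$reason[res$audit$encounter_id == "out_of_window"],
               "incomplete_panel")
  expect_equal(res$audit$reason[res$audit$encounter_id == "no_ammonia"],
               "no_ammonia")
  expect_equal(maxAmmonia(res$experiment)[["at_threshold"]], 50)
})

test_that("the temporally closest draw is selected, ties to the earlier one", {
  base <- completeEncounter(ammonia = 75)
  # extra sodium values at +2 h and -30 h from the ammonia peak
  extra <- rbind(base,
                 data.frame(analyte = "sodium", value = c(111, 222),
                            hours = c(2, -30)))
  extra$value[extra$analyte == "sodium" & extra$hours == 1] <- 999
  # nearest is the original at +1 h
  res <- assembleEncounters(makeLabStream(list(e1 = extra)))
  expect_equal(assay(res$experiment, "labs")["sodium", "e1"], 999)

  # remove the +1 h value: +2 h beats -30 h
  extra2 <- extra[!(extra$analyte == "sodium" & extra$hours == 1), ]
  res2 <- assembleEncounters(makeLabStream(list(e1 = extra2)))
  expect_equal(assay(res2$experiment, "labs")["sodium", "e1"], 111)

  # exact tie in |dt|: earlier measurement wins
  tie <- rbind(base[base$analyte != "potassium", ],
               data.frame(analyte = "potassium", value = c(3.3, 4.4),
                          hours = c(-6, 6)))
  res3 <- assembleEncounters(makeLabStream(list(e1 = tie)))
  expect_equal(assay(res3$experiment, "labs")["potassium", "e1"], 3.3)

  bad <- makeLabStream(list(e1 = base))
  bad$analyte[2] <- "glucose"
  expect_error(assembleEncounters(bad), "unknown analyte")
  bad2 <- makeLabStream(list(e1 = base))
  bad2$timestamp[1] <- "not-a-time"
  expect_error(assembleEncounters(bad2), "timestamp")
})

test_that("z-scoring matches the closed form and flags constant columns", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 8, 12))
  z <- scaleMatrix(m)
  expect_equal(z[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(scaleMatrix(z), z, tolerance = 1e-9)
  zs <- scaleMatrix(m, sdType = "sample")
  expect_equal(zs[2, ], c(a = 0, b = 0))
  expect_equal(apply(zs, 2, sd), c(a = 1, b = 1))
  expect_error(scaleMatrix(cbind(a = c(1, 2), b = c(5, 5))), "b")
})

test_that("kNN graph construction respects the metric and PCA cap", {
  line <- matrix(c(0, 1, 10), ncol = 1)
  g <- buildGraph(line, nNeighbors = 1, nPcs = 0)
  expect_true(igraph::are_adjacent(g, 1, 2))
  expect_false(igraph::are_adjacent(g, 1, 3))

  withr::with_seed(3, {
    m <- matrix(rnorm(30 * 4), 30, 4)
    # Minkowski p = 2 equals Euclidean on the same data
    d2 <- as.matrix(dist(m))
    dm <- as.matrix(dist(m, method = "minkowski", p = 2))
    expect_equal(dm, d2, tolerance = 1e-12)
    g2 <- buildGraph(m, nNeighbors = 3, nPcs = 0, minkowskiP = 2)
    ge <- buildGraph(m, nNeighbors = 3, nPcs = 0)
    expect_identical(igraph::as_edgelist(g2), igraph::as_edgelist(ge))
    # full-rank PCA is a rigid rotation: pairwise distances preserved
    pc <- prcomp(m, center = TRUE)$x
    expect_equal(as.matrix(dist(pc)), as.matrix(dist(scale(m, scale = FALSE))),
                 tolerance = 1e-9, ignore_attr = TRUE)
    gp <- buildGraph(m, nNeighbors = 3, nPcs = 40)
    expect_identical(igraph::as_edgelist(gp), igraph::as_edgelist(ge))
  })
  expect_error(buildGraph(line, nNeighbors = 5), "more points")
})

test_that("Leiden partitions respect graph structure and the seed", {
  # two cliques with no connecting edge
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(4))
  lab <- clusterGraph(g, resolution = 0.2, seed = 1)
  expect_equal(nlevels(lab), 2L)
  expect_equal(as.integer(lab), rep(c(1L, 2L), c(6, 4)))

  expect_identical(clusterGraph(g, seed = 5), clusterGraph(g, seed = 5))
  expect_error(clusterGraph(igraph::make_empty_graph(0)), "empty")
})

test_that("planted mixtures are recovered across a resolution band", {
  prm <- separatedLabParams(4, 400, sep = 10, seed = 14)
  gen <- generateLabEncounters(prm)
  z <- scaleMatrix(gen$panel)
  g <- buildGraph(z, nNeighbors = 5)
  for (res in c(0.1, 0.2, 0.35, 0.5)) {
    lab <- clusterGraph(g, resolution = res, seed = 7)
    expect_equal(nlevels(lab), 4L)
    expect_gte(ari(lab, gen$truth$cluster), 0.99)
  }
  # permuting encounter order only permutes the labels
  perm <- withr::with_seed(8, sample(nrow(z)))
  lab0 <- clusterGraph(g, resolution = 0.2, seed = 7)
  labp <- clusterGraph(buildGraph(z[perm, ], nNeighbors = 5),
                       resolution = 0.2, seed = 7)
  expect_equal(ari(lab0[perm], labp), 1)
  # k-means baseline agrees on well-separated data
  expect_equal(ari(kmeansBaseline(z, 4, seed = 2), gen$truth$cluster), 1)
})

test_that("cluster profiles are brute-force medians of raw values", {
  prm <- separatedLabParams(3, 90, sep = 10, seed = 31)
  gen <- generateLabEncounters(prm)
  lab <- factor(gen$truth$cluster)
  prof <- clusterProfiles(gen$panel, lab)
  for (i in sample(nrow(prof), 10)) {
    v <- gen$panel[lab == prof$cluster[i], prof$analyte[i]]
    expect_equal(prof$median[i], median(v))
    expect_equal(prof$q25[i], quantile(v, 0.25, names = FALSE))
  }
  # single cluster: medians equal the global medians
  one <- clusterProfiles(gen$panel, factor(rep(1, nrow(gen$panel))))
  expect_equal(one$median,
               apply(gen$panel, 2, median)[one$analyte],
               ignore_attr = TRUE)
  # cluster of one encounter reproduces that encounter
  solo <- clusterProfiles(gen$panel[1:2, ], factor(c(1, 2)))
  expect_equal(solo$median[solo$cluster == "1"],
               unname(gen$panel[1, solo$analyte[solo$cluster == "1"]]))
})

test_that("the encounter pipeline is deterministic end to end", {
  gen <- generateLabEncounters(labSimParams(nEncounters = 150, seed = 3))
  run <- function() {
    asm <- assembleEncounters(gen$events)
    lpe <- clusterEncounters(asm$experiment, seed = 10)
    list(labels = clusterLabels(lpe),
         cfg = metadata(lpe)$cluster_config)
  }
  expect_identical(run(), run())
})
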