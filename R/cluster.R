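## Hyperammonemia encounter assembly and graph-based clustering,
## mirroring the single-cell workflow: z-score scaling, PCA,
## k-nearest-neighbour graph under a Minkowski metric, Leiden community
## detection.

#' Assemble hyperammonemia encounters from a lab-event stream
#'
#' For every encounter whose maximum ammonia reaches the
#' hyperammonemia threshold, the temporally closest measurement of each
#' CMP analyte to the peak-ammonia draw is selected; encounters missing
#' any analyte within the window are excluded and audited. Multiple
#' encounters per patient are allowed. Ties in |time difference| go to
#' the earlier measurement.
#'
#' @param events long `data.frame`: `encounter_id`, `patient_id`,
#'   `analyte`, `value`, `timestamp` (ISO-8601 or `POSIXct`);
#'   `diagnosis` optional.
#' @param ammoniaThreshold hyperammonemia screen on the encounter
#'   maximum ammonia, in micromol/L; the boundary value is retained
#'   (`>=`).
#' @param windowDays every panel analyte must lie within this many days
#'   of the peak ammonia draw.
#' @return list with `experiment` (a [LabPanelExperiment-class]) and
#'   `audit` (`data.frame` of excluded encounters with a `reason`:
#'   `no_ammonia`, `below_threshold`, or `incomplete_panel`).
#' @export
assembleEncounters <- function(events, ammoniaThreshold = 50,
                               windowDays = 7) {
  known <- labAnalytes()
  bad <- setdiff(unique(events$analyte), known)
  if (length(bad)) {
    stop("unknown analyte name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ts <- events$timestamp
  if (!inherits(ts, "POSIXct")) {
    raw <- as.character(ts)
    ts <- tryCatch(
      as.POSIXct(raw, tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                "%Y-%m-%dT%H:%M:%OS",
                                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")),
      error = function(e) rep(as.POSIXct(NA), length(raw)))
    if (anyNA(ts)) {
      stop("unparseable timestamp(s), e.g. ",
           raw[which(is.na(ts))[1]], call. = FALSE)
    }
  }
  window <- windowDays * 86400
  eids <- unique(events$encounter_id)
  rows_by_enc <- split(seq_len(nrow(events)),
                       factor(events$encounter_id, levels = eids))
  cmp <- cmpAnalytes()
  panels <- matrix(NA_real_, nrow = 11L, ncol = length(eids),
                   dimnames = list(known, eids))
  pid <- diag_lab <- rep(NA_character_, length(eids))
  reason <- rep(NA_character_, length(eids))
  for (j in seq_along(eids)) {
    rows <- rows_by_enc[[j]]
    pid[j] <- events$patient_id[rows[1]]
    diag_lab[j] <- if ("diagnosis" %in% names(events)) {
      events$diagnosis[rows[1]]
    } else "unknown"
    amm <- rows[events$analyte[rows] == "ammonia"]
    if (length(amm) == 0L) { reason[j] <- "no_ammonia"; next }
    imax <- amm[which.max(events$value[amm])]
    if (events$value[imax] < ammoniaThreshold) {
      reason[j] <- "below_threshold"; next
    }
    t0 <- ts[imax]
    vals <- c(ammonia = events$value[imax])
    for (a in cmp) {
      cand <- rows[events$analyte[rows] == a]
      if (length(cand) == 0L) break
      dt <- abs(as.numeric(ts[cand]) - as.numeric(t0))
      cand <- cand[dt <= window]
      dt <- dt[dt <= window]
      if (length(cand) == 0L) break
      ## nearest in absolute time; exact tie -> earlier draw wins
      best <- cand[order(dt, as.numeric(ts[cand]))][1L]
      vals[a] <- events$value[best]
    }
    if (length(vals) < 11L) { reason[j] <- "incomplete_panel"; next }
    panels[, j] <- vals[known]
  }
  keep <- is.na(reason)
  audit <- data.frame(encounter_id = eids[!keep],
                      reason = reason[!keep], stringsAsFactors = FALSE)
  lpe <- LabPanelExperiment(
    panels[, keep, drop = FALSE], patientId = pid[keep],
    diagnosis = diag_lab[keep],
    metadata = list(ammonia_threshold = ammoniaThreshold,
                    window_days = windowDays))
  list(experiment = lpe, audit = audit)
}

#' Extract the clustering feature matrix
#'
#' @param x a [LabPanelExperiment-class].
#' @param includeAmmonia keep the peak-ammonia variable as a feature
#'   (default), giving the full 11-variable space; `FALSE` restricts to
#'   the 10 CMP analytes, with ammonia acting only as the selection
#'   criterion.
#' @return encounters x analytes numeric matrix (raw units).
#' @export
panelMatrix <- function(x, includeAmmonia = TRUE) {
  m <- t(assay(x, "labs"))
  if (!includeAmmonia) m <- m[, cmpAnalytes(), drop = FALSE]
  m
}

#' Z-score a feature matrix
#'
#' Centers each column to mean 0 and scales to unit variance. The SD
#' convention defaults to the population form (denominator n), matching
#' the single-cell scaling this workflow mirrors; the sample form
#' (n - 1) is available.
#'
#' @param mat encounters x analytes numeric matrix, n >= 2.
#' @param sdType `"population"` (default) or `"sample"`.
#' @return standardized matrix of the same shape.
#' @export
scaleMatrix <- function(mat, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (nrow(mat) < 2L) stop("need at least 2 rows", call. = FALSE)
  mu <- colMeans(mat)
  centered <- sweep(mat, 2L, mu)
  ss <- sqrt(colSums(centered^2) /
               (nrow(mat) - (sdType == "sample")))
  zero <- ss == 0 | !is.finite(ss)
  if (any(zero)) {
    stop("zero-variance analyte column(s): ",
         paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(centered, 2L, ss, "/")
}

#' Build a k-nearest-neighbour graph
#'
#' Optionally projects onto principal components — the PC count is
#' capped at min(nPcs, n_features, n - 1), so a nominal 40 PCs on 11
#' features keeps all 11 (a full-rank rotation that preserves Euclidean
#' geometry) — then connects each point to its k nearest neighbours
#' under the Minkowski-p metric. The graph is union-symmetrized,
#' unweighted (all edge weights 1) and has no self-edges.
#'
#' @param mat standardized feature matrix (rows = encounters).
#' @param nNeighbors neighbours per point (default 5).
#' @param nPcs nominal number of principal components (default 40,
#'   capped as above); `0` skips PCA.
#' @param minkowskiP Minkowski exponent (>= 1; 2 = Euclidean).
#' @return an undirected [igraph::graph] with `n` vertices.
#' @export
buildGraph <- function(mat, nNeighbors = 5L, nPcs = 40L,
                       minkowskiP = 2) {
  n <- nrow(mat)
  if (n <= nNeighbors) {
    stop("need more points than neighbours (n = ", n, ", k = ",
         nNeighbors, ")", call. = FALSE)
  }
  if (minkowskiP < 1) stop("minkowskiP must be >= 1", call. = FALSE)
  if (nPcs > 0L) {
    keep <- min(nPcs, ncol(mat), n - 1L)
    mat <- stats::prcomp(mat, center = TRUE,
                         scale. = FALSE)$x[, seq_len(keep), drop = FALSE]
  }
  d <- as.matrix(stats::dist(mat, method = "minkowski", p = minkowskiP))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(nNeighbors)]))
  edges <- cbind(rep(seq_len(n), each = nNeighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  g <- igraph::as_undirected(g, mode = "collapse")
  igraph::simplify(g)
}

#' Leiden community detection
#'
#' Partitions the neighbourhood graph by Leiden clustering under the
#' resolution-parameterized modularity objective. Deterministic given
#' the seed; labels are renumbered by descending cluster size.
#'
#' @param graph an undirected [igraph::graph].
#' @param resolution modularity resolution (default 0.2; lower gives
#'   coarser partitions).
#' @param seed RNG seed.
#' @param nIterations Leiden refinement iterations.
#' @return factor of cluster labels, one per vertex, levels `"1"`
#'   (largest) upward.
#' @export
clusterGraph <- function(graph, resolution = 0.2, seed = 1L,
                         nIterations = 10L) {
  if (igraph::vcount(graph) == 0L) {
    stop("empty graph", call. = FALSE)
  }
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  memb <- withSeed(seed, {
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity",
      resolution = resolution, n_iterations = nIterations))
  })
  ## stable size-descending relabel (ties by first appearance)
  sizes <- table(memb)
  ord <- order(-as.integer(sizes),
               match(names(sizes), as.character(memb)))
  relab <- match(as.character(memb), names(sizes)[ord])
  factor(relab, levels = seq_along(sizes))
}

#' Cluster the encounters of a LabPanelExperiment
#'
#' Runs scale -> PCA/kNN graph -> Leiden on the encounter panel and
#' stores the labels in `colData(x)$cluster` with the configuration in
#' the object metadata.
#'
#' @inheritParams panelMatrix
#' @inheritParams buildGraph
#' @inheritParams clusterGraph
#' @return `x` with a `cluster` column and a `cluster_config` metadata
#'   entry.
#' @export
clusterEncounters <- function(x, includeAmmonia = TRUE, nNeighbors = 5L,
                              nPcs = 40L, minkowskiP = 2,
                              resolution = 0.2, seed = 1L,
                              sdType = "population") {
  mat <- scaleMatrix(panelMatrix(x, includeAmmonia), sdType = sdType)
  g <- buildGraph(mat, nNeighbors = nNeighbors, nPcs = nPcs,
                  minkowskiP = minkowskiP)
  labels <- clusterGraph(g, resolution = resolution, seed = seed)
  colData(x)$cluster <- labels
  metadata(x)$cluster_config <- list(
    include_ammonia = includeAmmonia, n_neighbors = nNeighbors,
    n_pcs = nPcs, minkowski_p = minkowskiP, resolution = resolution,
    seed = seed, sd_type = sdType, n_clusters = nlevels(labels))
  x
}

#' Per-cluster analyte profiles
#'
#' Median and quartiles of every analyte within every cluster, on raw
#' (unscaled) values.
#'
#' @param x a clustered [LabPanelExperiment-class], or a raw
#'   encounters x analytes matrix.
#' @param labels cluster labels (taken from `x` when omitted).
#' @return `data.frame` keyed by (`cluster`, `analyte`) with `median`,
#'   `q25`, `q75`, `n`.
#' @export
clusterProfiles <- function(x, labels = NULL) {
  if (is(x, "LabPanelExperiment")) {
    if (is.null(labels)) labels <- clusterLabels(x)
    mat <- panelMatrix(x)
  } else {
    mat <- x
  }
  if (is.null(labels) || length(labels) != nrow(mat)) {
    stop("labels must align with encounters", call. = FALSE)
  }
  labels <- factor(labels)
  out <- expand.grid(cluster = levels(labels), analyte = colnames(mat),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qs <- mapply(function(cl, a) {
    v <- mat[labels == cl, a]
    c(stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE), length(v))
  }, out$cluster, out$analyte)
  out$median <- qs[1, ]
  out$q25 <- qs[2, ]
  out$q75 <- qs[3, ]
  out$n <- as.integer(qs[4, ])
  out
}

#' K-means baseline partition
#'
#' Convenience wrapper used to compare the graph-based partition with a
#' centroid-based one on the same standardized matrix.
#'
#' @param mat standardized feature matrix.
#' @param k number of centers.
#' @param seed RNG seed.
#' @return factor of cluster labels, size-descending relabel.
#' @export
kmeansBaseline <- function(mat, k, seed = 1L) {
  km <- withSeed(seed, stats::kmeans(mat, centers = k, nstart = 10L))
  sizes <- table(km$cluster)
  ord <- order(-as.integer(sizes),
               match(names(sizes), as.character(km$cluster)))
  factor(match(as.character(km$cluster), names(sizes)[ord]),
         levels = seq_along(sizes))
}
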