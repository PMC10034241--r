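## Diagnosis-enrichment testing within clusters: 2x2 contingency
## tables, Fisher's exact test, and the multiplicative multiple-testing
## corrections used for single clusters (x k) and cluster pairs
## (x choose(k, 2)). Encounters, not unique patients, are the unit of
## analysis.

#' Build a 2x2 diagnosis-by-cluster contingency table
#'
#' @param labels cluster labels, one per encounter.
#' @param diagnosisFlags logical, `TRUE` where the encounter carries
#'   the diagnosis of interest.
#' @param clusterSet one or two cluster labels; a pair is pooled into
#'   the "in" margin.
#' @return named integer vector `c(a, b, c, d)` =
#'   (in & diagnosed, in & other, out & diagnosed, out & other).
#' @export
makeTable <- function(labels, diagnosisFlags, clusterSet) {
  stopifnot(length(labels) == length(diagnosisFlags))
  if (length(clusterSet) == 0L) {
    stop("clusterSet must contain 1 or 2 cluster labels", call. = FALSE)
  }
  unknown <- setdiff(as.character(clusterSet),
                     as.character(unique(labels)))
  if (length(unknown)) {
    stop("unknown cluster label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  inset <- as.character(labels) %in% as.character(clusterSet)
  c(a = sum(inset & diagnosisFlags), b = sum(inset & !diagnosisFlags),
    c = sum(!inset & diagnosisFlags), d = sum(!inset & !diagnosisFlags))
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test. The two-sided p-value sums the
#' probabilities of all tables (with the observed margins) whose
#' probability is at most that of the observed table — stated
#' explicitly because two-sided exact-test conventions vary. The odds
#' ratio is the sample ratio `ad / bc` (`Inf` when `bc = 0` and
#' `ad > 0`; `NaN` when both products are 0).
#'
#' @param tab named or ordered vector `c(a, b, c, d)` as from
#'   [makeTable()].
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisherExact <- function(tab) {
  tab <- as.numeric(tab)
  if (length(tab) != 4L || any(tab < 0) || any(tab != floor(tab))) {
    stop("need four non-negative integer counts (a, b, c, d)",
         call. = FALSE)
  }
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  or <- if (b * cc > 0) (a * d) / (b * cc) else if (a * d > 0) Inf else NaN
  m <- a + b           # row-1 margin
  k <- a + cc          # col-1 margin
  n <- a + b + cc + d
  lo <- max(0, k - (n - m))
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n - m, k)
  ## relative slack guards against ties lost to floating-point rounding
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  list(odds_ratio = or, p_value = min(1, p))
}

#' Multiplicative correction for single-cluster tests
#'
#' Each p-value is multiplied by the number of clusters and capped at
#' 1 — the Bonferroni-style correction applied per diagnosis when every
#' cluster is tested once.
#'
#' @param pValues numeric vector of p-values.
#' @param nClusters number of clusters tested (>= 1).
#' @return adjusted p-values.
#' @export
adjustSingle <- function(pValues, nClusters) {
  if (nClusters < 1) stop("nClusters must be >= 1", call. = FALSE)
  pmin(1, pValues * nClusters)
}

#' Multiplicative correction for cluster-pair tests
#'
#' Multiplies by `choose(nClusters, 2)`, the number of unordered
#' cluster pairs, capped at 1. A `literalFactor` override is provided
#' for sensitivity to alternative factor conventions.
#'
#' @param pValues numeric vector of p-values.
#' @param nClusters number of clusters (>= 2).
#' @param literalFactor optional explicit multiplier replacing
#'   `choose(nClusters, 2)`.
#' @return adjusted p-values.
#' @export
adjustPairs <- function(pValues, nClusters, literalFactor = NULL) {
  if (nClusters < 2) stop("nClusters must be >= 2", call. = FALSE)
  f <- if (is.null(literalFactor)) choose(nClusters, 2) else literalFactor
  pmin(1, pValues * f)
}

#' Test every diagnosis against every cluster (and cluster pair)
#'
#' One Fisher test per diagnosis x cluster; with `includePairs`, also
#' per diagnosis x unordered cluster pair, pooling the pair into one
#' 2x2 table. `method = "multiplicative"` applies the
#' multiplicative corrections of [adjustSingle()]/[adjustPairs()]
#' within each family; `"bh"` applies Benjamini-Hochberg across each
#' diagnosis's family instead (a true FDR procedure, provided because
#' the multiplicative scheme controls family-wise error despite often
#' being labelled FDR).
#'
#' @param labels cluster labels per encounter.
#' @param diagnoses diagnosis string per encounter; encounters whose
#'   diagnosis should not be tested (e.g. `"other"`) are simply never a
#'   query, but always count in the margins.
#' @param testDiagnoses which diagnoses to test (default: all except
#'   `"other"`/`NA`).
#' @param includePairs also test pooled cluster pairs.
#' @param method correction scheme.
#' @return `data.frame` sorted by adjusted then raw p: `diagnosis`,
#'   `clusters` ("3" or "1+7"), `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`, `p_adjusted`, `correction_factor`.
#' @export
enrichAll <- function(labels, diagnoses, testDiagnoses = NULL,
                      includePairs = FALSE,
                      method = c("multiplicative", "bh")) {
  method <- match.arg(method)
  stopifnot(length(labels) == length(diagnoses))
  labels <- factor(labels)
  k <- nlevels(labels)
  if (is.null(testDiagnoses)) {
    testDiagnoses <- setdiff(unique(diagnoses[!is.na(diagnoses)]),
                             "other")
  }
  if (length(testDiagnoses) == 0L) {
    return(data.frame(diagnosis = character(), clusters = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      correction_factor = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (includePairs && k < 2L) {
    stop("pair mode needs at least 2 clusters", call. = FALSE)
  }
  sets <- as.list(levels(labels))
  names(sets) <- levels(labels)
  fam <- rep("single", k)
  if (includePairs) {
    pr <- utils::combn(levels(labels), 2L, simplify = FALSE)
    names(pr) <- vapply(pr, paste, "", collapse = "+")
    sets <- c(sets, pr)
    fam <- c(fam, rep("pair", length(pr)))
  }
  res <- lapply(testDiagnoses, function(dg) {
    flags <- !is.na(diagnoses) & diagnoses == dg
    rows <- lapply(seq_along(sets), function(i) {
      tb <- makeTable(labels, flags, sets[[i]])
      ft <- fisherExact(tb)
      data.frame(diagnosis = dg, clusters = names(sets)[i],
                 a = tb[["a"]], b = tb[["b"]], c = tb[["c"]],
                 d = tb[["d"]], odds_ratio = ft$odds_ratio,
                 p_value = ft$p_value, family = fam[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  if (method == "multiplicative") {
    out$correction_factor <- ifelse(out$family == "single", k,
                                    choose(k, 2))
    out$p_adjusted <- pmin(1, out$p_value * out$correction_factor)
  } else {
    out$correction_factor <- NA_real_
    out$p_adjusted <- NA_real_
    for (dg in unique(out$diagnosis)) {
      for (fm in unique(out$family)) {
        i <- out$diagnosis == dg & out$family == fm
        out$p_adjusted[i] <- stats::p.adjust(out$p_value[i],
                                             method = "BH")
      }
    }
  }
  out$family <- NULL
  out <- out[order(out$p_adjusted, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
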