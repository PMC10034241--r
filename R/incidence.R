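## Bayesian inference of age-specific subtype proportions and Monte
## Carlo extrapolation to annual national incidence.
##
## Model: within each decade age bin b the number of validated FLC
## cases among n_total liver-cancer patients is Binomial(n_total, p_b);
## a Beta(a0, b0) prior gives the conjugate posterior
## Beta(a0 + n_flc, b0 + n_total - n_flc). Bins with little data keep
## wide posteriors, propagating institutional sampling uncertainty into
## the national estimate. Each Monte Carlo replicate draws a national
## claims count per bin from Normal(mean, sd) (truncated at 0,
## rounded), a proportion from the bin posterior, and a binomial FLC
## count; replicate totals scaled by the coverage factor summarize
## annual national incidence.

#' Conjugate beta-binomial posterior per age bin
#'
#' @param counts an age-bin count table from [binCounts()] (columns
#'   `bin`, `n_flc`, `n_total`; real-valued totals from
#'   [renormalizeMissing()] are accepted — generalized conjugacy).
#' @param priorAlpha,priorBeta Beta prior hyperparameters (> 0).
#'   Default uniform Beta(1,1); use 0.5, 0.5 for the Jeffreys prior.
#' @return `data.frame` with `bin`, `alpha`, `beta`; an empty bin
#'   returns the prior unchanged (maximal uncertainty).
#' @export
fitPosterior <- function(counts, priorAlpha = 1, priorBeta = 1) {
  if (priorAlpha <= 0 || priorBeta <= 0) {
    stop("prior hyperparameters must be > 0", call. = FALSE)
  }
  if (any(counts$n_flc < 0) || any(counts$n_flc > counts$n_total + 1e-12)) {
    stop("need 0 <= n_flc <= n_total in every bin", call. = FALSE)
  }
  data.frame(bin = counts$bin,
             alpha = priorAlpha + counts$n_flc,
             beta = priorBeta + (counts$n_total - counts$n_flc),
             stringsAsFactors = FALSE)
}

#' Per-bin claims count statistics across reference years
#'
#' Sample mean and sample SD (denominator n - 1) of annual counts over
#' the listed years, one row per age bin. Years tainted by known
#' confounding (e.g. pandemic years) are simply left off the list.
#'
#' @param claims `data.frame` with `year`, `age_bin`, `count`.
#' @param years reference years; all must be present in the table.
#' @param sdOverride optional named numeric of per-bin SDs, required if
#'   fewer than two years are requested.
#' @return `data.frame` with `bin`, `mean_count`, `sd_count`,
#'   `n_years`.
#' @export
claimsStats <- function(claims, years, sdOverride = NULL) {
  missing_years <- setdiff(years, unique(claims$year))
  if (length(missing_years)) {
    stop("years absent from claims table: ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  sub <- claims[claims$year %in% years, , drop = FALSE]
  bins <- unique(sub$age_bin)
  mu <- vapply(bins, function(b) mean(sub$count[sub$age_bin == b]), 0)
  if (length(years) < 2L) {
    if (is.null(sdOverride)) {
      stop("sample SD is undefined for < 2 years; supply sdOverride",
           call. = FALSE)
    }
    sdv <- as.numeric(sdOverride[bins])
  } else {
    sdv <- vapply(bins, function(b) stats::sd(sub$count[sub$age_bin == b]), 0)
  }
  data.frame(bin = bins, mean_count = as.numeric(mu),
             sd_count = sdv, n_years = length(years),
             stringsAsFactors = FALSE)
}

#' Monte Carlo simulation of annual national incidence
#'
#' @param posteriors output of [fitPosterior()].
#' @param stats output of [claimsStats()]; bins must match
#'   `posteriors$bin` (order-insensitive).
#' @param nReps number of replicate national populations.
#' @param coverageFactor multiplier taking claims-covered counts to the
#'   national scale (claims enrollment is a fraction of the country);
#'   must be supplied — there is no defensible default.
#' @param population national population used for the per-100k rate.
#' @param seed RNG seed; identical inputs and seed give bit-identical
#'   estimates.
#' @param mode `"binomial"` (default) draws the subtype count
#'   Binomial(N, p) per replicate — fully generative; `"expectation"`
#'   uses N * p, isolating parameter uncertainty from binomial noise.
#' @param keepReps retain the replicate totals (needed for convergence
#'   checks and sweep diagnostics).
#' @return an [IncidenceEstimate-class].
#' @export
simulateIncidence <- function(posteriors, stats, nReps = 10000L,
                              coverageFactor, population,
                              seed = 1L,
                              mode = c("binomial", "expectation"),
                              keepReps = FALSE) {
  mode <- match.arg(mode)
  if (missing(coverageFactor) || coverageFactor <= 0) {
    stop("coverageFactor must be supplied and > 0", call. = FALSE)
  }
  if (population <= 0) stop("population must be > 0", call. = FALSE)
  m <- match(posteriors$bin, stats$bin)
  if (anyNA(m)) {
    stop("claims stats missing for bin(s): ",
         paste(posteriors$bin[is.na(m)], collapse = ", "), call. = FALSE)
  }
  stats <- stats[m, , drop = FALSE]
  nReps <- assertCount(nReps, "nReps")
  totals <- withSeed(seed, {
    tot <- numeric(nReps)
    for (b in seq_len(nrow(posteriors))) {
      N <- round(pmax(0, stats::rnorm(nReps, stats$mean_count[b],
                                      stats$sd_count[b])))
      p <- stats::rbeta(nReps, posteriors$alpha[b], posteriors$beta[b])
      f <- if (mode == "binomial") {
        stats::rbinom(nReps, size = as.integer(N), prob = p)
      } else {
        N * p
      }
      tot <- tot + f
    }
    tot
  })
  scaled <- coverageFactor * totals
  mu <- mean(scaled)
  new("IncidenceEstimate",
      meanCases = mu,
      sdCases = if (nReps > 1L) stats::sd(scaled) else 0,
      per100k = casesToRate(mu, population),
      nReps = nReps,
      coverageFactor = as.numeric(coverageFactor),
      population = as.numeric(population),
      seed = as.integer(seed),
      repTotals = if (keepReps) scaled else numeric())
}

#' Convert annual case counts to a per-100,000 rate
#'
#' @param cases annual case count.
#' @param population reference population (> 0).
#' @return `100000 * cases / population`.
#' @export
casesToRate <- function(cases, population) {
  if (population <= 0) stop("population must be > 0", call. = FALSE)
  1e5 * cases / population
}
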