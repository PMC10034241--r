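## Cohort construction: ICD-10 inclusion/exclusion filtering, decade
## age-bin summaries, and code co-occurrence rates.

normalizeCodes <- function(codes) toupper(trimws(codes))

splitCodes <- function(codes) {
  lapply(strsplit(ifelse(is.na(codes), "", codes), ";", fixed = TRUE),
         normalizeCodes)
}

#' ICD code inclusion/exclusion policy
#'
#' @param include inclusion codes; defaults to the two liver-cancer
#'   ICD-10-CM codes C22.0 ("liver cell carcinoma") and C22.7 ("other
#'   specified carcinoma of the liver").
#' @param exclude exclusion codes (e.g. a chronic-liver-inflammation
#'   list); may be empty.
#' @param prefixMatch if `TRUE`, a policy code also matches any patient
#'   code it prefixes (so "B18" matches "B18.2"). Default off: explicit
#'   code lists are matched exactly on normalized (uppercased,
#'   dot-preserved) strings.
#' @return a `CodePolicy` list.
#' @export
codePolicy <- function(include = c("C22.0", "C22.7"),
                       exclude = character(), prefixMatch = FALSE) {
  include <- unique(normalizeCodes(include))
  exclude <- unique(normalizeCodes(exclude))
  if (length(include) == 0L) {
    stop("include code set must be non-empty", call. = FALSE)
  }
  if (length(intersect(include, exclude))) {
    stop("include and exclude code sets overlap: ",
         paste(intersect(include, exclude), collapse = ", "),
         call. = FALSE)
  }
  structure(list(include = include, exclude = exclude,
                 prefixMatch = isTRUE(prefixMatch)),
            class = "CodePolicy")
}

matchesAny <- function(codeList, set, prefixMatch = FALSE) {
  if (length(set) == 0L) return(rep(FALSE, length(codeList)))
  if (!prefixMatch) {
    vapply(codeList, function(x) any(x %in% set), logical(1))
  } else {
    vapply(codeList, function(x) {
      any(vapply(set, function(s) any(startsWith(x, s)), logical(1)))
    }, logical(1))
  }
}

#' Filter a cohort by ICD code policy
#'
#' Retains patients carrying at least one inclusion code and no
#' exclusion code. Order-stable and idempotent.
#'
#' @param patients `data.frame` with at least `codes`
#'   (semicolon-joined ICD strings).
#' @param policy a [codePolicy()].
#' @return list with `retained` (the filtered `data.frame`) and `audit`
#'   (counts: `n_input`, `n_no_include`, `n_excluded`, `n_retained`).
#' @export
applyCodePolicy <- function(patients, policy = codePolicy()) {
  stopifnot(inherits(policy, "CodePolicy"), "codes" %in% names(patients))
  cl <- splitCodes(patients$codes)
  has_inc <- matchesAny(cl, policy$include, policy$prefixMatch)
  has_exc <- matchesAny(cl, policy$exclude, policy$prefixMatch)
  keep <- has_inc & !has_exc
  list(retained = patients[keep, , drop = FALSE],
       audit = list(n_input = nrow(patients),
                    n_no_include = sum(!has_inc),
                    n_excluded = sum(has_inc & has_exc),
                    n_retained = sum(keep)))
}

#' Decade age bins
#'
#' @param cap upper age limit (exclusive); patients aged `cap` or older
#'   fall outside every bin. "Between 0 and 50" is read half-open.
#' @param width bin width in years.
#' @return `data.frame` with `label`, `lower` (inclusive), `upper`
#'   (exclusive) partitioning `[0, cap)`.
#' @export
ageBins <- function(cap = 50, width = 10) {
  lower <- seq(0, cap - width, by = width)
  upper <- lower + width
  data.frame(label = sprintf("[%g,%g)", lower, upper),
             lower = lower, upper = upper, stringsAsFactors = FALSE)
}

checkBinsPartition <- function(bins, cap) {
  o <- order(bins$lower)
  b <- bins[o, , drop = FALSE]
  if (any(b$lower >= b$upper)) {
    stop("age bins must have lower < upper", call. = FALSE)
  }
  if (b$lower[1] != 0 || b$upper[nrow(b)] != cap ||
      (nrow(b) > 1 && any(b$upper[-nrow(b)] != b$lower[-1]))) {
    stop("age bins must partition [0, ", cap, ") without gaps or overlap",
         call. = FALSE)
  }
  invisible(b)
}

#' Tally validated labels by age bin
#'
#' Counts every patient with age below `ageCap` exactly once; bins are
#' half-open `[lower, upper)`. `n_flc` counts validated FLC labels
#' only; patients labelled `UNKNOWN`/`OTHER` contribute to `n_total`
#' but never to `n_flc` (chart validation is the only source of FLC
#' truth).
#'
#' @param patients `data.frame` with `age` and `label` columns.
#' @param bins an [ageBins()] table partitioning `[0, ageCap)`.
#' @param ageCap exclusive upper age limit.
#' @return `data.frame` with `bin` (label), `lower`, `upper`, `n_flc`,
#'   `n_total`.
#' @export
binCounts <- function(patients, bins = ageBins(), ageCap = 50) {
  bins <- checkBinsPartition(bins, ageCap)
  inb <- patients$age >= 0 & patients$age < ageCap
  idx <- findInterval(patients$age[inb], c(bins$lower, ageCap))
  flc <- patients$label[inb] == "FLC"
  data.frame(bin = bins$label, lower = bins$lower, upper = bins$upper,
             n_flc = as.integer(vapply(seq_len(nrow(bins)),
                                       function(b) sum(flc & idx == b), 0L)),
             n_total = as.integer(tabulate(idx, nbins = nrow(bins))),
             stringsAsFactors = FALSE)
}

#' Code co-occurrence rate
#'
#' Count and fraction of patients carrying at least one code from a
#' query set (e.g. hyperammonemia diagnosis codes within the filtered
#' liver-cancer cohort).
#'
#' @param patients `data.frame` with `codes`.
#' @param codeSet query ICD codes.
#' @param prefixMatch see [codePolicy()].
#' @return list with `n`, `count`, `fraction` (`NaN` on an empty
#'   cohort).
#' @export
codeCooccurrenceRate <- function(patients, codeSet, prefixMatch = FALSE) {
  hits <- matchesAny(splitCodes(patients$codes), normalizeCodes(codeSet),
                     prefixMatch)
  list(n = nrow(patients), count = sum(hits),
       fraction = sum(hits) / nrow(patients))
}

#' Read a one-code-per-line ICD list
#'
#' @param path text file, one ICD code per line; blank lines and
#'   `#`-comments ignored.
#' @return character vector of normalized codes.
#' @export
readCodeList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalizeCodes(x))
}
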