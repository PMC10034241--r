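#' Analyte vocabulary
#'
#' The fixed laboratory vocabulary used throughout the package: blood
#' ammonia plus the ten complete-metabolic-panel (CMP) analytes that are
#' temporally matched to the peak ammonia draw. Together they form the
#' 11-variable feature space used for clustering.
#'
#' @return `labAnalytes()` returns all 11 analyte names (ammonia first);
#'   `cmpAnalytes()` returns the 10 CMP analytes.
#' @export
labAnalytes <- function() {
  c("ammonia", "sodium", "potassium", "chloride", "bicarbonate",
    "BUN", "creatinine", "ALT", "AST", "total_bilirubin",
    "alkaline_phosphatase")
}

#' @rdname labAnalytes
#' @export
cmpAnalytes <- function() labAnalytes()[-1L]

## Run code with a temporary RNG state; the caller's .Random.seed is
## restored on exit so package functions do not perturb user RNG streams.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministic derived seed, kept below 2^31 - 1. `tag` may be a stage
## name or an integer offset; stages can rerun independently yet
## reproducibly.
deriveSeed <- function(seed, tag) {
  if (is.character(tag)) {
    tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(tag) * 16807) %%
               2147483647)
}

assertProbability <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

assertCount <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop(what, " must be a non-negative integer", call. = FALSE)
  }
  invisible(as.integer(x))
}
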