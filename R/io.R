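## Plain-CSV readers/writers for the pipeline's interchange files.
## Round-trip safety (write then read recovers the table) is part of
## the contract and is tested.

#' Read and write pipeline CSV tables
#'
#' `patients.csv`: `patient_id, age, codes, label, zip3` (codes
#' semicolon-joined; empty zip3 read as missing).
#' `claims.csv`: `year, age_bin, count`.
#' `labs.csv`: `encounter_id, patient_id, diagnosis, analyte, value,
#' timestamp` (ISO-8601).
#' `zip3_centroids.csv`: `zip3, lat, lon`.
#'
#' @param x table to write.
#' @param path file path.
#' @return readers return a `data.frame`; writers return `path`
#'   invisibly.
#' @name pipelineIO
NULL

writeCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname pipelineIO
#' @export
writePatients <- function(x, path) writeCsv(x, path)

#' @rdname pipelineIO
#' @export
readPatients <- function(path) {
  x <- utils::read.csv(path, colClasses = c(
    patient_id = "character", age = "integer", codes = "character",
    label = "character", zip3 = "character"))
  x$zip3[!nzchar(x$zip3) | is.na(x$zip3)] <- NA_character_
  x
}

#' @rdname pipelineIO
#' @export
writeClaims <- function(x, path) writeCsv(x, path)

#' @rdname pipelineIO
#' @export
readClaims <- function(path) {
  utils::read.csv(path, colClasses = c(
    year = "integer", age_bin = "character", count = "integer"))
}

#' @rdname pipelineIO
#' @export
writeLabs <- function(x, path) writeCsv(x, path)

#' @rdname pipelineIO
#' @export
readLabs <- function(path) {
  utils::read.csv(path, colClasses = c(
    encounter_id = "character", patient_id = "character",
    diagnosis = "character", analyte = "character",
    value = "numeric", timestamp = "character"))
}

#' @rdname pipelineIO
#' @export
writeZip3Centroids <- function(x, path) writeCsv(x, path)

#' @rdname pipelineIO
#' @export
readZip3Centroids <- function(path) {
  utils::read.csv(path, colClasses = c(
    zip3 = "character", lat = "numeric", lon = "numeric"))
}
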