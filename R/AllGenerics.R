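#' Accessors for incidence estimates and encounter containers
#'
#' @param x an [IncidenceEstimate-class] or [LabPanelExperiment-class].
#' @return `meanCases`, `sdCases`, `per100k` return scalars;
#'   `repTotals` the stored replicate totals (possibly length 0);
#'   `maxAmmonia` and `diagnosisGroup` per-encounter vectors;
#'   `clusterLabels` the cluster factor or `NULL` before clustering.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meanCases", function(x) standardGeneric("meanCases"))
#' @rdname accessors
#' @export
setGeneric("sdCases", function(x) standardGeneric("sdCases"))
#' @rdname accessors
#' @export
setGeneric("per100k", function(x) standardGeneric("per100k"))
#' @rdname accessors
#' @export
setGeneric("repTotals", function(x) standardGeneric("repTotals"))
#' @rdname accessors
#' @export
setGeneric("maxAmmonia", function(x) standardGeneric("maxAmmonia"))
#' @rdname accessors
#' @export
setGeneric("diagnosisGroup", function(x) standardGeneric("diagnosisGroup"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
setMethod("meanCases", "IncidenceEstimate", function(x) x@meanCases)
#' @rdname accessors
setMethod("sdCases", "IncidenceEstimate", function(x) x@sdCases)
#' @rdname accessors
setMethod("per100k", "IncidenceEstimate", function(x) x@per100k)
#' @rdname accessors
setMethod("repTotals", "IncidenceEstimate", function(x) x@repTotals)

#' @rdname accessors
setMethod("maxAmmonia", "LabPanelExperiment", function(x) {
  stats::setNames(colData(x)$max_ammonia, colnames(x))
})
#' @rdname accessors
setMethod("diagnosisGroup", "LabPanelExperiment", function(x) {
  stats::setNames(colData(x)$diagnosis, colnames(x))
})
#' @rdname accessors
setMethod("clusterLabels", "LabPanelExperiment", function(x) {
  cl <- colData(x)$cluster
  if (is.null(cl)) NULL else factor(cl)
})
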