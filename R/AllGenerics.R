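#' Accessors for GwasCohort
#'
#' @param x A [GwasCohort-class].
#' @return `dosages()` returns the dosage matrix (SNPs x samples);
#'   `snpInfo()` the per-SNP metadata as a data.frame; `phenotypes()` the
#'   phenotype table as a data.frame.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname cohort-accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname cohort-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname cohort-accessors
#' @export
setMethod("dosages", "GwasCohort", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname cohort-accessors
#' @export
setMethod("snpInfo", "GwasCohort", function(x)
    as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname cohort-accessors
#' @export
setMethod("phenotypes", "GwasCohort", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' Posterior hypothesis probabilities of a colocalization result
#'
#' @param x A [ColocResult-class].
#' @return Named numeric vector `PP0..PP4`.
#' @export
setGeneric("posteriorProb", function(x) standardGeneric("posteriorProb"))

#' @rdname posteriorProb
#' @export
setMethod("posteriorProb", "ColocResult", function(x) x@postProb)
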