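#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Sex-specific cumulative risk-by-age schedule
#'
#' Holds a schedule of cumulative disease risks at increasing ages for one
#' sex, anchored at an index (reference) age, together with the fraction of
#' all cases attributable to the disease subtype under study.  The schedule
#' is the calibration input for the liability threshold model: each printed
#' cumulative risk is treated as the probability of being affected by the
#' corresponding age.
#'
#' @slot sex Character scalar, e.g. \code{"female"} or \code{"male"}.
#' @slot indexAge Reference age in years at which the liability offset is
#'   anchored.
#' @slot ages Numeric vector of ages (years), strictly increasing.
#' @slot risks Numeric vector of cumulative risks in (0, 1), strictly
#'   increasing, one per age.
#' @slot subtypeFraction Fraction of all cases belonging to the analysed
#'   subtype, in (0, 1]; the whole-disease schedule is multiplied by this
#'   value before calibration.
#'
#' @seealso [RiskSchedule()], [defaultRiskSchedule()], [calibrateLiability()]
#' @export
setClass("RiskSchedule",
    representation(
        sex = "character",
        indexAge = "numeric",
        ages = "numeric",
        risks = "numeric",
        subtypeFraction = "numeric"
    )
)

setValidity("RiskSchedule", function(object) {
    msg <- character()
    if (length(object@sex) != 1L || is.na(object@sex) || !nzchar(object@sex))
        msg <- c(msg, "'sex' must be a non-empty character scalar")
    if (length(object@indexAge) != 1L || !is.finite(object@indexAge))
        msg <- c(msg, "'indexAge' must be a finite scalar")
    if (length(object@ages) < 2L)
        msg <- c(msg, "a risk schedule needs at least 2 (age, risk) points")
    if (length(object@ages) != length(object@risks))
        msg <- c(msg, "'ages' and 'risks' must have equal length")
    if (length(object@ages) >= 2L && any(diff(object@ages) <= 0))
        msg <- c(msg, "'ages' must be strictly increasing")
    if (any(!is.finite(object@risks)) || any(object@risks <= 0) ||
        any(object@risks >= 1))
        msg <- c(msg, "'risks' must lie strictly within (0, 1)")
    if (length(object@risks) >= 2L && any(diff(object@risks) <= 0))
        msg <- c(msg, "'risks' must be strictly increasing with age")
    if (length(object@subtypeFraction) != 1L ||
        !is.finite(object@subtypeFraction) ||
        object@subtypeFraction <= 0 || object@subtypeFraction > 1)
        msg <- c(msg, "'subtypeFraction' must lie in (0, 1]")
    if (length(msg) == 0L && length(object@risks) &&
        object@subtypeFraction * max(object@risks) >= 1)
        msg <- c(msg, "scaled risks must stay below 1")
    if (length(msg)) msg else TRUE
})

#' Construct a risk schedule
#'
#' @param sex Sex label (\code{"female"} / \code{"male"}).
#' @param ages Ages in years at which cumulative risks are quoted.
#' @param risks Cumulative risks in (0, 1), strictly increasing.
#' @param indexAge Reference age in years (default 55).
#' @param subtypeFraction Fraction of cases with the analysed subtype,
#'   in (0, 1] (default 1: whole-disease analysis).
#'
#' @return A [RiskSchedule-class] object.
#' @examples
#' RiskSchedule("female", ages = c(65, 75, 85),
#'              risks = c(0.018, 0.054, 0.121), indexAge = 55)
#' @export
RiskSchedule <- function(sex, ages, risks, indexAge = 55,
                         subtypeFraction = 1) {
    new("RiskSchedule", sex = as.character(sex), indexAge = as.numeric(indexAge),
        ages = as.numeric(ages), risks = as.numeric(risks),
        subtypeFraction = as.numeric(subtypeFraction))
}

setMethod("show", "RiskSchedule", function(object) {
    cat("RiskSchedule (", object@sex, ")\n", sep = "")
    cat("  index age: ", object@indexAge, " y; subtype fraction: ",
        object@subtypeFraction, "\n", sep = "")
    cat("  cumulative risk: ",
        paste0(format(100 * object@risks), "% by ", object@ages, "y",
               collapse = ", "), "\n", sep = "")
})

#' Calibrated liability threshold model
#'
#' Per-sex probit-linear mapping from age to the liability threshold.  With
#' slope \eqn{c} (liability units per year), offset \eqn{m} at the reference
#' age \eqn{\bar t}, the threshold is \eqn{\tau(t) = -c (t - \bar t) - m} and
#' the implied prevalence is \eqn{P(case | t) = 1 - \Phi(\tau(t))}.  The
#' offset is parameterised so that \eqn{P(case | \bar t) = \Phi(m)}; for a
#' rare disease \eqn{m} is negative and \eqn{\tau} large and positive.
#'
#' @slot slope Named numeric: liability units per year of age, per sex.
#' @slot offset Named numeric: liability offset at the reference age, per sex.
#' @slot referenceAge Reference age in years (shared across sexes).
#' @slot fit List of per-sex calibration diagnostics (ages, scaled risks,
#'   probit values, fitted values, residuals).
#'
#' @seealso [calibrateLiability()], [liabilityThreshold()],
#'   [posteriorMeanLiability()]
#' @export
setClass("LiabilityModel",
    representation(
        slope = "numeric",
        offset = "numeric",
        referenceAge = "numeric",
        fit = "list"
    )
)

setValidity("LiabilityModel", function(object) {
    msg <- character()
    if (length(object@slope) < 1L || is.null(names(object@slope)))
        msg <- c(msg, "'slope' must be a named numeric vector (one per sex)")
    if (!identical(names(object@slope), names(object@offset)))
        msg <- c(msg, "'slope' and 'offset' must share sex names")
    if (any(!is.finite(object@slope)) || any(!is.finite(object@offset)))
        msg <- c(msg, "slopes and offsets must be finite")
    if (length(object@referenceAge) != 1L || !is.finite(object@referenceAge))
        msg <- c(msg, "'referenceAge' must be a finite scalar")
    if (length(msg)) msg else TRUE
})

setMethod("show", "LiabilityModel", function(object) {
    cat("LiabilityModel (reference age ", object@referenceAge, " y)\n",
        sep = "")
    for (s in names(object@slope)) {
        tau0 <- -object@offset[[s]]
        cat(sprintf("  %-7s c = %.5f /y, m = %.4f, tau(%g) = %.4f, P(case|%g) = %.4g\n",
                    s, object@slope[[s]], object@offset[[s]],
                    object@referenceAge, tau0, object@referenceAge,
                    pnorm(object@offset[[s]])))
    }
})

#' Case/control cohort with genotype dosages
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one study cohort:
#' a dosage assay (SNPs in rows, samples in columns, values in [0, 2]),
#' per-SNP metadata in \code{rowData} (\code{SNP}, \code{CHR}, \code{BP},
#' \code{EA}, \code{OA}, \code{EAF}, \code{INFO}) and the phenotype table in
#' \code{colData} (\code{status} in \{0, 1\}, \code{age}, optional
#' \code{sex}, \code{PC1..PCk}).
#'
#' @seealso [GwasCohort()], [dosages()], [snpInfo()], [phenotypes()],
#'   [snpFilter()], [scanAssociation()]
#' @export
setClass("GwasCohort", contains = "SummarizedExperiment")

.required_snp_cols <- c("SNP", "CHR", "BP", "EA", "OA", "EAF", "INFO")

setValidity("GwasCohort", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "dosages must lie within [0, 2]")
    }
    rd <- SummarizedExperiment::rowData(object)
    miss <- setdiff(.required_snp_cols, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("SNP" %in% colnames(rd) && anyDuplicated(rd$SNP))
        msg <- c(msg, "duplicate SNP IDs within a cohort")
    cd <- SummarizedExperiment::colData(object)
    missp <- setdiff(c("status", "age"), colnames(cd))
    if (length(missp))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(missp, collapse = ", ")))
    if ("status" %in% colnames(cd) &&
        !all(cd$status %in% c(0L, 1L) | is.na(cd$status)))
        msg <- c(msg, "status must be 0/1 (NA allowed)")
    if (length(msg)) msg else TRUE
})

#' Construct a GwasCohort
#'
#' @param dosage Numeric matrix of expected allele counts, SNPs in rows and
#'   samples in columns (values in [0, 2]).
#' @param snpInfo data.frame with one row per SNP: columns \code{SNP},
#'   \code{CHR}, \code{BP} (1-based), \code{EA}, \code{OA}, \code{EAF},
#'   \code{INFO}.
#' @param phenotypes data.frame with one row per sample: \code{sample_id},
#'   \code{status} (0 control / 1 case), \code{age}; optional \code{sex} and
#'   principal-component columns \code{PC1..PCk}.
#' @param metadata Optional list stored as experiment metadata (e.g.
#'   simulation truth).
#'
#' @return A [GwasCohort-class].
#' @export
GwasCohort <- function(dosage, snpInfo, phenotypes, metadata = list()) {
    dosage <- as.matrix(dosage)
    snpInfo <- as.data.frame(snpInfo)
    phenotypes <- as.data.frame(phenotypes)
    if (nrow(snpInfo) != nrow(dosage))
        stop("one snpInfo row is required per dosage row (SNP)")
    if (nrow(phenotypes) != ncol(dosage))
        stop("one phenotype row is required per dosage column (sample)")
    rownames(dosage) <- snpInfo$SNP
    if ("sample_id" %in% colnames(phenotypes)) {
        colnames(dosage) <- phenotypes$sample_id
        rownames(phenotypes) <- phenotypes$sample_id
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = S4Vectors::DataFrame(snpInfo),
        colData = S4Vectors::DataFrame(phenotypes),
        metadata = metadata)
    new("GwasCohort", se)
}

setMethod("show", "GwasCohort", function(object) {
    cd <- SummarizedExperiment::colData(object)
    ncase <- sum(cd$status == 1, na.rm = TRUE)
    nctrl <- sum(cd$status == 0, na.rm = TRUE)
    cat("GwasCohort: ", nrow(object), " SNPs x ", ncol(object),
        " samples (", ncase, " cases / ", nctrl, " controls)\n", sep = "")
    if ("age" %in% colnames(cd)) {
        cat(sprintf("  mean age: cases %.1f, controls %.1f\n",
                    mean(cd$age[cd$status == 1], na.rm = TRUE),
                    mean(cd$age[cd$status == 0], na.rm = TRUE)))
    }
    pcs <- grep("^PC[0-9]+$", colnames(cd), value = TRUE)
    if (length(pcs)) cat("  covariates: ", length(pcs), " PCs\n", sep = "")
})

#' Colocalization result
#'
#' Posterior probabilities over the five colocalization hypotheses for one
#' region: H0 no association with either trait, H1 association with trait 1
#' only, H2 trait 2 only, H3 both traits via two distinct SNPs, H4 both
#' traits via one shared SNP.
#'
#' @slot nsnps Number of SNPs used after intersection/windowing.
#' @slot postProb Named numeric of length 5 (\code{PP0..PP4}), summing to 1.
#' @slot priors Named numeric: per-SNP priors \code{p1}, \code{p2},
#'   \code{p12}.
#' @slot summary data.frame of per-SNP log approximate Bayes factors for
#'   each trait.
#'
#' @seealso [colocPosterior()]
#' @export
setClass("ColocResult",
    representation(
        nsnps = "integer",
        postProb = "numeric",
        priors = "numeric",
        summary = "data.frame"
    )
)

setValidity("ColocResult", function(object) {
    msg <- character()
    if (length(object@postProb) != 5L ||
        !identical(names(object@postProb), paste0("PP", 0:4)))
        msg <- c(msg, "'postProb' must be named PP0..PP4")
    else {
        if (any(object@postProb < -1e-12))
            msg <- c(msg, "posterior probabilities must be non-negative")
        if (abs(sum(object@postProb) - 1) > 1e-12)
            msg <- c(msg, "posterior probabilities must sum to 1")
    }
    if (!all(c("p1", "p2", "p12") %in% names(object@priors)))
        msg <- c(msg, "'priors' must contain p1, p2, p12")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ColocResult", function(object) {
    cat("ColocResult over", object@nsnps, "SNPs\n")
    cat(sprintf("  priors: p1 = %g, p2 = %g, p12 = %g\n",
                object@priors[["p1"]], object@priors[["p2"]],
                object@priors[["p12"]]))
    pp <- object@postProb
    for (i in seq_along(pp))
        cat(sprintf("  %s = %.4f\n", names(pp)[i], pp[i]))
    best <- names(pp)[which.max(pp)]
    cat("  best supported: ", sub("PP", "H", best), "\n", sep = "")
})
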