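#' Per-study sample counts of the three-stage stroke GWAS design
#'
#' The shipped table lists, for each contributing study, its stage and its
#' case counts for all ischemic stroke (IS) and the cardioembolic (CE),
#' large-artery (LAS) and small-vessel (SVS) subtypes, plus controls.
#' Missing phenotype contributions are \code{NA}.
#'
#' @param path Optional alternative counts TSV (same columns).
#' @return data.frame with columns \code{population}, \code{stage},
#'   \code{IS}, \code{CE}, \code{LAS}, \code{SVS}, \code{controls}.
#' @export
studyCounts <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "study_counts.tsv",
                            package = "liabilityGWAS", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
}

#' Reconcile staged sample counts
#'
#' Sums per-study counts within each stage and overall, the bookkeeping
#' used to report discovery and combined sample sizes of a staged design.
#'
#' @param counts data.frame from [studyCounts()].
#' @return data.frame with one row per stage plus a \code{total} row;
#'   columns \code{IS}, \code{CE}, \code{LAS}, \code{SVS},
#'   \code{controls}.
#' @examples
#' reconcileStageCounts(studyCounts())
#' @export
reconcileStageCounts <- function(counts) {
    num <- c("IS", "CE", "LAS", "SVS", "controls")
    miss <- setdiff(c("stage", num), colnames(counts))
    if (length(miss))
        stop("counts table lacks column(s): ", paste(miss, collapse = ", "))
    stages <- unique(counts$stage)
    rows <- lapply(stages, function(s) {
        d <- counts[counts$stage == s, num, drop = FALSE]
        cbind(data.frame(stage = s), as.data.frame(t(colSums(d, na.rm = TRUE))))
    })
    tot <- cbind(data.frame(stage = "total"),
                 as.data.frame(t(colSums(counts[, num], na.rm = TRUE))))
    out <- rbind(do.call(rbind, rows), tot)
    rownames(out) <- NULL
    out
}
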