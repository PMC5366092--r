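#' Read genotype dosages from VCF or TSV
#'
#' VCF input (via the VariantAnnotation package) prefers the per-sample
#' \code{DS} (dosage) FORMAT field and falls back to hard-calling
#' \code{GT} as 0/1/2; multiallelic records are skipped with a warning.
#' TSV input expects a dosage matrix file (first column \code{SNP}, one
#' column per sample) plus a metadata file with columns \code{SNP},
#' \code{CHR}, \code{BP}, \code{EA}, \code{OA}, \code{EAF}, \code{INFO}.
#' Positions are 1-based.
#'
#' @param path VCF (\code{.vcf}) or dosage-matrix TSV path.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"tsv"}.
#' @param metadataPath SNP metadata TSV (TSV format only).
#'
#' @return List with \code{dosage} (SNPs x samples matrix) and
#'   \code{snpInfo} (data.frame).
#' @export
readDosages <- function(path, format = c("auto", "vcf", "tsv"),
                        metadataPath = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "vcf") .readDosagesVcf(path) else
        .readDosagesTsv(path, metadataPath)
}

.readDosagesVcf <- function(path) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("reading VCF requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    alt <- VariantAnnotation::alt(vcf)
    multi <- S4Vectors::elementNROWS(alt) > 1L
    if (any(multi)) {
        warning("skipping ", sum(multi), " multiallelic record(s)")
        vcf <- vcf[!multi, ]
        alt <- alt[!multi]
    }
    gen <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(gen)) {
        d <- gen$DS
        mode(d) <- "numeric"
    } else if ("GT" %in% names(gen)) {
        gt <- gen$GT
        d <- apply(gt, c(1, 2), function(x) {
            if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
            sum(as.integer(strsplit(x, "[/|]")[[1]]))
        })
    } else stop("VCF carries neither DS nor GT genotype fields")
    rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
    fixed <- VariantAnnotation::info(vcf)
    info <- if ("INFO" %in% colnames(fixed)) as.numeric(fixed$INFO)
            else rep(1, nrow(d))
    snp <- data.frame(
        SNP = rownames(d),
        CHR = as.character(rr$seqnames),
        BP = rr$start,
        EA = as.character(unlist(alt)),
        OA = as.character(VariantAnnotation::ref(vcf)),
        EAF = colMeans(t(d), na.rm = TRUE) / 2,
        INFO = info,
        stringsAsFactors = FALSE)
    list(dosage = d, snpInfo = snp)
}

.readDosagesTsv <- function(path, metadataPath) {
    if (is.null(metadataPath))
        stop("TSV dosages need a 'metadataPath' SNP metadata file")
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = ".")
    if (colnames(d)[1] != "SNP")
        stop("malformed dosage TSV header (line 1): first column must be 'SNP'")
    mat <- as.matrix(d[, -1, drop = FALSE])
    rownames(mat) <- d$SNP
    meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE,
                              na.strings = ".")
    miss <- setdiff(.required_snp_cols, colnames(meta))
    if (length(miss))
        stop("metadata TSV lacks column(s): ", paste(miss, collapse = ", "))
    if (!identical(sort(meta$SNP), sort(rownames(mat))))
        stop("SNP sets differ between dosage and metadata files")
    meta <- meta[match(rownames(mat), meta$SNP), , drop = FALSE]
    list(dosage = mat, snpInfo = meta)
}

#' Read a phenotype table
#'
#' Tab-separated with header; required columns \code{sample_id},
#' \code{status} (0/1), \code{age}; optional \code{sex} and
#' principal-component columns \code{PC1..PCk} (auto-detected by prefix).
#' Missing values are coded \code{.} or empty.
#'
#' @param path Phenotype TSV path.
#' @return data.frame; the number of missing ages (candidates for
#'   [imputeMissingAge()]) is in \code{attr(x, "nMissingAge")} and the
#'   detected PC count in \code{attr(x, "nPCs")}.
#' @export
readPhenotypes <- function(path) {
    ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c(".", "", "NA"))
    need <- c("sample_id", "status", "age")
    miss <- setdiff(need, colnames(ph))
    if (length(miss))
        stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(ph$sample_id))
        stop("duplicate sample IDs: ",
             paste(unique(ph$sample_id[duplicated(ph$sample_id)]),
                   collapse = ", "))
    st <- suppressWarnings(as.numeric(ph$status))
    if (any(!is.na(st) & !st %in% c(0, 1)) || any(is.na(st) & !is.na(ph$status)))
        stop("status values outside {0, 1, NA}")
    ph$status <- as.integer(st)
    ph$age <- suppressWarnings(as.numeric(ph$age))
    attr(ph, "nMissingAge") <- sum(is.na(ph$age))
    attr(ph, "nPCs") <- length(pcColumns(ph))
    ph
}

#' Assemble a cohort from dosage and phenotype inputs
#'
#' Samples are aligned by ID (order-independent); an error lists samples
#' present on only one side.
#'
#' @param dosagePart List from [readDosages()].
#' @param pheno data.frame from [readPhenotypes()].
#' @return A [GwasCohort-class].
#' @export
assembleCohort <- function(dosagePart, pheno) {
    dn <- colnames(dosagePart$dosage)
    onlyD <- setdiff(dn, pheno$sample_id)
    onlyP <- setdiff(pheno$sample_id, dn)
    if (length(onlyD) || length(onlyP))
        stop("sample mismatch between dosage and phenotype files; ",
             "dosage-only: [", paste(onlyD, collapse = ", "),
             "], phenotype-only: [", paste(onlyP, collapse = ", "), "]")
    d <- dosagePart$dosage[, pheno$sample_id, drop = FALSE]
    GwasCohort(d, dosagePart$snpInfo, pheno)
}

.statsCols <- c("SNP", "CHR", "BP", "EA", "OA", "EAF", "INFO", "N", "Z",
                "CHISQ", "P", "BETA", "SE", "ANALYSIS")

#' Write / read summary statistics TSV
#'
#' Lossless round trip of association records: canonical column order,
#' tab-separated, \code{.} for missing, numeric fields (including
#' p-values down to the smallest representable doubles) written with 15
#' significant digits.  Unknown extra columns are preserved (with a
#' warning on read).
#'
#' @param stats Association records data.frame.
#' @param path Output / input path.
#' @return `readSummaryStats()` returns the data.frame.
#' @export
writeSummaryStats <- function(stats, path) {
    cols <- c(intersect(.statsCols, colnames(stats)),
              setdiff(colnames(stats), .statsCols))
    out <- stats[, cols, drop = FALSE]
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], function(x) {
        y <- sprintf("%.15g", x)
        y[!is.finite(x)] <- "."
        y
    })
    out[!num] <- lapply(out[!num], function(x) ifelse(is.na(x), ".", x))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
    invisible(path)
}

#' @rdname writeSummaryStats
#' @export
readSummaryStats <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = ".", check.names = FALSE)
    extra <- setdiff(colnames(tab),
                     c(.statsCols, "NCAS", "NCON", "R2", "DIRECTION", "k"))
    if (length(extra))
        warning("unknown column(s) preserved: ",
                paste(extra, collapse = ", "))
    for (cc in intersect(c("BP", "N"), colnames(tab)))
        tab[[cc]] <- as.integer(tab[[cc]])
    for (cc in intersect(c("EAF", "INFO", "Z", "CHISQ", "P", "BETA", "SE"),
                         colnames(tab)))
        tab[[cc]] <- as.numeric(tab[[cc]])
    tab
}

#' Write METAL-style meta-analysis output
#'
#' Columns \code{MarkerName}, \code{Allele1}, \code{Allele2},
#' \code{Weight}, \code{Zscore}, \code{P-value}, \code{Direction}.
#'
#' @param meta Meta-analysis data.frame from [stoufferMeta()].
#' @param path Output path.
#' @param alleles Optional data.frame (\code{SNP}, \code{EA}, \code{OA})
#'   supplying the harmonized alleles.
#' @export
writeMetal <- function(meta, path, alleles = NULL) {
    a1 <- a2 <- rep(NA_character_, nrow(meta))
    if (!is.null(alleles)) {
        i <- match(meta$SNP, alleles$SNP)
        a1 <- tolower(alleles$EA[i]); a2 <- tolower(alleles$OA[i])
    }
    out <- data.frame(MarkerName = meta$SNP, Allele1 = a1, Allele2 = a2,
                      Weight = meta$N, Zscore = sprintf("%.3f", meta$Z),
                      `P-value` = sprintf("%.4g", meta$P),
                      Direction = meta$DIRECTION, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
    invisible(path)
}
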