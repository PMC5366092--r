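#' Filter SNPs on imputation quality and minor allele frequency
#'
#' Retains SNPs with imputation info score >= \code{minInfo} and minor
#' allele frequency >= \code{minMaf} (both inclusive); the conventional
#' GWAS defaults exclude SNPs with info < 0.7 or MAF < 0.01.
#'
#' @param cohort A [GwasCohort-class].
#' @param minInfo Minimum info score in [0, 1].
#' @param minMaf Minimum minor allele frequency in [0, 0.5].
#'
#' @return The filtered cohort; the exclusion report (data.frame with
#'   columns \code{SNP}, \code{INFO}, \code{MAF}, \code{reason}) is stored
#'   in \code{metadata(cohort)$exclusions} and retrievable with
#'   [exclusionReport()].
#' @export
snpFilter <- function(cohort, minInfo = 0.7, minMaf = 0.01) {
    stopifnot(is(cohort, "GwasCohort"))
    if (minInfo < 0 || minInfo > 1 || minMaf < 0 || minMaf > 1)
        stop("filter thresholds must lie in [0, 1]")
    info <- snpInfo(cohort)
    maf <- pmin(info$EAF, 1 - info$EAF)
    lowInfo <- info$INFO < minInfo
    lowMaf <- maf < minMaf
    keep <- !(lowInfo | lowMaf)
    reason <- character(nrow(info))
    reason[lowInfo] <- sprintf("info %.3f < %.3f", info$INFO[lowInfo], minInfo)
    reason[lowMaf & !lowInfo] <-
        sprintf("MAF %.4f < %.4f", maf[lowMaf & !lowInfo], minMaf)
    reason[lowMaf & lowInfo] <- paste0(reason[lowMaf & lowInfo],
        sprintf("; MAF %.4f < %.4f", maf[lowMaf & lowInfo], minMaf))
    report <- data.frame(SNP = info$SNP[!keep], INFO = info$INFO[!keep],
                         MAF = maf[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
    out <- cohort[keep, ]
    if (!any(keep)) warning("all SNPs excluded by the filter")
    S4Vectors::metadata(out)$exclusions <- report
    out
}

#' Exclusion report of the last [snpFilter()] call
#'
#' @param cohort A filtered [GwasCohort-class].
#' @return data.frame of excluded SNPs with reasons (empty if none).
#' @export
exclusionReport <- function(cohort) {
    rep <- S4Vectors::metadata(cohort)$exclusions
    if (is.null(rep)) rep <- data.frame(SNP = character(), INFO = numeric(),
                                        MAF = numeric(), reason = character())
    rep
}

#' Residualize values on covariates (EIGENSTRAT-style adjustment)
#'
#' Ordinary least-squares residuals of \code{values} on an intercept plus
#' the covariate columns; with no covariates this is mean-centering.  The
#' residuals are orthogonal to every covariate column.
#'
#' @param values Numeric vector, or matrix with one series per column.
#' @param covariates Optional numeric matrix (samples x covariates).
#'
#' @return Residuals with the same shape as \code{values}.
#' @export
residualize <- function(values, covariates = NULL) {
    v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
    n <- nrow(v)
    X <- cbind(`(Intercept)` = rep(1, n), covariates)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
        if (is.null(dropped)) dropped <- "<unnamed>"
        stop("covariate matrix is rank deficient; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    res <- qr.resid(qrX, v)
    if (is.matrix(values)) res else drop(res)
}

.assocRecord <- function(snp = NA_character_, chr = NA_character_,
                         bp = NA_integer_, ea = NA_character_,
                         oa = NA_character_, eaf = NA_real_,
                         info = NA_real_, n, z, chisq, p,
                         beta = NA_real_, se = NA_real_, analysis) {
    data.frame(SNP = snp, CHR = as.character(chr), BP = as.integer(bp),
               EA = ea, OA = oa, EAF = eaf, INFO = info, N = as.integer(n),
               Z = z, CHISQ = chisq, P = p, BETA = beta, SE = se,
               ANALYSIS = analysis, stringsAsFactors = FALSE)
}

.snpMeta <- function(snp) {
    defaults <- list(snp = NA_character_, chr = NA_character_,
                     bp = NA_integer_, ea = NA_character_,
                     oa = NA_character_, eaf = NA_real_, info = NA_real_)
    if (is.null(snp)) return(defaults)
    for (nm in intersect(names(snp), names(defaults)))
        defaults[[nm]] <- snp[[nm]]
    defaults
}

#' Liability score test for one SNP
#'
#' The covariate-informed association statistic: dosage and posterior mean
#' liability are each residualized on the covariates, and the test
#' statistic is \eqn{\chi^2 = N r^2} with \eqn{r} their Pearson
#' correlation, referred to the 1-df chi-square distribution.  The signed
#' score is \eqn{Z = sign(r) \sqrt{\chi^2}}, oriented to the counted
#' (effect) allele.
#'
#' @param dosage Numeric vector of effect-allele dosages in [0, 2].
#' @param posterior Posterior mean liabilities (see
#'   [posteriorMeanLiability()]).
#' @param covariates Optional covariate matrix (e.g. ancestry PCs).
#' @param snp Optional named list of SNP metadata (\code{snp}, \code{chr},
#'   \code{bp}, \code{ea}, \code{oa}, \code{eaf}, \code{info}) copied into
#'   the record.
#'
#' @return One-row association record (data.frame).  A dosage that is
#'   constant after residualization yields an untestable record with
#'   missing Z/chi-square/p rather than an error.
#' @examples
#' liabilityScoreTest(c(0, 1, 2, 1), c(-1, 0, 1, 0))
#' @export
liabilityScoreTest <- function(dosage, posterior, covariates = NULL,
                               snp = NULL) {
    meta <- .snpMeta(snp)
    keep <- complete.cases(dosage, posterior,
                           if (is.null(covariates)) rep(0, length(dosage))
                           else covariates)
    n <- sum(keep)
    if (n < 10L)
        warning("fewer than 10 complete samples in liabilityScoreTest()")
    d <- dosage[keep]
    y <- posterior[keep]
    C <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
    dres <- residualize(d, C)
    yres <- residualize(y, C)
    if (sd(dres) < 1e-12 || sd(yres) < 1e-12) {
        return(.assocRecord(meta$snp, meta$chr, meta$bp, meta$ea, meta$oa,
                            meta$eaf, meta$info, n = n, z = NA_real_,
                            chisq = NA_real_, p = NA_real_,
                            analysis = "liability"))
    }
    r <- sum(dres * yres) / sqrt(sum(dres^2) * sum(yres^2))
    chisq <- n * r^2
    z <- sign(r) * sqrt(chisq)
    .assocRecord(meta$snp, meta$chr, meta$bp, meta$ea, meta$oa, meta$eaf,
                 meta$info, n = n, z = z, chisq = chisq, p = chisqP(chisq),
                 analysis = "liability")
}

#' Logistic regression association for one SNP
#'
#' Maximum-likelihood logistic regression of case/control status on dosage
#' plus an intercept and covariates (the conventional GWAS analysis),
#' with Wald statistics from the observed information.
#'
#' @inheritParams liabilityScoreTest
#' @param status 0/1 vector.
#'
#' @return One-row association record with log-odds \code{BETA} and
#'   \code{SE}.  Perfect separation yields a flagged record with missing
#'   SE.
#' @export
logisticAssoc <- function(dosage, status, covariates = NULL, snp = NULL) {
    meta <- .snpMeta(snp)
    keep <- complete.cases(dosage, status,
                           if (is.null(covariates)) rep(0, length(dosage))
                           else covariates)
    n <- sum(keep)
    if (n < 10L)
        warning("fewer than 10 complete samples in logisticAssoc()")
    d <- dosage[keep]
    s <- status[keep]
    if (length(unique(s)) < 2L)
        stop("both cases and controls are required")
    C <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
    df <- data.frame(status = s, dosage = d)
    form <- status ~ dosage
    if (!is.null(C)) {
        colnames(C) <- paste0("C", seq_len(ncol(C)))
        df <- cbind(df, C)
        form <- reformulate(c("dosage", colnames(C)), response = "status")
    }
    sep <- FALSE
    fit <- withCallingHandlers(
        glm(form, family = binomial(), data = df,
            control = list(epsilon = 1e-10, maxit = 100L)),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    beta <- unname(coef(fit)["dosage"])
    se <- sqrt(diag(vcov(fit)))[["dosage"]]
    if (sep || !is.finite(se) || se > 1e3) {
        return(.assocRecord(meta$snp, meta$chr, meta$bp, meta$ea, meta$oa,
                            meta$eaf, meta$info, n = n, z = NA_real_,
                            chisq = NA_real_, p = NA_real_, beta = beta,
                            se = NA_real_, analysis = "logistic"))
    }
    z <- beta / se
    .assocRecord(meta$snp, meta$chr, meta$bp, meta$ea, meta$oa, meta$eaf,
                 meta$info, n = n, z = z, chisq = z^2, p = chisqP(z^2),
                 beta = beta, se = se, analysis = "logistic")
}

#' Additive linear regression of a quantitative trait on dosage
#'
#' cis-QTL style test: OLS slope of the molecular trait (e.g. methylation
#' or expression level) on effect-allele dosage with covariates; reports
#' the t-based two-sided p and the fraction of (covariate-adjusted) trait
#' variance explained by genotype (\code{R2}).
#'
#' @inheritParams liabilityScoreTest
#' @param trait Numeric trait vector.
#'
#' @return One-row association record with extra column \code{R2}.
#' @export
linearQtlAssoc <- function(trait, dosage, covariates = NULL, snp = NULL) {
    meta <- .snpMeta(snp)
    keep <- complete.cases(trait, dosage,
                           if (is.null(covariates)) rep(0, length(dosage))
                           else covariates)
    n <- sum(keep)
    if (n < 10L)
        warning("fewer than 10 complete samples in linearQtlAssoc()")
    y <- trait[keep]
    d <- dosage[keep]
    C <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
    rec <- function(z, chisq, p, beta, se, r2) {
        out <- .assocRecord(meta$snp, meta$chr, meta$bp, meta$ea, meta$oa,
                            meta$eaf, meta$info, n = n, z = z, chisq = chisq,
                            p = p, beta = beta, se = se, analysis = "linear")
        out$R2 <- r2
        out
    }
    if (sd(y) < 1e-12 || sd(residualize(d, C)) < 1e-12)
        return(rec(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                   NA_real_))
    df <- data.frame(y = y, dosage = d)
    form <- y ~ dosage
    if (!is.null(C)) {
        colnames(C) <- paste0("C", seq_len(ncol(C)))
        df <- cbind(df, C)
        form <- reformulate(c("dosage", colnames(C)), response = "y")
    }
    fit <- lm(form, data = df)
    sm <- summary(fit)$coefficients
    beta <- sm["dosage", "Estimate"]
    se <- sm["dosage", "Std. Error"]
    tstat <- sm["dosage", "t value"]
    p <- sm["dosage", "Pr(>|t|)"]
    r2 <- cor(residualize(y, C), residualize(d, C))^2
    rec(tstat, tstat^2, p, beta, se, r2)
}

#' Genome-wide association scan of a cohort
#'
#' Runs the chosen per-SNP analysis over every SNP of a cohort, using the
#' cohort's ancestry PCs (columns \code{PC1..PCk} of the phenotype table)
#' as covariates, and returns a METAL-consumable summary-statistics
#' data.frame.  For \code{analysis = "liability"} the cohort must carry a
#' \code{posterior} phenotype column (see [addPosteriorLiability()]); for
#' \code{"linear"} a numeric \code{trait} vector is required.
#'
#' @param cohort A [GwasCohort-class].
#' @param analysis One of \code{"liability"}, \code{"logistic"},
#'   \code{"linear"}.
#' @param trait Trait vector for \code{analysis = "linear"}.
#'
#' @return data.frame with columns \code{SNP, CHR, BP, EA, OA, EAF, INFO,
#'   N, Z, CHISQ, P, BETA, SE, ANALYSIS} (plus \code{R2} for linear),
#'   one row per SNP in cohort order.
#' @export
scanAssociation <- function(cohort,
                            analysis = c("liability", "logistic", "linear"),
                            trait = NULL) {
    analysis <- match.arg(analysis)
    stopifnot(is(cohort, "GwasCohort"))
    ph <- phenotypes(cohort)
    C <- pcMatrix(ph)
    info <- snpInfo(cohort)
    D <- t(dosages(cohort))                     # samples x SNPs
    metaFor <- function(j) list(snp = info$SNP[j], chr = info$CHR[j],
                                bp = info$BP[j], ea = info$EA[j],
                                oa = info$OA[j], eaf = info$EAF[j],
                                info = info$INFO[j])
    if (analysis == "liability") {
        if (!"posterior" %in% colnames(ph))
            stop("no 'posterior' phenotype column; run addPosteriorLiability() first")
        y <- ph$posterior
        if (!anyNA(D) && !anyNA(y) && (is.null(C) || !anyNA(C))) {
            # fast path: one joint residualization, vectorised correlations
            n <- nrow(D)
            yres <- residualize(y, C)
            Dres <- residualize(D, C)
            ssd <- colSums(Dres^2)
            ssy <- sum(yres^2)
            testable <- ssd > 1e-12 * n & ssy > 1e-12 * n
            r <- rep(NA_real_, ncol(D))
            r[testable] <- as.vector(crossprod(Dres[, testable, drop = FALSE],
                                               yres)) /
                sqrt(ssd[testable] * ssy)
            chisq <- n * r^2
            z <- sign(r) * sqrt(chisq)
            out <- .assocRecord(info$SNP, info$CHR, info$BP, info$EA,
                                info$OA, info$EAF, info$INFO, n = n, z = z,
                                chisq = chisq, p = chisqP(chisq),
                                analysis = "liability")
            return(out)
        }
        rows <- lapply(seq_len(ncol(D)), function(j)
            liabilityScoreTest(D[, j], y, C, snp = metaFor(j)))
    } else if (analysis == "logistic") {
        rows <- lapply(seq_len(ncol(D)), function(j)
            logisticAssoc(D[, j], ph$status, C, snp = metaFor(j)))
    } else {
        if (is.null(trait)) stop("'trait' is required for a linear scan")
        rows <- lapply(seq_len(ncol(D)), function(j)
            linearQtlAssoc(trait, D[, j], C, snp = metaFor(j)))
    }
    do.call(rbind, rows)
}

#' Genomic control
#'
#' The inflation factor \eqn{\lambda} is the median observed 1-df
#' chi-square divided by its null median (0.4549364).  When
#' \eqn{\lambda > 1} every chi-square is divided by \eqn{\lambda} and Z and
#' p are recomputed; statistics are never inflated
#' (\eqn{\lambda \le 1} leaves records untouched).
#'
#' @param records Association records (data.frame with \code{CHISQ},
#'   \code{Z}, \code{P}).
#'
#' @return List with \code{records} (possibly adjusted) and \code{lambda}.
#' @export
genomicControl <- function(records) {
    testable <- is.finite(records$CHISQ)
    if (!any(testable)) stop("no testable records for genomic control")
    if (sum(testable) < 100L)
        warning("fewer than 100 testable records; lambda estimate is noisy")
    lambda <- median(records$CHISQ[testable]) / qchisq(0.5, df = 1L)
    if (lambda > 1) {
        records$CHISQ[testable] <- records$CHISQ[testable] / lambda
        records$Z[testable] <- sign(records$Z[testable]) *
            sqrt(records$CHISQ[testable])
        records$P[testable] <- chisqP(records$CHISQ[testable])
    }
    list(records = records, lambda = lambda)
}

#' Rescale an inflation factor to 1,000 cases and 1,000 controls
#'
#' \eqn{\lambda_{1000} = 1 + (\lambda - 1) \cdot 500 \cdot (1/n_{cases} +
#' 1/n_{controls})}: the inflation the same confounding would produce in a
#' study of 1,000 cases and 1,000 controls.
#'
#' @param lambda Observed inflation factor (>= 0).
#' @param nCases,nControls Sample counts (> 0).
#'
#' @return The rescaled inflation factor (unrounded).
#' @examples
#' lambda1000(1.05, 10210, 12285)  # ~1.00
#' @export
lambda1000 <- function(lambda, nCases, nControls) {
    if (lambda < 0) stop("'lambda' must be non-negative")
    if (nCases <= 0 || nControls <= 0)
        stop("case and control counts must be positive")
    1 + (lambda - 1) * 500 * (1 / nCases + 1 / nControls)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level \code{q}; also reports the largest raw p
#' passing, i.e. the "equivalent p threshold" for the achieved FDR.
#'
#' @param pvalues Raw p-values in (0, 1].
#' @param q Target FDR in (0, 1).
#'
#' @return List with \code{reject} (logical, input order),
#'   \code{threshold} (largest rejected p, \code{NA} if none) and
#'   \code{nRejected}.
#' @examples
#' bhFdr(c(0.001, 0.02, 0.04, 0.9), q = 0.05)
#' @export
bhFdr <- function(pvalues, q = 0.05) {
    if (!length(pvalues)) stop("empty p-value vector")
    if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1))
        stop("p-values must lie in (0, 1]")
    if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
    reject <- p.adjust(pvalues, method = "BH") <= q
    list(reject = reject,
         threshold = if (any(reject)) max(pvalues[reject]) else NA_real_,
         nRejected = sum(reject))
}

#' Age-at-onset quartile analysis of one SNP
#'
#' Within each cohort, cases are split into quartiles of age-at-onset
#' (type-7 sample quantiles, boundary ties to the lower quartile); each
#' quartile's cases are tested against all of the cohort's controls by
#' logistic regression (with the cohort's PCs); per-quartile estimates are
#' pooled across cohorts by fixed-effects inverse-variance meta-analysis.
#'
#' @param cohorts List of [GwasCohort-class] objects.
#' @param snp SNP ID to analyse.
#'
#' @return data.frame with one row per quartile: \code{quartile},
#'   \code{nCohorts}, \code{beta}, \code{se}, \code{OR}, \code{lo},
#'   \code{hi} (95\% CI) and \code{p}.  Cohorts without case ages (or with
#'   fewer than 4 aged cases, or lacking the SNP) are skipped with a
#'   message.
#' @export
quartileAnalysis <- function(cohorts, snp) {
    if (is(cohorts, "GwasCohort")) cohorts <- list(cohorts)
    perQuartile <- vector("list", 4L)
    for (ci in seq_along(cohorts)) {
        co <- cohorts[[ci]]
        ph <- phenotypes(co)
        ids <- snpInfo(co)$SNP
        if (!snp %in% ids) {
            message("cohort ", ci, " lacks SNP ", snp, "; skipped")
            next
        }
        caseAge <- ph$age[ph$status == 1]
        if (sum(!is.na(caseAge)) < 4L) {
            message("cohort ", ci, " has no usable case ages; skipped")
            next
        }
        d <- dosages(co)[match(snp, ids), ]
        C <- pcMatrix(ph)
        br <- quantile(caseAge, probs = c(0.25, 0.5, 0.75), type = 7,
                       na.rm = TRUE)
        qidx <- 1L + (ph$age > br[1]) + (ph$age > br[2]) + (ph$age > br[3])
        for (k in 1:4) {
            use <- ph$status == 0 | (ph$status == 1 & qidx == k &
                                     !is.na(ph$age))
            rec <- logisticAssoc(d[use], ph$status[use],
                                 if (is.null(C)) NULL
                                 else C[use, , drop = FALSE])
            if (is.finite(rec$SE))
                perQuartile[[k]] <- rbind(perQuartile[[k]],
                    data.frame(cohort = ci, beta = rec$BETA, se = rec$SE))
        }
    }
    out <- do.call(rbind, lapply(1:4, function(k) {
        contrib <- perQuartile[[k]]
        if (is.null(contrib) || !nrow(contrib))
            return(data.frame(quartile = k, nCohorts = 0L, beta = NA_real_,
                              se = NA_real_, OR = NA_real_, lo = NA_real_,
                              hi = NA_real_, p = NA_real_))
        m <- ivwMeta(contrib$beta, contrib$se)
        data.frame(quartile = k, nCohorts = nrow(contrib), beta = m$beta,
                   se = m$se, OR = m$OR, lo = m$lo, hi = m$hi, p = m$p)
    }))
    rownames(out) <- NULL
    out
}

.complementAllele <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize summary statistics to reference alleles
#'
#' Aligns each record's effect allele to a per-SNP reference: swapped
#' alleles flip the sign of Z and BETA and complement EAF; strand flips are
#' resolved by complementing for unambiguous SNPs.  Strand-ambiguous SNPs
#' (A/T, C/G) are kept only when the allele frequencies disambiguate the
#' orientation (|effect-allele frequency difference| < 0.2 for one
#' orientation only); otherwise they are dropped with a warning.
#'
#' @param stats Summary-statistics data.frame (association-module format).
#' @param reference data.frame with columns \code{SNP}, \code{EA},
#'   \code{OA} and optionally \code{EAF}.
#'
#' @return The harmonized subset of \code{stats}.
#' @export
harmonizeAlleles <- function(stats, reference) {
    idx <- match(stats$SNP, reference$SNP)
    keep <- rep(TRUE, nrow(stats))
    dropped <- character()
    for (i in seq_len(nrow(stats))) {
        j <- idx[i]
        if (is.na(j)) { keep[i] <- FALSE; next }
        ea <- toupper(stats$EA[i]); oa <- toupper(stats$OA[i])
        rea <- toupper(reference$EA[j]); roa <- toupper(reference$OA[j])
        ambiguous <- identical(oa, .complementAllele[[ea]])
        flip <- NA     # NA unknown, FALSE keep, TRUE flip sign
        if (ea == rea && oa == roa) flip <- FALSE
        else if (ea == roa && oa == rea) flip <- TRUE
        else if (!ambiguous) {
            cea <- .complementAllele[[ea]]; coa <- .complementAllele[[oa]]
            if (cea == rea && coa == roa) flip <- FALSE
            else if (cea == roa && coa == rea) flip <- TRUE
        }
        if (ambiguous && !is.na(flip) && "EAF" %in% colnames(reference) &&
            is.finite(reference$EAF[j]) && is.finite(stats$EAF[i])) {
            sameOk <- abs(stats$EAF[i] - reference$EAF[j]) < 0.2
            flipOk <- abs((1 - stats$EAF[i]) - reference$EAF[j]) < 0.2
            if (sameOk && !flipOk) flip <- FALSE
            else if (flipOk && !sameOk) flip <- TRUE
            else flip <- NA
        } else if (ambiguous) flip <- NA
        if (is.na(flip)) {
            keep[i] <- FALSE
            dropped <- c(dropped, stats$SNP[i])
            next
        }
        if (flip) {
            stats$Z[i] <- -stats$Z[i]
            if ("BETA" %in% colnames(stats)) stats$BETA[i] <- -stats$BETA[i]
            if (is.finite(stats$EAF[i])) stats$EAF[i] <- 1 - stats$EAF[i]
            stats$EA[i] <- rea; stats$OA[i] <- roa
        }
    }
    if (length(dropped))
        warning("dropped unresolvable strand-ambiguous SNP(s): ",
                paste(unique(dropped), collapse = ", "))
    stats[keep, , drop = FALSE]
}
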