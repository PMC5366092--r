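#' Effective sample size of a case/control study
#'
#' The METAL convention for sample-size-weighted meta-analysis of
#' case/control studies: \eqn{N_{eff} = 4 / (1/n_{cases} +
#' 1/n_{controls})}, the size of a balanced study with equal power.
#'
#' @param nCases,nControls Sample counts (> 0).
#' @return Effective sample size.
#' @export
effectiveN <- function(nCases, nControls) {
    if (any(nCases <= 0) || any(nControls <= 0))
        stop("case and control counts must be positive")
    4 / (1 / nCases + 1 / nControls)
}

#' Stouffer (sample-size weighted) meta-analysis of Z scores
#'
#' Combines per-cohort signed Z scores per SNP as
#' \eqn{Z_{meta} = \sum_i w_i Z_i / \sqrt{\sum_i w_i^2}} with
#' \eqn{w_i = \sqrt{N_i}}, where \eqn{N_i} is the cohort's effective
#' sample size (\code{weights = "effective"}, the METAL case/control
#' convention, requiring \code{NCAS}/\code{NCON} columns) or its raw
#' sample size (\code{weights = "raw"}).  Alleles must be harmonized
#' beforehand (see [harmonizeAlleles()]).
#'
#' @param statsList List of per-cohort summary-statistics data.frames
#'   (columns \code{SNP}, \code{Z}, \code{N}, optional \code{NCAS},
#'   \code{NCON}).
#' @param weights \code{"effective"} or \code{"raw"}.
#'
#' @return data.frame with one row per SNP occurring in any cohort:
#'   \code{SNP}, \code{Z}, \code{P}, \code{N} (summed weight base),
#'   \code{k} contributing cohorts and a METAL-style \code{DIRECTION}
#'   string (\code{+}/\code{-}/\code{?} per cohort, in input order).
#' @examples
#' s <- data.frame(SNP = "rs1", Z = 1.96, N = 1000)
#' stoufferMeta(list(s, s), weights = "raw")   # Z = 2.772
#' @export
stoufferMeta <- function(statsList, weights = c("effective", "raw")) {
    weights <- match.arg(weights)
    if (is.data.frame(statsList)) statsList <- list(statsList)
    snps <- unique(unlist(lapply(statsList, function(s) s$SNP)))
    if (!length(snps)) {
        warning("no SNPs to meta-analyse")
        return(data.frame(SNP = character(), Z = numeric(), P = numeric(),
                          N = numeric(), k = integer(),
                          DIRECTION = character()))
    }
    K <- length(statsList)
    weightOf <- function(s, i) {
        if (weights == "effective") {
            if (all(c("NCAS", "NCON") %in% colnames(s)) &&
                is.finite(s$NCAS[i]) && is.finite(s$NCON[i]))
                return(sqrt(effectiveN(s$NCAS[i], s$NCON[i])))
            # fall back to raw N when case/control split is unavailable
        }
        sqrt(s$N[i])
    }
    rows <- lapply(snps, function(id) {
        num <- 0; den <- 0; ntot <- 0; k <- 0L
        dir <- character(K)
        for (ci in seq_len(K)) {
            s <- statsList[[ci]]
            i <- match(id, s$SNP)
            if (is.na(i) || !is.finite(s$Z[i])) { dir[ci] <- "?"; next }
            w <- weightOf(s, i)
            num <- num + w * s$Z[i]
            den <- den + w^2
            ntot <- ntot + w^2
            k <- k + 1L
            dir[ci] <- if (s$Z[i] >= 0) "+" else "-"
        }
        if (k == 0L)
            return(data.frame(SNP = id, Z = NA_real_, P = NA_real_,
                              N = 0, k = 0L,
                              DIRECTION = paste(dir, collapse = "")))
        z <- num / sqrt(den)
        data.frame(SNP = id, Z = z, P = 2 * pnorm(-abs(z)), N = ntot,
                   k = k, DIRECTION = paste(dir, collapse = ""),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Fixed-effects inverse-variance weighted meta-analysis
#'
#' \eqn{\hat\beta = \sum_i \beta_i / se_i^2 \big/ \sum_i 1 / se_i^2},
#' \eqn{SE = (\sum_i 1/se_i^2)^{-1/2}}; the odds ratio and 95\% CI are
#' \eqn{\exp(\hat\beta \pm 1.96\,SE)}.
#'
#' @param betas Per-cohort effect estimates (log odds ratios).
#' @param ses Per-cohort standard errors (> 0).
#'
#' @return List with \code{beta}, \code{se}, \code{OR}, \code{lo},
#'   \code{hi}, \code{z}, \code{p} and \code{k}.
#' @examples
#' ivwMeta(c(0.1, 0.3), c(0.1, 0.1))  # beta 0.2, se ~0.0707
#' @export
ivwMeta <- function(betas, ses) {
    if (!length(betas) || length(betas) != length(ses))
        stop("'betas' and 'ses' must be non-empty and equal length")
    if (any(ses <= 0)) stop("standard errors must be positive")
    w <- 1 / ses^2
    beta <- sum(w * betas) / sum(w)
    se <- sqrt(1 / sum(w))
    z <- beta / se
    list(beta = beta, se = se, OR = exp(beta),
         lo = exp(beta - 1.96 * se), hi = exp(beta + 1.96 * se),
         z = z, p = 2 * pnorm(-abs(z)), k = length(betas))
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_i ((\beta_i - \hat\beta) / se_i)^2} referred to a
#' chi-square with \eqn{k - 1} degrees of freedom, with \eqn{\hat\beta}
#' the inverse-variance pooled estimate.
#'
#' @inheritParams ivwMeta
#' @param pooled Optional pooled estimate; computed by [ivwMeta()] when
#'   omitted.
#'
#' @return List with \code{Q}, \code{df} and \code{p}.
#' @export
cochranQ <- function(betas, ses, pooled = NULL) {
    if (length(betas) < 2L)
        stop("heterogeneity requires at least 2 cohorts")
    if (any(ses <= 0)) stop("standard errors must be positive")
    if (is.null(pooled)) pooled <- ivwMeta(betas, ses)$beta
    Q <- sum(((betas - pooled) / ses)^2)
    df <- length(betas) - 1L
    list(Q = Q, df = df, p = pchisq(Q, df = df, lower.tail = FALSE))
}

#' Greedy distance/LD clumping of summary statistics
#'
#' Repeatedly takes the smallest-p unassigned SNP as a locus index and
#' claims every unassigned SNP on the same chromosome within
#' \code{windowKb} kb; within each locus up to \code{snpsPerLocus - 1}
#' additional members are chosen by smallest p among claimed SNPs with
#' \eqn{r^2 \ge} \code{ldThreshold} to the index (when an LD matrix is
#' supplied) or among all claimed SNPs otherwise.  Ties are broken
#' deterministically by (p, chromosome, position, effect allele).
#'
#' @param stats Summary statistics with \code{SNP}, \code{CHR}, \code{BP},
#'   \code{P} (and \code{EA} for tie-breaking).
#' @param nLoci Maximum number of loci to form.
#' @param snpsPerLocus Maximum SNPs selected per locus.
#' @param windowKb Half-window in kb claimed either side of the index.
#' @param ld Optional symmetric r-squared matrix with dimnames = SNP IDs.
#' @param ldThreshold Minimum r-squared to the index for LD-based
#'   membership.
#' @param exclude Optional SNP IDs (e.g. previously reported loci) removed
#'   before clumping.
#'
#' @return data.frame with one row per selected SNP: \code{LOCUS},
#'   \code{INDEX_SNP}, \code{CHR}, \code{START}, \code{END}, \code{SNP},
#'   \code{P}, \code{RANK} (1 = index).
#' @export
clumpSelect <- function(stats, nLoci = 25L, snpsPerLocus = 3L,
                        windowKb = 500, ld = NULL, ldThreshold = 0.5,
                        exclude = NULL) {
    stopifnot(nLoci >= 1L, snpsPerLocus >= 1L)
    s <- stats[is.finite(stats$P), , drop = FALSE]
    if (!is.null(exclude)) s <- s[!s$SNP %in% exclude, , drop = FALSE]
    if (!nrow(s)) return(data.frame(LOCUS = integer(), INDEX_SNP = character(),
                                    CHR = character(), START = integer(),
                                    END = integer(), SNP = character(),
                                    P = numeric(), RANK = integer()))
    ea <- if ("EA" %in% colnames(s)) s$EA else rep("", nrow(s))
    ord <- order(s$P, s$CHR, s$BP, ea)
    s <- s[ord, , drop = FALSE]
    assigned <- rep(FALSE, nrow(s))
    win <- windowKb * 1000
    out <- list()
    locus <- 0L
    while (locus < nLoci && !all(assigned)) {
        idx <- which(!assigned)[1L]            # smallest p by sort order
        locus <- locus + 1L
        sameChr <- !assigned & s$CHR == s$CHR[idx] &
            abs(s$BP - s$BP[idx]) <= win
        claimed <- which(sameChr)              # includes the index itself
        assigned[claimed] <- TRUE
        members <- setdiff(claimed, idx)
        if (!is.null(ld)) {
            r2 <- vapply(members, function(m) {
                if (s$SNP[m] %in% rownames(ld) && s$SNP[idx] %in% colnames(ld))
                    ld[s$SNP[m], s$SNP[idx]] else 0
            }, numeric(1))
            members <- members[r2 >= ldThreshold]
        }
        members <- head(members, snpsPerLocus - 1L)  # already p-ordered
        pick <- c(idx, members)
        out[[locus]] <- data.frame(
            LOCUS = locus, INDEX_SNP = s$SNP[idx], CHR = s$CHR[idx],
            START = s$BP[idx] - win, END = s$BP[idx] + win,
            SNP = s$SNP[pick], P = s$P[pick], RANK = seq_along(pick),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Three-stage discovery / replication workflow
#'
#' Stage I summary statistics are clumped to the top loci
#' ([clumpSelect()]); the selected SNPs are meta-analysed across stages I
#' and II ([stoufferMeta()]); survivors of the first gate (default
#' \eqn{p < 5\times10^{-7}}) are carried into stage III and the final meta
#' combines all three stages, flagging genome-wide significance (default
#' \eqn{p < 5\times10^{-8}}).  The final statistic for a SNP is the plain
#' Stouffer combination of every stage — gating affects selection only.
#'
#' @param stage1,stage2,stage3 Per-stage summary-statistics data.frames
#'   (harmonized alleles; columns as for [stoufferMeta()]).
#' @param gate1 p-value gate applied to the stage I+II meta.
#' @param gwThreshold Genome-wide significance threshold for the final
#'   meta.
#' @param weights Weighting mode passed to [stoufferMeta()].
#' @param ... Further arguments (e.g. \code{nLoci}, \code{snpsPerLocus},
#'   \code{windowKb}, \code{exclude}) passed to [clumpSelect()].
#'
#' @return List with \code{selection} (stage I clumping), \code{meta12},
#'   \code{final} (meta data.frames) and \code{audit}: one row per carried
#'   SNP with its p at each decision point, gate outcomes and where (if
#'   anywhere) it was eliminated.  A carried SNP absent from a later stage
#'   keeps a \code{?} in its direction string and is flagged in the audit.
#' @export
runStages <- function(stage1, stage2, stage3, gate1 = 5e-7,
                      gwThreshold = 5e-8, weights = "effective", ...) {
    selection <- clumpSelect(stage1, ...)
    carried <- unique(selection$SNP)
    sub <- function(s, ids) s[s$SNP %in% ids, , drop = FALSE]
    meta12 <- stoufferMeta(list(sub(stage1, carried), sub(stage2, carried)),
                           weights = weights)
    pass1 <- meta12$SNP[is.finite(meta12$P) & meta12$P < gate1]
    final <- stoufferMeta(list(sub(stage1, pass1), sub(stage2, pass1),
                               sub(stage3, pass1)), weights = weights)
    p1 <- stage1$P[match(carried, stage1$SNP)]
    p12 <- meta12$P[match(carried, meta12$SNP)]
    pf <- final$P[match(carried, final$SNP)]
    inS2 <- carried %in% stage2$SNP
    inS3 <- carried %in% stage3$SNP
    passedGate1 <- carried %in% pass1
    genomeWide <- passedGate1 & is.finite(pf) & pf < gwThreshold
    audit <- data.frame(
        SNP = carried, P_STAGE1 = p1, P_META12 = p12,
        PASSED_GATE1 = passedGate1, P_FINAL = pf,
        GENOME_WIDE = genomeWide,
        IN_STAGE2 = inS2, IN_STAGE3 = inS3,
        ELIMINATED_AT = ifelse(!passedGate1, "gate1",
                        ifelse(!genomeWide, "final", "")),
        stringsAsFactors = FALSE)
    list(selection = selection, meta12 = meta12, final = final,
         audit = audit, gates = c(gate1 = gate1, gw = gwThreshold))
}
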