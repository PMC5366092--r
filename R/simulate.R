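#' Simulation configuration
#'
#' Bundles the generator settings for one synthetic case/control cohort
#' sampled under the age-structured liability model.  Defaults describe
#' the study conditions used throughout the package's own validation:
#' three-figure case/control cohorts drawn from an adult source population
#' (uniform ages 35-85), a modest SNP panel in AR(1)-correlated LD blocks,
#' one causal SNP of frequency 0.3, and clean (info = 1) dosages.
#'
#' @param nCases,nControls Target sample counts after ascertainment.
#' @param ageRange Source-population age range in years (uniform).
#' @param M Number of SNPs.
#' @param mafRange Range the non-causal effect-allele frequencies are
#'   drawn from.
#' @param blockSize SNPs per LD block (AR(1) latent correlation within a
#'   block, independence across blocks).
#' @param rho Latent within-block AR(1) correlation, in [0, 1).
#' @param causalIndex Column index of the causal SNP (default: middle of
#'   the panel).
#' @param causalMaf Effect-allele frequency of the causal SNP.
#' @param gamma Liability effect per effect allele (0 = null).
#' @param targetInfo Imputation info score targeted by dosage degradation
#'   (scalar or per-SNP vector; 1 = genotypes passed through unchanged).
#' @param caseAgeWeight Case-ascertainment rate per year: cases are
#'   sampled from the affected pool with weight
#'   \eqn{\exp(-caseAgeWeight (t - t_{min}))}.  0 samples cases in
#'   proportion to the population; ~0.08 mimics a cohort enriched for
#'   younger-onset cases.
#' @param poolBatch,maxPool Source-population batch size and cap.
#'
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nCases = 1500L, nControls = 1500L,
                      ageRange = c(35, 85), M = 60L,
                      mafRange = c(0.05, 0.5), blockSize = 10L,
                      rho = 0.8, causalIndex = NULL, causalMaf = 0.3,
                      gamma = 0, targetInfo = 1, caseAgeWeight = 0,
                      poolBatch = 50000L, maxPool = 4e6) {
    if (is.null(causalIndex)) causalIndex <- ceiling(M / 2)
    cfg <- list(nCases = as.integer(nCases), nControls = as.integer(nControls),
                ageRange = ageRange, M = as.integer(M),
                mafRange = mafRange, blockSize = as.integer(blockSize),
                rho = rho, causalIndex = as.integer(causalIndex),
                causalMaf = causalMaf, gamma = gamma,
                targetInfo = targetInfo, caseAgeWeight = caseAgeWeight,
                poolBatch = as.integer(poolBatch), maxPool = maxPool)
    if (!is.finite(cfg$gamma)) stop("'gamma' must be finite")
    if (cfg$blockSize > cfg$M) stop("'blockSize' must not exceed M")
    if (cfg$rho < 0 || cfg$rho >= 1) stop("'rho' must lie in [0, 1)")
    if (any(cfg$mafRange <= 0) || any(cfg$mafRange > 0.5))
        stop("'mafRange' must lie in (0, 0.5]")
    if (cfg$causalMaf <= 0 || cfg$causalMaf > 0.5)
        stop("'causalMaf' must lie in (0, 0.5]")
    if (cfg$causalIndex < 1L || cfg$causalIndex > cfg$M)
        stop("'causalIndex' out of range")
    if (any(cfg$targetInfo <= 0 | cfg$targetInfo > 1))
        stop("'targetInfo' must lie in (0, 1]")
    class(cfg) <- "SimConfig"
    cfg
}

.blockOf <- function(M, blockSize) rep(seq_len(ceiling(M / blockSize)),
                                       each = blockSize, length.out = M)

# One haplotype matrix (n x M, alleles 0/1): latent AR(1) Gaussian within
# blocks thresholded at qnorm(1 - maf).
.haplotype <- function(n, maf, blockId, rho) {
    M <- length(maf)
    z <- matrix(NA_real_, n, M)
    for (j in seq_len(M)) {
        if (j == 1L || blockId[j] != blockId[j - 1L])
            z[, j] <- rnorm(n)
        else
            z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * rnorm(n)
    }
    z > matrix(qnorm(1 - maf), n, M, byrow = TRUE)
}

#' Simulate genotypes with block LD structure
#'
#' Two haplotypes per individual are generated from a latent Gaussian
#' AR(1) process within consecutive blocks (independent across blocks) and
#' thresholded so each SNP's allele frequency matches its target MAF; the
#' genotype is the haplotype sum.  Fully deterministic under \code{seed}.
#'
#' @param n Individuals.
#' @param M SNPs.
#' @param mafRange Range targeted frequencies are drawn from (ignored when
#'   \code{maf} is supplied).
#' @param blockSize SNPs per LD block.
#' @param rho Latent AR(1) correlation within blocks.
#' @param seed Optional integer seed.
#' @param maf Optional vector of target frequencies (length \code{M}).
#'
#' @return List with \code{genotypes} (n x M matrix of 0/1/2),
#'   \code{maf} (targets) and \code{blockId}.
#' @export
simulateHaplotypes <- function(n, M, mafRange = c(0.05, 0.5),
                               blockSize = 10L, rho = 0.8, seed = NULL,
                               maf = NULL) {
    if (blockSize > M) stop("'blockSize' must not exceed M")
    withSeed(seed, {
        if (is.null(maf))
            maf <- runif(M, mafRange[1], mafRange[2])
        blockId <- .blockOf(M, blockSize)
        g <- .haplotype(n, maf, blockId, rho) +
             .haplotype(n, maf, blockId, rho)
        list(genotypes = g, maf = maf, blockId = blockId)
    })
}

# Truncated standard-normal draw above (allele = 1) or below the
# threshold, by inverse-CDF on the appropriate tail.
.truncLatent <- function(allele, thr) {
    u <- runif(length(allele))
    p <- pnorm(thr)
    ifelse(allele, qnorm(p + u * (1 - p)), qnorm(u * p))
}

# Rebuild a whole LD block's haplotype alleles conditional on the observed
# allele at one position, using the AR(1) Markov property in both
# directions from that position.
.expandBlock <- function(allele, pos, maf, rho) {
    n <- length(allele)
    M <- length(maf)
    thr <- qnorm(1 - maf)
    z <- matrix(NA_real_, n, M)
    z[, pos] <- .truncLatent(allele, thr[pos])
    if (pos < M) for (j in seq.int(pos + 1L, M))
        z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * rnorm(n)
    if (pos > 1L) for (j in seq.int(pos - 1L, 1L))
        z[, j] <- rho * z[, j + 1L] + sqrt(1 - rho^2) * rnorm(n)
    z > matrix(thr, n, M, byrow = TRUE)
}

#' Degrade hard genotypes to imputed-quality dosages
#'
#' Models lossy imputation as a per-haplotype posterior: each of an
#' individual's two haplotype alleles is retained with probability equal
#' to the target info score and otherwise replaced by the population
#' allele frequency (its prior mean), and the dosage is the sum of the
#' two resulting allele posteriors.  Under this mixture the dosage
#' variance is exactly \eqn{k \cdot 2 f (1 - f)} at retention probability
#' \eqn{k}, so the estimated info score, var(dosage) / (2 f (1 - f)),
#' is unbiased for the target, and dosages always lie in [0, 2].  A
#' target of 1 passes genotypes through unchanged.
#'
#' @param genotypes n x M matrix of allele counts (0/1/2).
#' @param targetInfo Scalar or per-SNP target info in (0, 1].
#' @param seed Optional integer seed.
#'
#' @return List with \code{dosage} (n x M) and \code{info} (estimated
#'   per-SNP info scores of the returned dosages).
#' @export
degradeToDosage <- function(genotypes, targetInfo, seed = NULL) {
    if (any(targetInfo <= 0 | targetInfo > 1))
        stop("'targetInfo' must lie in (0, 1]")
    M <- ncol(genotypes)
    n <- nrow(genotypes)
    target <- rep_len(targetInfo, M)
    withSeed(seed, {
        dosage <- genotypes
        mode(dosage) <- "numeric"
        for (j in seq_len(M)) {
            if (target[j] == 1) next
            f <- mean(genotypes[, j]) / 2
            if (f == 0 || f == 1) next
            # split the genotype into exchangeable haplotype alleles
            g <- genotypes[, j]
            a1 <- ifelse(g == 2L, 1L, ifelse(g == 0L, 0L,
                                             rbinom(n, 1L, 0.5)))
            a2 <- g - a1
            keep1 <- rbinom(n, 1L, target[j]) == 1L
            keep2 <- rbinom(n, 1L, target[j]) == 1L
            dosage[, j] <- ifelse(keep1, a1, f) + ifelse(keep2, a2, f)
        }
        list(dosage = dosage, info = infoScore(dosage))
    })
}

#' Estimated imputation info score of dosages
#'
#' Ratio of the observed dosage variance to the binomial variance expected
#' at the estimated allele frequency, \eqn{var(d) / (2 \hat f (1 - \hat
#' f))} with \eqn{\hat f = mean(d) / 2}.
#'
#' @param dosage Vector, or n x M matrix (per-column scores).
#' @return Numeric info score(s).
#' @export
infoScore <- function(dosage) {
    if (!is.matrix(dosage)) dosage <- matrix(dosage, ncol = 1L)
    f <- colMeans(dosage) / 2
    drop(apply(dosage, 2, var) / (2 * f * (1 - f)))
}

#' Simulate an age-structured case/control cohort
#'
#' Individuals are drawn from the source population with uniform ages and
#' balanced sexes; the liability is \eqn{\phi = c (t - \bar t) + m +
#' \gamma (g - 2f) + N(0, 1)} (the genetic term centred so the marginal
#' age-specific case rate stays on the calibrated schedule), and a person
#' is a case iff \eqn{\phi \ge 0}.  Drawing continues in batches until the
#' case and control quotas are reachable; cases are then sampled with the
#' configured young-onset ascertainment weight and controls uniformly.
#' Only the causal SNP is generated at the population stage (its marginal
#' law is Binomial(2, maf)); after selection the causal SNP's LD block is
#' completed by exact conditional AR(1) reconstruction and all other
#' blocks, independent of the phenotype given the causal genotype, are
#' generated directly for the selected samples.
#'
#' @param config A [simConfig()] list.
#' @param model A calibrated [LiabilityModel-class].
#' @param seed Optional integer seed (full determinism).
#' @param maf Optional fixed per-SNP frequency vector (e.g. to share a SNP
#'   panel across cohorts); drawn from \code{config$mafRange} otherwise.
#'
#' @return A [GwasCohort-class]; simulation truth (gamma, causal index,
#'   frequencies, pool size, population case rate) is stored in its
#'   metadata under \code{$truth}.
#' @export
simulateCohort <- function(config, model, seed = NULL, maf = NULL) {
    stopifnot(inherits(config, "SimConfig"), is(model, "LiabilityModel"))
    withSeed(seed, {
        M <- config$M
        if (is.null(maf)) maf <- runif(M, config$mafRange[1], config$mafRange[2])
        maf[config$causalIndex] <- config$causalMaf
        sexes <- names(model@slope)
        acc <- list(age = list(), sex = list(), h1 = list(), h2 = list(),
                    phi = list())
        pool <- 0L; nCase <- 0L
        repeat {
            nb <- config$poolBatch
            t <- runif(nb, config$ageRange[1], config$ageRange[2])
            sx <- sample(sexes, nb, replace = TRUE)
            a1 <- rbinom(nb, 1L, config$causalMaf)
            a2 <- rbinom(nb, 1L, config$causalMaf)
            g <- a1 + a2
            eps <- config$gamma * (g - 2 * config$causalMaf) + rnorm(nb)
            tau <- liabilityThreshold(model, t, sx)
            ph <- eps - tau
            acc$age <- c(acc$age, list(t)); acc$sex <- c(acc$sex, list(sx))
            acc$h1 <- c(acc$h1, list(a1)); acc$h2 <- c(acc$h2, list(a2))
            acc$phi <- c(acc$phi, list(ph))
            pool <- pool + nb
            nCase <- nCase + sum(ph >= 0)
            nCtrl <- pool - nCase
            # weighted case ascertainment needs a surplus of affected
            # individuals to choose from
            caseNeed <- config$nCases *
                (if (config$caseAgeWeight > 0) 3L else 1L)
            if (nCase >= caseNeed && nCtrl >= config$nControls) break
            if (pool >= config$maxPool)
                stop(sprintf(paste0("source population exhausted: %d cases",
                                    " / %d controls available of %d / %d",
                                    " requested"),
                             nCase, nCtrl, config$nCases, config$nControls))
        }
        age <- unlist(acc$age); sex <- unlist(acc$sex)
        h1 <- unlist(acc$h1); h2 <- unlist(acc$h2); phi <- unlist(acc$phi)
        isCase <- phi >= 0
        caseIdx <- which(isCase)
        w <- exp(-config$caseAgeWeight * (age[caseIdx] - config$ageRange[1]))
        pickCase <- if (config$caseAgeWeight > 0)
            sample(caseIdx, config$nCases, prob = w)
        else sample(caseIdx, config$nCases)
        pickCtrl <- sample(which(!isCase), config$nControls)
        sel <- c(pickCase, pickCtrl)
        n <- length(sel)
        status <- rep(c(1L, 0L), c(config$nCases, config$nControls))

        blockId <- .blockOf(M, config$blockSize)
        cb <- blockId[config$causalIndex]
        inCb <- which(blockId == cb)
        posInCb <- match(config$causalIndex, inCb)
        geno <- matrix(0L, n, M)
        for (hap in list(h1[sel], h2[sel])) {
            hb <- .expandBlock(hap == 1L, posInCb, maf[inCb], config$rho)
            geno[, inCb] <- geno[, inCb] + hb
            for (b in setdiff(unique(blockId), cb)) {
                cols <- which(blockId == b)
                geno[, cols] <- geno[, cols] +
                    .haplotype(n, maf[cols], blockId[cols], config$rho)
            }
        }
        deg <- degradeToDosage(geno, config$targetInfo)
        # ten 2-Mb block regions per chromosome keeps positions in range
        chr <- 1L + (blockId - 1L) %/% 10L
        blockInChr <- (blockId - 1L) %% 10L
        snpPos <- as.integer(blockInChr * 2e6 +
            (seq_len(M) - ave(seq_len(M), blockId, FUN = min)) * 1e4 +
            1e5)
        info <- data.frame(
            SNP = sprintf("snp%04d", seq_len(M)), CHR = as.character(chr),
            BP = snpPos, EA = "A", OA = "G",
            EAF = colMeans(deg$dosage) / 2,
            INFO = ifelse(rep_len(config$targetInfo, M) == 1, 1, deg$info),
            stringsAsFactors = FALSE)
        pheno <- data.frame(
            sample_id = sprintf("S%05d", seq_len(n)),
            status = status, age = age[sel], sex = sex[sel],
            stringsAsFactors = FALSE)
        truth <- list(gamma = config$gamma, causalIndex = config$causalIndex,
                      causalSnp = info$SNP[config$causalIndex],
                      maf = maf, poolSize = pool,
                      caseRate = mean(isCase), seed = seed,
                      caseAgeWeight = config$caseAgeWeight)
        GwasCohort(t(deg$dosage), info, pheno, metadata = list(truth = truth))
    })
}

#' Simulate a multi-cohort study with a shared SNP panel
#'
#' Draws the SNP frequency panel once and generates \code{nCohorts}
#' cohorts under the same configuration (deterministic per-cohort seeds
#' derived from \code{seed}).
#'
#' @inheritParams simulateCohort
#' @param nCohorts Number of cohorts.
#'
#' @return List of [GwasCohort-class] objects.
#' @export
simulateStudy <- function(config, model, nCohorts = 3L, seed = NULL) {
    maf <- withSeed(seed, runif(config$M, config$mafRange[1],
                                config$mafRange[2]))
    base <- if (is.null(seed)) sample.int(1e6, 1) else as.integer(seed)
    lapply(seq_len(nCohorts), function(i)
        simulateCohort(config, model, seed = (base + 7919L * i) %% .Machine$integer.max,
                       maf = maf))
}

#' Simulate a molecular trait driven by one SNP
#'
#' \eqn{trait = b \cdot dosage + N(0, \sigma^2)}, with \eqn{b} either given
#' or derived from a target fraction of trait variance explained,
#' \eqn{b^2 2 f (1 - f) / (b^2 2 f (1 - f) + \sigma^2)}.
#'
#' @param cohort A [GwasCohort-class].
#' @param snp SNP ID (or index) of the trait's causal SNP.
#' @param varExplained Target variance explained (used when \code{b} is
#'   NULL); the cis-mQTL design point in this package is 0.06.
#' @param sigma Residual SD.
#' @param b Optional effect size per allele.
#' @param seed Optional integer seed.
#'
#' @return List with \code{trait}, \code{b}, \code{snp} and the implied
#'   \code{varExplained}.
#' @export
simulateMolecularTrait <- function(cohort, snp, varExplained = 0.06,
                                   sigma = 1, b = NULL, seed = NULL) {
    ids <- snpInfo(cohort)$SNP
    j <- if (is.character(snp)) match(snp, ids) else as.integer(snp)
    if (is.na(j) || j < 1L || j > length(ids))
        stop("causal SNP not present in the cohort")
    d <- dosages(cohort)[j, ]
    f <- mean(d) / 2
    V <- 2 * f * (1 - f)
    if (is.null(b))
        b <- sqrt(varExplained * sigma^2 / ((1 - varExplained) * V))
    ve <- b^2 * V / (b^2 * V + sigma^2)
    withSeed(seed, {
        trait <- b * d + rnorm(length(d), 0, sigma)
        list(trait = trait, b = b, snp = ids[j], varExplained = ve)
    })
}
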