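test_that("Stouffer meta matches hand-computed combinations", {
    s <- data.frame(SNP = "rs1", Z = 1.96, N = 1000)
    out <- stoufferMeta(list(s, s), weights = "raw")
    expect_equal(out$Z, (1.96 + 1.96) / sqrt(2), tolerance = 1e-10)
    expect_equal(out$Z, 2.772, tolerance = 1e-3)
    expect_equal(out$DIRECTION, "++")

    # single cohort: identity
    one <- stoufferMeta(list(s), weights = "raw")
    expect_equal(one$Z, 1.96, tolerance = 1e-12)

    # opposite Z, equal weights: exact cancellation
    s2 <- s; s2$Z <- -1.96
    null <- stoufferMeta(list(s, s2), weights = "raw")
    expect_equal(null$Z, 0, tolerance = 1e-12)
    expect_equal(null$P, 1)
    expect_equal(null$DIRECTION, "+-")
})

test_that("Stouffer weighting modes and missing cohorts behave as specified", {
    a <- data.frame(SNP = "rs1", Z = 2.0, N = 3000, NCAS = 500, NCON = 2500)
    b <- data.frame(SNP = "rs1", Z = 1.0, N = 3000, NCAS = 1500, NCON = 1500)
    out <- stoufferMeta(list(a, b), weights = "effective")
    wA <- sqrt(4 / (1 / 500 + 1 / 2500))
    wB <- sqrt(4 / (1 / 1500 + 1 / 1500))
    expect_equal(out$Z, (wA * 2 + wB * 1) / sqrt(wA^2 + wB^2),
                 tolerance = 1e-12)
    # raw mode weights equally here
    raw <- stoufferMeta(list(a, b), weights = "raw")
    expect_equal(raw$Z, 3 / sqrt(2), tolerance = 1e-12)

    # permutation invariance across cohort order (up to direction string)
    rev <- stoufferMeta(list(b, a), weights = "effective")
    expect_equal(rev$Z, out$Z, tolerance = 1e-12)

    # SNP absent from one cohort: '?' in the direction string
    c2 <- data.frame(SNP = "rs2", Z = -1.0, N = 1000)
    m <- stoufferMeta(list(a, c2), weights = "raw")
    expect_equal(m$DIRECTION[m$SNP == "rs1"], "+?")
    expect_equal(m$DIRECTION[m$SNP == "rs2"], "?-")
    expect_equal(m$Z[m$SNP == "rs2"], -1.0)
})

test_that("inverse-variance pooling matches the closed form", {
    out <- ivwMeta(c(0.1, 0.3), c(0.1, 0.1))
    expect_equal(out$beta, 0.2, tolerance = 1e-12)
    expect_equal(out$se, 0.1 / sqrt(2), tolerance = 1e-12)
    expect_equal(out$se, 0.0707, tolerance = 1e-3)
    expect_equal(out$OR, exp(0.2))
    expect_true(out$lo <= out$OR && out$OR <= out$hi)

    one <- ivwMeta(0.25, 0.1)
    expect_equal(one$beta, 0.25)
    expect_equal(one$se, 0.1)

    # near-infinite SE: that cohort's weight vanishes
    cont <- ivwMeta(c(0.1, 5), c(0.1, 1e6))
    expect_equal(cont$beta, 0.1, tolerance = 1e-6)

    # pooled SE never exceeds the best cohort's SE (randomized instances)
    set.seed(8)
    for (i in 1:20) {
        k <- sample(2:6, 1)
        betas <- rnorm(k); ses <- runif(k, 0.05, 0.5)
        expect_lte(ivwMeta(betas, ses)$se, min(ses))
    }
    expect_error(ivwMeta(c(0.1), c(-1)), "positive")
})

test_that("Cochran's Q heterogeneity is exact and calibrated", {
    out <- cochranQ(c(0.1, 0.3), c(0.1, 0.1))
    expect_equal(out$Q, 2, tolerance = 1e-12)
    expect_equal(out$df, 1L)
    expect_equal(out$p, 0.1573, tolerance = 1e-3)

    same <- cochranQ(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3))
    expect_equal(same$Q, 0, tolerance = 1e-20)
    expect_equal(same$p, 1)

    # under homogeneity the heterogeneity p is uniform
    set.seed(13)
    ps <- replicate(300, {
        ses <- runif(10, 0.05, 0.3)
        cochranQ(rnorm(10, 0, ses), ses)$p
    })
    expect_gt(ks.test(ps, "punif")$p.value, 0.001)
    expect_error(cochranQ(0.1, 0.1), "at least 2")
})

test_that("clumping matches a brute-force locus assignment oracle", {
    # 6 SNPs within 100kb on one chromosome, window 500kb -> one locus,
    # members are the three smallest p
    st <- data.frame(SNP = paste0("rs", 1:6), CHR = "1",
                     BP = c(100, 120, 140, 160, 180, 200) * 1000L,
                     EA = "A",
                     P = c(0.02, 1e-6, 0.5, 3e-4, 0.07, 0.009))
    sel <- clumpSelect(st, nLoci = 25, snpsPerLocus = 3, windowKb = 500)
    expect_equal(length(unique(sel$LOCUS)), 1L)
    expect_equal(sel$INDEX_SNP[1], "rs2")
    expect_setequal(sel$SNP, c("rs2", "rs4", "rs6"))   # three smallest p
    expect_equal(sel$SNP[sel$RANK == 1], "rs2")

    # SNPs farther apart than the window: one locus each
    far <- st; far$BP <- (1:6) * 2e6L
    self <- clumpSelect(far, nLoci = 25, snpsPerLocus = 3, windowKb = 500)
    expect_equal(length(unique(self$LOCUS)), 6L)
    expect_equal(nrow(self), 6L)

    # LD-restricted membership
    ld <- diag(6); dimnames(ld) <- list(st$SNP, st$SNP)
    ld["rs2", "rs4"] <- ld["rs4", "rs2"] <- 0.8
    ld["rs2", "rs6"] <- ld["rs6", "rs2"] <- 0.1
    sel2 <- clumpSelect(st, nLoci = 1, snpsPerLocus = 3, windowKb = 500,
                        ld = ld)
    expect_setequal(sel2$SNP, c("rs2", "rs4"))

    # exact p ties resolved by position, stably across runs
    tie <- data.frame(SNP = c("a", "b"), CHR = "1", BP = c(5e6L, 1e6L),
                      EA = "A", P = c(0.01, 0.01))
    s1 <- clumpSelect(tie, nLoci = 2, snpsPerLocus = 1, windowKb = 100)
    s2 <- clumpSelect(tie, nLoci = 2, snpsPerLocus = 1, windowKb = 100)
    expect_identical(s1, s2)
    expect_equal(s1$INDEX_SNP[1], "b")   # smaller position wins the tie
})

test_that("three-stage workflow gates, audits, and preserves the final meta", {
    mk <- function(snp, z, n) data.frame(SNP = snp, CHR = "1",
                                         BP = match(snp, snp) * 2e6L,
                                         EA = "A", Z = z, N = n,
                                         P = pchisq(z^2, 1, lower.tail = FALSE))
    s1 <- mk(c("rsA", "rsB", "rsC"), c(6.0, 5.2, 1.0), 3000)
    s2 <- mk(c("rsA", "rsB", "rsC"), c(4.5, -0.5, 0.3), 3000)
    s3 <- mk(c("rsA", "rsB", "rsC"), c(3.0, 0.2, -0.1), 3000)
    out <- runStages(s1, s2, s3, gate1 = 5e-7, gwThreshold = 5e-8,
                     weights = "raw")
    aud <- out$audit
    # rsA replicates through both gates; rsB was stage-I-only
    expect_true(aud$GENOME_WIDE[aud$SNP == "rsA"])
    expect_false(aud$PASSED_GATE1[aud$SNP == "rsB"])
    expect_equal(aud$ELIMINATED_AT[aud$SNP == "rsB"], "gate1")
    # final statistic equals the plain Stouffer over all three stages
    direct <- stoufferMeta(list(s1[s1$SNP == "rsA", ], s2[s2$SNP == "rsA", ],
                                s3[s3$SNP == "rsA", ]), weights = "raw")
    expect_equal(out$final$Z[out$final$SNP == "rsA"], direct$Z,
                 tolerance = 1e-12)

    # SNP absent from stage III: kept, flagged, direction has '?'
    s3b <- s3[s3$SNP != "rsA", ]
    out2 <- runStages(s1, s2, s3b, gate1 = 5e-7, weights = "raw")
    expect_false(out2$audit$IN_STAGE3[out2$audit$SNP == "rsA"])
    expect_match(out2$final$DIRECTION[out2$final$SNP == "rsA"], "\\?$")
})
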