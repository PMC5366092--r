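test_that("snpFilter applies inclusive info and MAF thresholds with a report", {
    d <- matrix(1, nrow = 5, ncol = 12)
    info <- data.frame(SNP = paste0("rs", 1:5), CHR = "1",
                       BP = (1:5) * 1000L, EA = "A", OA = "G",
                       EAF = c(0.30, 0.30, 0.005, 0.02, 0.30),
                       INFO = c(0.95, 0.65, 0.80, 0.71, 0.99))
    ph <- data.frame(sample_id = sprintf("S%02d", 1:12),
                     status = rep(c(1L, 0L), 6), age = 60)
    co <- GwasCohort(d, info, ph)
    out <- snpFilter(co, minInfo = 0.7, minMaf = 0.01)
    expect_equal(snpInfo(out)$SNP, c("rs1", "rs4", "rs5"))
    rep <- exclusionReport(out)
    expect_setequal(rep$SNP, c("rs2", "rs3"))
    expect_match(rep$reason[rep$SNP == "rs2"], "info")
    expect_match(rep$reason[rep$SNP == "rs3"], "MAF")

    # boundary: info exactly at the threshold is retained
    info$INFO[2] <- 0.7
    co2 <- GwasCohort(d, info, ph)
    out2 <- snpFilter(co2, 0.7, 0.01)
    expect_true("rs2" %in% snpInfo(out2)$SNP)
    expect_false("rs2" %in% exclusionReport(out2)$SNP)

    # everything passes: identical cohort, empty report
    info$INFO <- 0.99; info$EAF <- 0.3
    co3 <- GwasCohort(d, info, ph)
    out3 <- snpFilter(co3)
    expect_equal(dim(out3), dim(co3))
    expect_equal(nrow(exclusionReport(out3)), 0L)
    expect_error(snpFilter(co3, minInfo = 1.2), "thresholds")
})

test_that("residualize matches the normal-equations oracle and its invariants", {
    set.seed(41)
    # no covariates: mean centering
    v <- rnorm(15)
    expect_equal(residualize(v), v - mean(v), tolerance = 1e-12)
    # values equal to a covariate column: zero residual
    C <- matrix(rnorm(30), ncol = 2)
    expect_lt(max(abs(residualize(C[, 1], C))), 1e-12)
    # random instance vs explicit (X'X)^{-1} X'y solve
    y <- rnorm(20); X <- matrix(rnorm(40), ncol = 2)
    Xi <- cbind(1, X)
    oracle <- y - Xi %*% solve(t(Xi) %*% Xi, t(Xi) %*% y)
    expect_equal(residualize(y, X), drop(oracle), tolerance = 1e-10)
    # idempotence and orthogonality
    r1 <- residualize(y, X)
    expect_equal(residualize(r1, X), r1, tolerance = 1e-10)
    expect_lt(max(abs(t(Xi) %*% r1)), 1e-8 * 20 * max(abs(Xi)))
    # rank deficiency is reported with the collinear column
    Xbad <- cbind(a = X[, 1], b = X[, 1])
    expect_error(residualize(y, Xbad), "collinear.*b")
})

test_that("liability score test equals N r^2 against the brute-force oracle", {
    rec <- suppressWarnings(liabilityScoreTest(c(0, 1, 2, 1), c(-1, 0, 1, 0)))
    expect_equal(rec$CHISQ, 4, tolerance = 1e-12)
    expect_equal(rec$Z, 2, tolerance = 1e-12)
    expect_equal(rec$P, 0.0455, tolerance = 1e-3)

    # exactly orthogonal posterior: chi-square 0, p = 1
    rec0 <- suppressWarnings(liabilityScoreTest(c(0, 1, 2, 1),
                                                c(1, -1, 1, -1)))
    expect_equal(rec0$CHISQ, 0, tolerance = 1e-20)
    expect_equal(rec0$P, 1)

    # n = 200 null SNP with covariates vs an independent implementation
    set.seed(99)
    n <- 200
    d <- rbinom(n, 2, 0.4); y <- rnorm(n); C <- matrix(rnorm(2 * n), ncol = 2)
    rec <- liabilityScoreTest(d, y, C)
    Xi <- cbind(1, C)
    H <- Xi %*% solve(t(Xi) %*% Xi) %*% t(Xi)
    dr <- d - H %*% d; yr <- y - H %*% y
    r <- sum(dr * yr) / sqrt(sum(dr^2) * sum(yr^2))
    expect_equal(rec$CHISQ, n * r^2, tolerance = 1e-12)
    expect_equal(rec$Z, sign(r) * sqrt(n * r^2), tolerance = 1e-12)

    # constant dosage: flagged untestable, not dropped
    flat <- liabilityScoreTest(rep(1, n), y, C)
    expect_true(is.na(flat$P) && is.na(flat$Z))
    expect_equal(flat$N, n)
})

test_that("logistic association reproduces the contingency-table odds ratio", {
    # 2x2 collapse: cases 30 exposed / 70 unexposed, controls 10 / 90
    dosage <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
    status <- c(rep(1, 100), rep(0, 100))
    rec <- logisticAssoc(dosage, status)
    expect_equal(exp(rec$BETA), (30 * 90) / (70 * 10), tolerance = 1e-6)
    expect_equal(rec$CHISQ, rec$Z^2, tolerance = 1e-12)

    # dosage independent of status: estimate near zero
    set.seed(11)
    d <- rbinom(400, 2, 0.3); s <- rep(c(0, 1), 200)
    r0 <- logisticAssoc(d, s)
    expect_lt(abs(r0$BETA), 3 * r0$SE)

    # parameter recovery at n = 2000, true log-OR 0.15
    set.seed(12)
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    pr <- plogis(-0.5 + 0.15 * g)
    z <- rbinom(n, 1, pr)
    r1 <- logisticAssoc(g, z)
    expect_lt(abs(r1$BETA - 0.15), 3 * r1$SE)

    # perfect separation: flagged with missing SE
    sep <- suppressWarnings(logisticAssoc(c(rep(0, 10), rep(2, 10)),
                                          c(rep(0, 10), rep(1, 10))))
    expect_true(is.na(sep$SE))
    expect_error(logisticAssoc(g, rep(1, n)), "cases and controls")
})

test_that("linear QTL regression matches the normal-equations oracle", {
    set.seed(21)
    d <- rbinom(12, 2, 0.5)
    rec <- suppressWarnings(linearQtlAssoc(0.5 * d, d))
    expect_equal(rec$BETA, 0.5, tolerance = 1e-12)
    expect_equal(rec$R2, 1, tolerance = 1e-12)

    # independent trait: slope within 3 SE of zero
    y <- rnorm(300); g <- rbinom(300, 2, 0.3)
    r0 <- linearQtlAssoc(y, g)
    expect_lt(abs(r0$BETA), 3 * r0$SE)

    # 12-point worked instance vs explicit solve
    y12 <- rnorm(12); C <- matrix(rnorm(12), ncol = 1)
    r12 <- suppressWarnings(linearQtlAssoc(y12, d, C))
    Xi <- cbind(1, d, C)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y12)
    expect_equal(r12$BETA, beta[2], tolerance = 1e-10)

    flat <- suppressWarnings(linearQtlAssoc(rep(1, 12), d))
    expect_true(is.na(flat$P))
})

test_that("genomic control deflates but never inflates", {
    set.seed(5)
    z <- rnorm(500)
    rec <- data.frame(SNP = paste0("rs", 1:500), Z = z, CHISQ = z^2,
                      P = pchisq(z^2, 1, lower.tail = FALSE))
    out <- genomicControl(rec)
    expect_equal(out$lambda, median(z^2) / qchisq(0.5, 1), tolerance = 1e-12)

    # doubling every chi-square doubles lambda, and adjustment restores scale
    rec2 <- rec; rec2$CHISQ <- 2 * rec$CHISQ; rec2$Z <- sqrt(2) * rec$Z
    out2 <- genomicControl(rec2)
    expect_equal(out2$lambda, 2 * out$lambda, tolerance = 1e-12)
    if (out2$lambda > 1)
        expect_equal(median(out2$records$CHISQ), qchisq(0.5, 1),
                     tolerance = 1e-12)

    # lambda below 1: records untouched
    shrunk <- rec; shrunk$CHISQ <- 0.5 * rec$CHISQ; shrunk$Z <- sqrt(0.5) * rec$Z
    out3 <- genomicControl(shrunk)
    expect_lt(out3$lambda, 1)
    expect_identical(out3$records$CHISQ, shrunk$CHISQ)

    none <- rec; none$CHISQ <- NA_real_
    expect_error(genomicControl(none), "no testable")
    expect_warning(genomicControl(rec[1:20, ]), "fewer than 100")
})

test_that("lambda_1000 scaling matches the reference formula", {
    expect_equal(round(lambda1000(1.05, 10210, 12285), 2), 1.00)
    expect_equal(lambda1000(1, 123, 4567), 1)
    expect_equal(lambda1000(1.10, 1000, 1000), 1.10, tolerance = 1e-12)
    expect_error(lambda1000(1.05, 0, 10), "positive")
})

test_that("Benjamini-Hochberg step-up returns flags and the equivalent p threshold", {
    out <- bhFdr(c(0.001, 0.02, 0.04, 0.9), q = 0.05)
    expect_equal(out$nRejected, 2L)
    expect_equal(out$threshold, 0.02)
    expect_equal(out$reject, c(TRUE, TRUE, FALSE, FALSE))

    expect_equal(bhFdr(rep(1, 10))$nRejected, 0L)
    expect_true(bhFdr(0.01, 0.05)$reject)
    expect_error(bhFdr(numeric(0)), "empty")
    expect_error(bhFdr(c(0.5, 1.5)), "in \\(0, 1\\]")
})

test_that("cohort scan emits internally consistent records on both paths", {
    model <- svsModel()
    cfg <- simConfig(nCases = 150, nControls = 150, M = 12, blockSize = 4,
                     gamma = 0.4, caseAgeWeight = 0)
    co <- addPosteriorLiability(simulateCohort(cfg, model, seed = 31), model)
    fast <- scanAssociation(co, "liability")
    # slow per-SNP path must agree exactly with the vectorised path
    ph <- phenotypes(co)
    for (j in c(1L, 6L, 12L)) {
        rec <- liabilityScoreTest(dosages(co)[j, ], ph$posterior)
        expect_equal(fast$CHISQ[j], rec$CHISQ, tolerance = 1e-12)
        expect_equal(fast$Z[j], rec$Z, tolerance = 1e-12)
    }
    ok <- is.finite(fast$CHISQ)
    expect_equal(fast$CHISQ[ok], fast$Z[ok]^2, tolerance = 1e-10)
    expect_equal(fast$P[ok], pchisq(fast$CHISQ[ok], 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_true(all(fast$P[ok] > 0 & fast$P[ok] <= 1))
    logi <- scanAssociation(co, "logistic")
    okl <- is.finite(logi$CHISQ)
    expect_equal(logi$CHISQ[okl], logi$Z[okl]^2, tolerance = 1e-10)
})

test_that("quartile analysis splits cases by onset age and meta-analyses", {
    model <- svsModel()
    cfg <- simConfig(nCases = 400, nControls = 400, M = 4, blockSize = 1,
                     gamma = 0.5, caseAgeWeight = 0.08)
    co <- simulateCohort(cfg, model, seed = 77)
    snp <- S4Vectors::metadata(co)$truth$causalSnp
    one <- quartileAnalysis(co, snp)
    expect_equal(nrow(one), 4L)
    expect_true(all(one$nCohorts == 1L))
    # single cohort: meta equals the cohort's own logistic fit (quartile 1)
    ph <- phenotypes(co)
    caseAge <- ph$age[ph$status == 1]
    br <- quantile(caseAge, c(0.25, 0.5, 0.75), type = 7)
    use <- ph$status == 0 | (ph$status == 1 & ph$age <= br[1])
    ref <- logisticAssoc(dosages(co)[match(snp, snpInfo(co)$SNP), use],
                         ph$status[use])
    expect_equal(one$beta[1], ref$BETA, tolerance = 1e-10)
    expect_equal(one$se[1], ref$SE, tolerance = 1e-10)
    expect_true(all(one$lo <= one$OR & one$OR <= one$hi))

    # a cohort without case ages is skipped with a message
    co2 <- co
    cd <- SummarizedExperiment::colData(co2)
    cd$age[cd$status == 1] <- NA
    SummarizedExperiment::colData(co2) <- cd
    expect_message(two <- quartileAnalysis(list(co, co2), snp), "skipped")
    expect_equal(two$nCohorts, one$nCohorts)
})

test_that("allele harmonization flips, complements, and drops ambiguity", {
    ref <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4"),
                      EA = c("A", "A", "A", "A"),
                      OA = c("G", "G", "T", "T"),
                      EAF = c(0.3, 0.3, 0.2, 0.2))
    st <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4"),
                     EA = c("G", "T", "T", "A"),
                     OA = c("A", "C", "A", "T"),
                     EAF = c(0.7, 0.68, 0.82, 0.5),
                     Z = c(2, -1.5, 3, 1), BETA = c(0.2, -0.1, 0.3, 0.1))
    out <- suppressWarnings(harmonizeAlleles(st, ref))
    # rs1: swapped alleles -> sign flip
    expect_equal(out$Z[out$SNP == "rs1"], -2)
    expect_equal(out$EAF[out$SNP == "rs1"], 0.3)
    # rs2: strand complement T/C -> A/G, same orientation
    expect_equal(out$Z[out$SNP == "rs2"], -1.5)
    # rs3: A/T ambiguous but frequencies disambiguate (flip)
    expect_equal(out$Z[out$SNP == "rs3"], -3)
    # rs4: ambiguous at EAF 0.5 -> dropped
    expect_false("rs4" %in% out$SNP)
    expect_warning(harmonizeAlleles(st, ref), "ambiguous")
})
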