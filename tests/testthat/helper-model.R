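# Shared fixtures: calibrated models and small deterministic cohorts.

isModel <- function() {
    calibrateLiability(list(defaultRiskSchedule("female"),
                            defaultRiskSchedule("male")))
}

svsModel <- function() {
    calibrateLiability(list(defaultRiskSchedule("female", 0.2),
                            defaultRiskSchedule("male", 0.2)))
}

# Independent quadrature oracle for the truncated-normal posterior mean:
# E(eps | case) over (tau, Inf), E(eps | control) over (-Inf, tau).
# The substitution eps = tau +/- x removes the common factor phi(tau), so
# the integrand stays well scaled even deep in the tails.
quadPosterior <- function(tau, status) {
    if (status == 1) {
        f <- function(x) exp(-tau * x - x^2 / 2)
        tau + integrate(function(x) x * f(x), 0, Inf,
                        rel.tol = 1e-12)$value /
              integrate(f, 0, Inf, rel.tol = 1e-12)$value
    } else {
        f <- function(x) exp(tau * x - x^2 / 2)
        tau - integrate(function(x) x * f(x), 0, Inf,
                        rel.tol = 1e-12)$value /
              integrate(f, 0, Inf, rel.tol = 1e-12)$value
    }
}

# Minimal cohort built by hand (no simulation) for interface tests.
toyCohort <- function(nSnp = 4L, nSample = 12L, seed = 7) {
    set.seed(seed)
    d <- matrix(rbinom(nSnp * nSample, 2L, 0.3), nrow = nSnp)
    info <- data.frame(SNP = paste0("rs", seq_len(nSnp)), CHR = "1",
                       BP = seq_len(nSnp) * 10000L, EA = "A", OA = "G",
                       EAF = rowMeans(d) / 2, INFO = 0.95,
                       stringsAsFactors = FALSE)
    ph <- data.frame(sample_id = sprintf("S%02d", seq_len(nSample)),
                     status = rep(c(1L, 0L), length.out = nSample),
                     age = round(runif(nSample, 45, 80)),
                     sex = rep(c("female", "male"), length.out = nSample),
                     stringsAsFactors = FALSE)
    GwasCohort(d, info, ph)
}

# Brute-force five-hypothesis colocalization oracle: enumerate all
# configurations (none, each single SNP per trait, every ordered pair).
enumColoc <- function(l1, l2, p1, p2, p12) {
    M <- length(l1)
    b1 <- exp(l1); b2 <- exp(l2)
    h0 <- 1
    h1 <- p1 * sum(b1)
    h2 <- p2 * sum(b2)
    h3 <- 0
    for (j in seq_len(M)) for (k in seq_len(M))
        if (j != k) h3 <- h3 + p1 * p2 * b1[j] * b2[k]
    h4 <- p12 * sum(b1 * b2)
    u <- c(h0, h1, h2, h3, h4)
    setNames(u / sum(u), paste0("PP", 0:4))
}

# Summary-stats frame for coloc tests.
colocStats <- function(z, n = 5000L, eaf = 0.3, bp = NULL) {
    M <- length(z)
    data.frame(SNP = paste0("rs", seq_len(M)), CHR = "1",
               BP = if (is.null(bp)) seq_len(M) * 1000L else bp,
               EA = "A", OA = "G", EAF = rep_len(eaf, M), INFO = 1,
               N = n, Z = z, CHISQ = z^2, P = pchisq(z^2, 1, lower.tail = FALSE),
               BETA = NA_real_, SE = NA_real_, ANALYSIS = "liability",
               stringsAsFactors = FALSE)
}
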