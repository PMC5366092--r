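#' Wakefield log approximate Bayes factor
#'
#' For an estimate with Z score \eqn{z} and sampling variance \eqn{v},
#' against a normal effect prior with variance \eqn{w}:
#' \deqn{\log ABF = \tfrac12 \log\frac{v}{v+w} +
#'   \tfrac12 z^2 \frac{w}{v+w}.}
#' Symmetric in the sign of \eqn{z}; tends to 0 as \eqn{w \to 0} and is
#' negative (evidence for the null) at \eqn{z = 0}.
#'
#' @param z Z score(s).
#' @param v Sampling variance(s) of the effect estimate (> 0).
#' @param w Prior effect variance (> 0).
#'
#' @return log ABF (vectorised).
#' @examples
#' wakefieldLogABF(5, 0.01, 0.15^2)
#' @export
wakefieldLogABF <- function(z, v, w) {
    if (any(v <= 0) || any(w <= 0))
        stop("variances must be positive")
    0.5 * log(v / (v + w)) + 0.5 * z^2 * w / (v + w)
}

.colocVariance <- function(stats, type, caseFraction = 0.5) {
    # sampling variance of the per-SNP effect: se^2 when given, otherwise
    # the 1 / (2 f (1-f) N) approximation (times 1/(s(1-s)) for
    # case-control), flagged as approximate
    if (all(c("BETA", "SE") %in% colnames(stats)) &&
        all(is.finite(stats$SE)) && all(stats$SE > 0))
        return(list(v = stats$SE^2, approx = FALSE))
    f <- stats$EAF
    if (any(!is.finite(f) | f <= 0 | f >= 1))
        stop("EAF needed to approximate sampling variances")
    v <- 1 / (2 * f * (1 - f) * stats$N)
    if (type == "cc") v <- v / (caseFraction * (1 - caseFraction))
    list(v = v, approx = TRUE)
}

#' Bayesian colocalization of two association signals
#'
#' Per-SNP Wakefield log approximate Bayes factors are computed for both
#' traits over the SNPs shared by the two summary-statistics sets (within
#' an optional window around a lead SNP), and combined into posterior
#' probabilities of the five hypotheses: H0 neither trait associated, H1
#' trait 1 only, H2 trait 2 only, H3 both traits, two distinct causal
#' SNPs, H4 both traits, one shared causal SNP.  All sums over SNP
#' configurations use log-sum-exp arithmetic.
#'
#' @param stats1,stats2 Summary statistics for trait 1 (disease) and
#'   trait 2 (molecular), association-module format; columns \code{SNP},
#'   \code{Z}, \code{N}, \code{EAF} and ideally \code{BETA}/\code{SE}
#'   (otherwise sampling variances are approximated from frequency and N).
#' @param type1,type2 Trait types, \code{"cc"} (case-control) or
#'   \code{"quant"}.
#' @param p1,p2,p12 Per-SNP prior probabilities that a SNP is associated
#'   with trait 1 only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param w1,w2 Prior effect variances; default \eqn{0.15^2} for
#'   case-control and \eqn{0.2^2} for quantitative traits.
#' @param leadSnp,windowKb Optional window restriction: keep SNPs within
#'   \code{windowKb} kb of \code{leadSnp} (positions from \code{BP};
#'   default window 50 kb, inclusive on both ends).
#' @param caseFraction Case fraction used in the case-control variance
#'   approximation.
#'
#' @return A [ColocResult-class].
#' @export
colocPosterior <- function(stats1, stats2, type1 = "cc", type2 = "quant",
                           p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                           w1 = NULL, w2 = NULL,
                           leadSnp = NULL, windowKb = 50,
                           caseFraction = 0.5) {
    if (p1 <= 0 || p2 <= 0 || p12 <= 0 || p1 + p2 + p12 >= 1)
        stop("priors must be positive with p1 + p2 + p12 < 1")
    shared <- intersect(stats1$SNP, stats2$SNP)
    if (!is.null(leadSnp)) {
        if (!leadSnp %in% stats1$SNP)
            stop("lead SNP not present in stats1")
        bp0 <- stats1$BP[match(leadSnp, stats1$SNP)]
        inWin <- stats1$SNP[abs(stats1$BP - bp0) <= windowKb * 1000]
        shared <- intersect(shared, inWin)
    }
    if (!length(shared)) stop("no shared SNPs in the window")
    s1 <- stats1[match(shared, stats1$SNP), , drop = FALSE]
    s2 <- stats2[match(shared, stats2$SNP), , drop = FALSE]
    if (is.null(w1)) w1 <- if (type1 == "cc") 0.15^2 else 0.2^2
    if (is.null(w2)) w2 <- if (type2 == "cc") 0.15^2 else 0.2^2
    v1 <- .colocVariance(s1, type1, caseFraction)
    v2 <- .colocVariance(s2, type2, caseFraction)
    l1 <- wakefieldLogABF(s1$Z, v1$v, w1)
    l2 <- wakefieldLogABF(s2$Z, v2$v, w2)
    pp <- .colocCombine(l1, l2, p1, p2, p12)
    new("ColocResult", nsnps = length(shared), postProb = pp,
        priors = c(p1 = p1, p2 = p2, p12 = p12),
        summary = data.frame(SNP = shared, lABF1 = l1, lABF2 = l2,
                             approx1 = v1$approx, approx2 = v2$approx,
                             stringsAsFactors = FALSE))
}

# Combine per-SNP log ABFs into PP0..PP4 using log-sum-exp throughout.
.colocCombine <- function(l1, l2, p1, p2, p12) {
    S1 <- logSumExp(l1)
    S2 <- logSumExp(l2)
    S4 <- logSumExp(l1 + l2)
    S12 <- S1 + S2
    # sum over ordered pairs (j, k), j != k: exp(S1)exp(S2) - exp(S4);
    # exactly empty (PP3 = 0) when only one SNP is in the window
    S3 <- if (length(l1) == 1L || S4 >= S12) -Inf
          else S12 + log1p(-exp(S4 - S12))
    lpost <- c(0,
               log(p1) + S1,
               log(p2) + S2,
               log(p1) + log(p2) + S3,
               log(p12) + S4)
    pp <- exp(lpost - logSumExp(lpost))
    names(pp) <- paste0("PP", 0:4)
    pp / sum(pp)
}
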