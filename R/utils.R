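# Internal numerical helpers.

# log(sum(exp(x))) without overflow; -Inf-safe.
logSumExp <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(-Inf)
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# Upper-tail Mills ratio phi(tau) / (1 - Phi(tau)), evaluated on the log
# scale so it stays finite far into the tail (|tau| up to ~38 and beyond).
millsUpper <- function(tau) {
    exp(dnorm(tau, log = TRUE) -
        pnorm(tau, lower.tail = FALSE, log.p = TRUE))
}

# Lower-tail analogue phi(tau) / Phi(tau).
millsLower <- function(tau) {
    exp(dnorm(tau, log = TRUE) - pnorm(tau, log.p = TRUE))
}

# Two-sided p from a signed Z, via the 1-df chi-square upper tail.
chisqP <- function(chisq) {
    pchisq(chisq, df = 1L, lower.tail = FALSE)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. seed = NULL uses (and advances) the global stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!is.finite(seed)) stop("'seed' must be a finite integer")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Principal-component covariate columns of a phenotype table.
pcColumns <- function(pheno) {
    grep("^PC[0-9]+$", colnames(pheno), value = TRUE)
}

# Covariate matrix (possibly NULL) from a phenotype table's PC columns.
pcMatrix <- function(pheno) {
    pcs <- pcColumns(pheno)
    if (!length(pcs)) return(NULL)
    as.matrix(pheno[, pcs, drop = FALSE])
}

# Empty association record with the canonical summary-statistics columns.
emptyAssocFrame <- function(n = 0L) {
    data.frame(SNP = character(n), CHR = character(n), BP = integer(n),
               EA = character(n), OA = character(n), EAF = numeric(n),
               INFO = numeric(n), N = integer(n), Z = numeric(n),
               CHISQ = numeric(n), P = numeric(n), BETA = numeric(n),
               SE = numeric(n), ANALYSIS = character(n),
               stringsAsFactors = FALSE)
}
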