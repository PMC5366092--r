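#' Built-in ischemic stroke risk schedules
#'
#' Sex-specific population-based cumulative risks of ischemic stroke from an
#' index age of 55: 1.8\%, 5.4\% and 12.1\% before ages 65, 75 and 85 in
#' women; 2.4\%, 7.3\% and 12.6\% in men.  For a stroke subtype analysis the
#' whole-disease schedule is scaled by the fraction of cases with that
#' subtype (conventionally 0.20 for each of the cardioembolic, large-artery
#' and small-vessel subtypes).
#'
#' @param sex \code{"female"} or \code{"male"}.
#' @param subtypeFraction Fraction of cases with the analysed subtype,
#'   in (0, 1]; 1 analyses all ischemic stroke.
#'
#' @return A [RiskSchedule-class].
#' @examples
#' defaultRiskSchedule("female")                    # all ischemic stroke
#' defaultRiskSchedule("male", subtypeFraction = 0.2)  # one subtype
#' @export
defaultRiskSchedule <- function(sex = c("female", "male"),
                                subtypeFraction = 1) {
    sex <- match.arg(sex)
    risks <- switch(sex,
        female = c(0.018, 0.054, 0.121),
        male   = c(0.024, 0.073, 0.126))
    RiskSchedule(sex, ages = c(65, 75, 85), risks = risks, indexAge = 55,
                 subtypeFraction = subtypeFraction)
}

#' Read risk schedules from a TSV file
#'
#' Expects columns \code{sex}, \code{age}, \code{risk} and optionally
#' \code{index_age} and \code{subtype_fraction} (constant within sex).
#'
#' @param path Path to a tab-separated file.
#' @return Named list of [RiskSchedule-class] objects, one per sex.
#' @export
readRiskSchedule <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sex", "age", "risk")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("risk schedule file lacks column(s): ",
             paste(miss, collapse = ", "))
    out <- lapply(split(tab, tab$sex), function(d) {
        d <- d[order(d$age), , drop = FALSE]
        RiskSchedule(d$sex[1], ages = d$age, risks = d$risk,
            indexAge = if ("index_age" %in% colnames(d)) d$index_age[1] else 55,
            subtypeFraction = if ("subtype_fraction" %in% colnames(d))
                d$subtype_fraction[1] else 1)
    })
    out[order(names(out))]
}

#' Calibrate the liability threshold model from risk schedules
#'
#' Each cumulative risk \eqn{R_k} at age \eqn{a_k} is scaled by the subtype
#' fraction \eqn{s} and probit-transformed, \eqn{y_k = \Phi^{-1}(s R_k)};
#' ordinary least squares of \eqn{y_k} on age gives the per-year liability
#' slope \eqn{c} and, evaluated at the index age \eqn{\bar t}, the offset
#' \eqn{m}, so that the implied prevalence
#' \eqn{P(case|t) = \Phi(c (t - \bar t) + m)} reproduces the scaled
#' schedule up to the fit's residuals (exactly when the probit-transformed
#' schedule is collinear in age).  The case threshold on the residual
#' liability scale is \eqn{\tau(t) = -c (t - \bar t) - m}.
#'
#' @param schedules A single [RiskSchedule-class] or a (possibly named) list
#'   of them, one per sex.  All must share the same index age.
#'
#' @return A [LiabilityModel-class] with per-sex slope and offset.
#' @examples
#' calibrateLiability(defaultRiskSchedule("female"))
#' calibrateLiability(list(defaultRiskSchedule("female", 0.2),
#'                         defaultRiskSchedule("male", 0.2)))
#' @export
calibrateLiability <- function(schedules) {
    if (is(schedules, "RiskSchedule")) schedules <- list(schedules)
    if (!length(schedules) || !all(vapply(schedules, is, TRUE, "RiskSchedule")))
        stop("'schedules' must be RiskSchedule objects")
    for (s in schedules) validObject(s)
    ref <- vapply(schedules, function(s) s@indexAge, numeric(1))
    if (length(unique(ref)) != 1L)
        stop("all schedules must share the same index age")
    slope <- offset <- numeric(0)
    fits <- list()
    for (s in schedules) {
        scaled <- s@subtypeFraction * s@risks
        if (any(scaled >= 1))
            stop("scaled risk reaches 1; schedule not usable on probit scale")
        y <- qnorm(scaled)
        ctr <- s@ages - s@indexAge
        fit <- lm(y ~ ctr)
        cf <- coef(fit)
        slope[s@sex] <- unname(cf[2])
        offset[s@sex] <- unname(cf[1])
        fits[[s@sex]] <- data.frame(
            age = s@ages, risk = scaled, probit = y,
            fitted = fitted(fit), residual = residuals(fit))
    }
    new("LiabilityModel", slope = slope, offset = offset,
        referenceAge = ref[1], fit = fits)
}

.modelSex <- function(model, sex, n) {
    sexes <- names(model@slope)
    if (is.null(sex)) sex <- rep(NA_character_, n)
    sex <- as.character(sex)
    if (length(sex) == 1L) sex <- rep(sex, n)
    bad <- !is.na(sex) & !(sex %in% sexes)
    if (any(bad))
        stop("unknown sex label(s): ", paste(unique(sex[bad]), collapse = ", "))
    sex
}

#' Liability threshold at given ages
#'
#' \eqn{\tau(t) = -c (t - \bar t) - m}: the residual-liability cutoff above
#' which an individual of age \eqn{t} is a case.  Individuals with missing
#' or unrecorded sex get the average of the per-sex thresholds.
#'
#' @param model A [LiabilityModel-class].
#' @param age Ages in years (vectorised).
#' @param sex Optional sex labels matching the calibrated sexes; \code{NA}
#'   or \code{NULL} averages across sexes.
#'
#' @return Numeric vector of thresholds.
#' @export
liabilityThreshold <- function(model, age, sex = NULL) {
    stopifnot(is(model, "LiabilityModel"))
    if (any(!is.finite(age)))
        stop("non-finite age passed to liabilityThreshold()")
    sex <- .modelSex(model, sex, length(age))
    tauFor <- function(s, t) -model@slope[[s]] * (t - model@referenceAge) -
        model@offset[[s]]
    out <- numeric(length(age))
    for (s in names(model@slope)) {
        i <- !is.na(sex) & sex == s
        if (any(i)) out[i] <- tauFor(s, age[i])
    }
    unk <- is.na(sex)
    if (any(unk)) {
        # sex unrecorded: average of the per-sex thresholds
        avg <- vapply(names(model@slope), function(s) tauFor(s, age[unk]),
                      numeric(sum(unk)))
        out[unk] <- if (is.matrix(avg)) rowMeans(avg) else mean(avg)
    }
    unname(out)
}

#' Implied prevalence at given ages
#'
#' @inheritParams liabilityThreshold
#' @return \eqn{P(case | t) = 1 - \Phi(\tau(t))}.
#' @export
caseProbability <- function(model, age, sex = NULL) {
    pnorm(liabilityThreshold(model, age, sex), lower.tail = FALSE)
}

#' Posterior mean residual liability given status and threshold
#'
#' For a case (status 1) the residual liability is standard normal truncated
#' below at \eqn{\tau}, with mean \eqn{\phi(\tau) / (1 - \Phi(\tau))} (the
#' inverse Mills ratio); for a control (status 0) it is truncated above at
#' \eqn{\tau}, with mean \eqn{-\phi(\tau) / \Phi(\tau)}.  Both are computed
#' through log-scale Mills ratios and stay finite for \eqn{|\tau|} well
#' beyond 38.
#'
#' @param tau Liability threshold(s).
#' @param status 0/1 control/case indicator(s), recycled against `tau`.
#'
#' @return Numeric vector of posterior mean liabilities.
#' @examples
#' posteriorMeanFromThreshold(0, 1)    # sqrt(2/pi), the half-normal mean
#' posteriorMeanFromThreshold(2, 1)    # ~2.3732
#' posteriorMeanFromThreshold(-1, 0)   # ~-1.5251
#' @export
posteriorMeanFromThreshold <- function(tau, status) {
    if (any(!is.finite(tau)))
        stop("non-finite threshold in posteriorMeanFromThreshold()")
    if (!all(status %in% c(0, 1)))
        stop("'status' must be 0 or 1")
    n <- max(length(tau), length(status))
    tau <- rep_len(tau, n)
    status <- rep_len(status, n)
    out <- numeric(n)
    cs <- status == 1
    out[cs] <- millsUpper(tau[cs])
    out[!cs] <- -millsLower(tau[!cs])
    out
}

#' Posterior mean liabilities for individuals
#'
#' Combines [liabilityThreshold()] and [posteriorMeanFromThreshold()]:
#' each individual's case/control status and age (age-at-onset for cases,
#' age-at-observation for controls) is converted to the expected residual
#' liability under the calibrated threshold model.  Younger cases take
#' larger positive values than older cases; older stroke-free controls take
#' more negative values than younger controls.
#'
#' @param model A [LiabilityModel-class].
#' @param status 0/1 vector.
#' @param age Ages in years.
#' @param sex Optional sex labels (see [liabilityThreshold()]).
#'
#' @return Numeric vector of posterior mean liabilities.
#' @export
posteriorMeanLiability <- function(model, status, age, sex = NULL) {
    tau <- liabilityThreshold(model, age, sex)
    posteriorMeanFromThreshold(tau, status)
}

#' Median-impute missing ages within status groups
#'
#' Missing ages are replaced by the median observed age of the same status
#' group (cases' median for cases, controls' for controls) within the
#' cohort.
#'
#' @param age Numeric vector, \code{NA} for missing.
#' @param status 0/1 vector of the same length.
#'
#' @return List with \code{age} (completed vector) and \code{nImputed}.
#' @examples
#' imputeMissingAge(c(60, NA, 70), c(1, 1, 1))
#' @export
imputeMissingAge <- function(age, status) {
    stopifnot(length(age) == length(status))
    if (!all(status %in% c(0, 1)))
        stop("'status' must be 0 or 1")
    nImp <- 0L
    for (g in unique(status)) {
        idx <- status == g
        missing <- idx & is.na(age)
        if (!any(missing)) next
        obs <- age[idx & !is.na(age)]
        if (!length(obs))
            stop("all ages missing in status group ", g,
                 "; cannot median-impute")
        age[missing] <- median(obs)
        nImp <- nImp + sum(missing)
    }
    list(age = age, nImputed = nImp)
}

#' Attach posterior mean liabilities to a cohort
#'
#' Convenience wrapper: median-imputes missing ages within status groups,
#' evaluates the posterior mean liability for every sample, and returns the
#' cohort with a \code{posterior} column added to its phenotype table.
#'
#' @param cohort A [GwasCohort-class].
#' @param model A [LiabilityModel-class].
#'
#' @return The cohort with \code{phenotypes(cohort)$posterior} filled in;
#'   the number of imputed ages is recorded in
#'   \code{metadata(cohort)$nAgesImputed}.
#' @export
addPosteriorLiability <- function(cohort, model) {
    ph <- phenotypes(cohort)
    imp <- imputeMissingAge(ph$age, ph$status)
    sex <- if ("sex" %in% colnames(ph)) ph$sex else NULL
    post <- posteriorMeanLiability(model, ph$status, imp$age, sex)
    SummarizedExperiment::colData(cohort)$posterior <- post
    S4Vectors::metadata(cohort)$nAgesImputed <- imp$nImputed
    cohort
}
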