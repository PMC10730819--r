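.CI_Z <- 1.96  # fixed normal multiplier for all 95% intervals

# Run expr with a temporary RNG state seeded by `seed`; restores the caller's
# state so package functions never perturb the session RNG.
.withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("an explicit integer seed is required")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Shared MREstimate assembly: normal CI at +/-1.96, p from the reference
# distribution (normal unless df given, then t), OR scale populated.
.mrEstimate <- function(method, beta, se, nSNPs, df = NULL) {
    if (!is.finite(se) || se <= 0) stop("estimate se must be > 0")
    z <- beta / se
    pval <- if (is.null(df)) 2 * stats::pnorm(-abs(z))
            else 2 * stats::pt(-abs(z), df = df)
    new("MREstimate", method = method, beta = beta, se = se,
        ciLow = beta - .CI_Z * se, ciHigh = beta + .CI_Z * se,
        pval = pval, nSNPs = as.integer(nSNPs),
        orValue = exp(beta), orCiLow = exp(beta - .CI_Z * se),
        orCiHigh = exp(beta + .CI_Z * se), scale = "beta")
}

.checkHarmonized <- function(h) {
    if (!is(h, "HarmonizedSet")) stop("expected a HarmonizedSet")
    h
}

#' Wald ratio causal estimate from one SNP
#'
#' The per-SNP causal estimate beta_outcome / beta_exposure with the
#' first-order delta-method standard error se_outcome / |beta_exposure|
#' (the uncertainty in the exposure association is ignored, the standard
#' approximation when instruments are strong).
#'
#' @param betaOut,seOut SNP-outcome effect and its SE.
#' @param betaExp SNP-exposure effect; must be non-zero.
#' @return an [MREstimate-class] with method "wald".
#' @examples
#' waldRatio(0.05, 0.01, 0.10)  # beta 0.5, se 0.1
#' @export
waldRatio <- function(betaOut, seOut, betaExp) {
    if (!is.finite(betaExp) || betaExp == 0)
        stop("degenerate instrument: beta_exposure must be non-zero")
    .mrEstimate("wald", betaOut / betaExp, seOut / abs(betaExp), 1L)
}

#' Inverse-variance-weighted (IVW) causal estimate
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights 1/se_outcome^2 — algebraically the
#' inverse-variance-weighted mean of the per-SNP Wald ratios. In
#' `"fixed"` mode the SE is the weighted-least-squares one; in `"mre"`
#' (multiplicative random effects) it is inflated by the residual scale,
#' floored at 1, to absorb between-SNP heterogeneity. The default picks
#' `"mre"` for 4 or more SNPs and `"fixed"` below that.
#'
#' @param h a [HarmonizedSet-class].
#' @param mode "default", "fixed" or "mre". Fixed needs >= 1 SNP,
#'   multiplicative random effects >= 2.
#' @return an [MREstimate-class] with method "ivw_fixed" or "ivw_mre".
#' @export
mrIVW <- function(h, mode = c("default", "fixed", "mre")) {
    mode <- match.arg(mode)
    .checkHarmonized(h)
    x <- h@betaExposure; y <- h@betaOutcome; w <- 1 / h@seOutcome^2
    J <- length(x)
    if (all(x == 0)) stop("degenerate: all beta_exposure are zero")
    if (mode == "default") mode <- if (J >= 4L) "mre" else "fixed"
    if (mode == "mre" && J < 2L)
        stop("multiplicative random effects needs >= 2 SNPs")
    sxx <- sum(w * x^2)
    beta <- sum(w * x * y) / sxx
    se <- sqrt(1 / sxx)
    if (mode == "mre") {
        sigma2 <- sum(w * (y - beta * x)^2) / (J - 1L)
        se <- se * max(1, sqrt(sigma2))
    }
    .mrEstimate(if (mode == "mre") "ivw_mre" else "ivw_fixed", beta, se, J)
}

# weighted median of values r with weights w: linear interpolation of the
# standardized mid-point cumulative weight function at 0.5
.weightedMedianPoint <- function(r, w) {
    ord <- order(r)
    r <- r[ord]; w <- w[ord]
    s <- (cumsum(w) - w / 2) / sum(w)
    stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' Orders the per-SNP Wald ratios and returns the value at cumulative
#' inverse-variance weight 0.5 (linear interpolation of the mid-point
#' cumulative weight function). Consistent when at least half the weight
#' comes from valid instruments, so it tolerates a minority of pleiotropic
#' SNPs that would bias IVW. The standard error comes from a parametric
#' bootstrap: exposure and outcome effects are redrawn from their sampling
#' distributions and the estimator recomputed.
#'
#' @param h a [HarmonizedSet-class] with >= 3 SNPs.
#' @param nBoot bootstrap resamples for the SE (default 1000).
#' @param seed mandatory integer seed for the bootstrap.
#' @return an [MREstimate-class] with method "weighted_median".
#' @export
weightedMedian <- function(h, nBoot = 1000L, seed) {
    .checkHarmonized(h)
    J <- length(h@snpIds)
    if (J < 3L) stop("insufficient instruments: weighted median needs >= 3")
    if (missing(seed)) stop("an explicit integer seed is required")
    if (any(h@betaExposure == 0))
        stop("degenerate instrument: beta_exposure must be non-zero")
    ratio <- h@betaOutcome / h@betaExposure
    wse <- h@seOutcome / abs(h@betaExposure)
    beta <- .weightedMedianPoint(ratio, 1 / wse^2)
    boot <- .withSeed(seed, {
        vapply(seq_len(nBoot), function(b) {
            bx <- stats::rnorm(J, h@betaExposure, h@seExposure)
            by <- stats::rnorm(J, h@betaOutcome, h@seOutcome)
            ok <- bx != 0
            .weightedMedianPoint(by[ok] / bx[ok],
                                 (abs(bx[ok]) / h@seOutcome[ok])^2)
        }, numeric(1))
    })
    .mrEstimate("weighted_median", beta, stats::sd(boot), J)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept (weights 1/se_outcome^2), after orienting every SNP
#' so its exposure effect is non-negative. The slope estimates the causal
#' effect allowing all instruments a pleiotropic effect, provided pleiotropy
#' is independent of instrument strength (the InSIDE assumption); the
#' intercept estimates the average directional pleiotropy, and its two-sided
#' test (t with J-2 df) is the pleiotropy test. Residual overdispersion is
#' absorbed multiplicatively, floored at 1.
#'
#' @param h a [HarmonizedSet-class] with >= 3 SNPs.
#' @param forceNullIntercept fit through the origin instead (the nested
#'   model: identical to fixed-effect IVW's point estimate); intended for
#'   model comparison.
#' @return an [EggerResult-class].
#' @export
mrEgger <- function(h, forceNullIntercept = FALSE) {
    .checkHarmonized(h)
    J <- length(h@snpIds)
    if (J < 3L) stop("insufficient instruments: MR-Egger needs >= 3")
    s <- ifelse(h@betaExposure < 0, -1, 1)
    x <- abs(h@betaExposure); y <- s * h@betaOutcome
    w <- 1 / h@seOutcome^2
    if (stats::var(x) == 0)
        stop("collinearity: no variance in beta_exposure")
    if (forceNullIntercept) {
        fit <- stats::lm(y ~ 0 + x, weights = w)
        df <- J - 1L
        co <- stats::coef(fit)
        V <- 1 / sum(w * x^2)
        sigma2 <- sum(w * stats::resid(fit)^2) / df
        se <- sqrt(V) * max(1, sqrt(sigma2))
        slope <- .mrEstimate("egger_slope", unname(co[["x"]]), se, J, df = df)
        return(new("EggerResult", slope = slope, intercept = 0,
                   interceptSE = NA_real_, interceptPval = 1))
    }
    fit <- stats::lm(y ~ x, weights = w)
    df <- J - 2L
    co <- stats::coef(fit)
    XtWX <- crossprod(sqrt(w) * cbind(1, x))
    V <- solve(XtWX)
    sigma2 <- sum(w * stats::resid(fit)^2) / df
    infl <- max(1, sqrt(sigma2))
    seSlope <- sqrt(V[2L, 2L]) * infl
    seInt <- sqrt(V[1L, 1L]) * infl
    slope <- .mrEstimate("egger_slope", unname(co[["x"]]), seSlope, J,
                         df = df)
    int <- unname(co[["(Intercept)"]])
    new("EggerResult", slope = slope, intercept = int, interceptSE = seInt,
        interceptPval = 2 * stats::pt(-abs(int / seInt), df = df))
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' @param beta log-odds effect estimate(s).
#' @param se standard error(s), > 0.
#' @return data.frame with columns or, ci_low, ci_high: exp(beta) and
#'   exp(beta +/- 1.96 se).
#' @examples
#' toOddsRatio(log(2), 0.1)
#' @export
toOddsRatio <- function(beta, se) {
    if (any(!is.finite(se)) || any(se <= 0)) stop("se must be > 0")
    data.frame(or = exp(beta), ci_low = exp(beta - .CI_Z * se),
               ci_high = exp(beta + .CI_Z * se))
}

#' Run all univariable estimators on one harmonized pair
#'
#' Convenience wrapper producing the standard results table: IVW (default
#' mode), weighted median (when >= 3 SNPs) and the MR-Egger slope and
#' intercept (when >= 3 SNPs), one row per method.
#'
#' @param h a [HarmonizedSet-class].
#' @param seed seed for the weighted-median bootstrap.
#' @param nBoot bootstrap resamples (default 1000).
#' @return data.frame in the results-table dialect (method, beta, se,
#'   ci_low, ci_high, pval, n_snps, or columns; the Egger intercept row
#'   reports the intercept in the beta column with method
#'   "egger_intercept").
#' @export
mrAllMethods <- function(h, seed, nBoot = 1000L) {
    .checkHarmonized(h)
    rows <- list(as.data.frame(mrIVW(h)))
    if (length(h@snpIds) >= 3L) {
        rows <- c(rows, list(as.data.frame(weightedMedian(h, nBoot = nBoot,
                                                          seed = seed))))
        eg <- mrEgger(h)
        rows <- c(rows, list(as.data.frame(eg@slope)))
        rows <- c(rows, list(data.frame(
            method = "egger_intercept", beta = eg@intercept,
            se = eg@interceptSE,
            ci_low = eg@intercept - .CI_Z * eg@interceptSE,
            ci_high = eg@intercept + .CI_Z * eg@interceptSE,
            pval = eg@interceptPval, n_snps = eg@slope@nSNPs,
            or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
            stringsAsFactors = FALSE)))
    }
    do.call(rbind, rows)
}

#' Write a results table as TSV
#'
#' @param tab data.frame as produced by [mrAllMethods()] (or rbind of such).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(tab, path) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
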