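#' Construct an MVHarmonizedSet
#'
#' @param snpIds SNP identifiers (length J).
#' @param betaExposures,seExposures J x K matrices of SNP effects on the K
#'   exposures and their SEs; columns must be named by exposure.
#' @param betaOutcome,seOutcome per-SNP outcome effect and SE.
#' @return a validated [MVHarmonizedSet-class].
#' @export
MVHarmonizedSet <- function(snpIds, betaExposures, seExposures,
                            betaOutcome, seOutcome) {
    new("MVHarmonizedSet", snpIds = as.character(snpIds),
        betaExposures = as.matrix(betaExposures),
        seExposures = as.matrix(seExposures),
        betaOutcome = betaOutcome, seOutcome = seOutcome)
}

# Weighted no-intercept least squares of y on the K columns of X with
# weights w, multiplicative overdispersion floored at 1. Shared by the K>=2
# multivariable path and the K=1 reduction.
.mvWLS <- function(X, y, w, labels) {
    J <- nrow(X); K <- ncol(X)
    Xw <- sqrt(w) * X
    qrX <- qr(Xw)
    if (qrX$rank < K) {
        bad <- labels[qrX$pivot[(qrX$rank + 1L):K]]
        stop("collinearity: exposure-effect matrix is rank deficient (",
             paste(bad, collapse = ", "), ")")
    }
    XtWX <- crossprod(Xw)
    V <- solve(XtWX)
    beta <- drop(V %*% crossprod(X, w * y))
    resid <- y - drop(X %*% beta)
    Q <- sum(w * resid^2)
    phi <- max(1, Q / (J - K))
    se <- sqrt(diag(V) * phi)
    list(beta = beta, se = se, Q = Q, labels = labels)
}

#' Multivariable IVW: direct effects of several exposures
#'
#' Weighted least squares of the per-SNP outcome effects on the K exposure
#' effect columns, no intercept, weights 1/se_outcome^2. Each coefficient is
#' the direct causal effect of that exposure conditional on the others.
#' Standard errors come from the weighted normal equations with a
#' multiplicative overdispersion scale floored at 1 (the multivariable
#' analogue of multiplicative random-effects IVW). Per-exposure conditional
#' instrument strength is reported as the mean squared standardized residual
#' of regressing that exposure's SNP effects on the other exposures'
#' (flagging, not dropping, below 10).
#'
#' @param m an [MVHarmonizedSet-class] (or, for the K = 1 degenerate case,
#'   a [HarmonizedSet-class], in which case the result matches [mrIVW()]).
#' @return an [MVMRResult-class].
#' @export
mvmrIVW <- function(m) {
    if (is(m, "HarmonizedSet")) {
        X <- matrix(m@betaExposure, ncol = 1L,
                    dimnames = list(NULL, "exposure"))
        seX <- matrix(m@seExposure, ncol = 1L)
        y <- m@betaOutcome; w <- 1 / m@seOutcome^2
    } else {
        stopifnot(is(m, "MVHarmonizedSet"))
        X <- m@betaExposures; seX <- m@seExposures
        y <- m@betaOutcome; w <- 1 / m@seOutcome^2
    }
    J <- nrow(X); K <- ncol(X)
    if (J <= K)
        stop("under-identified: J = ", J, " SNPs for K = ", K, " exposures")
    fit <- .mvWLS(X, y, w, colnames(X))
    ests <- stats::setNames(lapply(seq_len(K), function(k)
        .mrEstimate("mvmr_ivw", unname(fit$beta[k]), unname(fit$se[k]),
                    J)), colnames(X))
    condF <- vapply(seq_len(K), function(k) {
        if (K == 1L) return(mean((X[, 1L] / seX[, 1L])^2))
        e <- stats::resid(stats::lm.fit(X[, -k, drop = FALSE], X[, k]))
        mean((e / seX[, k])^2)
    }, numeric(1))
    names(condF) <- colnames(X)
    new("MVMRResult", estimates = ests, conditionalF = condF,
        heterogeneity = fit$Q, nSNPs = as.integer(J))
}

#' Flatten an MVMRResult to a data.frame
#'
#' @param x an [MVMRResult-class].
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return data.frame with one row per exposure: exposure, beta, se, ci_low,
#'   ci_high, pval, conditional_f, n_snps.
#' @export
as.data.frame.MVMRResult <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    do.call(rbind, lapply(names(x@estimates), function(nm) {
        e <- x@estimates[[nm]]
        data.frame(exposure = nm, beta = e@beta, se = e@se,
                   ci_low = e@ciLow, ci_high = e@ciHigh, pval = e@pval,
                   conditional_f = x@conditionalF[[nm]], n_snps = e@nSNPs,
                   stringsAsFactors = FALSE)
    }))
}

setMethod("as.data.frame", "MVMRResult", as.data.frame.MVMRResult)
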