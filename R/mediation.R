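#' Indirect (mediation) effect by product of coefficients
#'
#' Combines the exposure-to-mediator effect A and the mediator-to-outcome
#' effect B into the indirect effect A*B. The standard error is the
#' first-order delta-method (Sobel) form
#' sqrt(A^2 se_B^2 + B^2 se_A^2); the second-order term se_A^2 se_B^2 can be
#' added via `secondOrder = TRUE`. CI is normal at +/-1.96, p two-sided
#' normal. Symmetric in its two arguments.
#'
#' @param aBeta,aSE effect A (exposure to mediator) and its SE.
#' @param bBeta,bSE effect B (mediator to outcome) and its SE.
#' @param secondOrder include the se_A^2 se_B^2 variance term (default
#'   FALSE, the Sobel form).
#' @return list with beta, se, ciLow, ciHigh, pval.
#' @examples
#' indirectEffect(-2.65, 0.676, -0.068, 0.0071)  # indirect 0.1802
#' @export
indirectEffect <- function(aBeta, aSE, bBeta, bSE, secondOrder = FALSE) {
    if (!is.finite(aSE) || aSE <= 0 || !is.finite(bSE) || bSE <= 0)
        stop("standard errors must be > 0")
    beta <- aBeta * bBeta
    v <- aBeta^2 * bSE^2 + bBeta^2 * aSE^2
    if (secondOrder) v <- v + aSE^2 * bSE^2
    se <- sqrt(v)
    if (se == 0) stop("degenerate: both coefficients are zero")
    list(beta = beta, se = se,
         ciLow = beta - .CI_Z * se, ciHigh = beta + .CI_Z * se,
         pval = 2 * stats::pnorm(-abs(beta / se)))
}

#' Mediated proportion of the total effect
#'
#' The indirect effect as a percentage of the total exposure-to-outcome
#' effect, reported as a magnitude: 100 * |indirect / total|, clipped to
#' [0,100]. When indirect and total effects disagree in sign the ratio is
#' still reported as a magnitude but flagged as inconsistent mediation. The
#' default CI propagates the indirect effect's normal CI through the ratio
#' at fixed total (bounds clipped to [0,100]; a ratio interval spanning zero
#' gets magnitude lower bound 0); `method = "delta"` instead uses the full
#' bivariate delta-method variance of indirect/total.
#'
#' @param indirectBeta,indirectSE indirect effect and SE.
#' @param totalBeta,totalSE total effect (non-zero) and SE (only used by
#'   the delta method).
#' @param method "ratio" (default) or "delta".
#' @return list with proportion, ciLow, ciHigh (percent, all in [0,100])
#'   and inconsistent (logical sign-discordance flag).
#' @examples
#' mediatedProportion(0.18, 0.0503, -0.57, 0.788)  # 31.6%, flagged
#' @export
mediatedProportion <- function(indirectBeta, indirectSE, totalBeta, totalSE,
                               method = c("ratio", "delta")) {
    method <- match.arg(method)
    if (!is.finite(totalBeta) || totalBeta == 0)
        stop("undefined proportion: total effect is zero")
    if (!is.finite(indirectSE) || indirectSE <= 0)
        stop("indirect se must be > 0")
    clip <- function(v) pmin(100, pmax(0, v))
    prop <- clip(100 * abs(indirectBeta / totalBeta))
    inconsistent <- indirectBeta != 0 &&
        sign(indirectBeta) != sign(totalBeta)
    if (method == "ratio") {
        r <- 100 * c(indirectBeta - .CI_Z * indirectSE,
                     indirectBeta + .CI_Z * indirectSE) / totalBeta
        lo <- min(r); hi <- max(r)
        ci <- if (lo <= 0 && hi >= 0) c(0, max(abs(lo), abs(hi)))
              else sort(abs(c(lo, hi)))
    } else {
        if (!is.finite(totalSE) || totalSE <= 0)
            stop("total se must be > 0 for the delta method")
        se <- 100 * sqrt(indirectSE^2 / totalBeta^2 +
                         indirectBeta^2 * totalSE^2 / totalBeta^4)
        p0 <- 100 * abs(indirectBeta / totalBeta)
        ci <- c(p0 - .CI_Z * se, p0 + .CI_Z * se)
    }
    ci <- clip(ci)
    list(proportion = prop, ciLow = ci[1L], ciHigh = ci[2L],
         inconsistent = inconsistent)
}

#' Two-step MR mediation analysis
#'
#' Assembles the full mediation decomposition from three MR estimates: the
#' total exposure-to-outcome effect, step 1 (exposure to mediator, effect
#' A, from the exposure's instruments) and step 2 (mediator to outcome,
#' effect B, from the mediator's own instruments). The indirect effect is
#' A*B with delta-method SE; the mediated proportion is taken against the
#' total effect. All three inputs must be on an additive (log-odds for
#' binary traits) scale — estimates tagged as odds-ratio scale are refused.
#'
#' @param step1,step2,total [MREstimate-class] objects for A, B and the
#'   total effect.
#' @param proportionMethod CI construction for the proportion, see
#'   [mediatedProportion()].
#' @param secondOrder passed to [indirectEffect()].
#' @return a [MediationResult-class]; provenance records which estimator
#'   produced each input. A sign-discordant indirect/total pair is flagged
#'   as inconsistent mediation (with a warning), not an error.
#' @export
twoStepMediation <- function(step1, step2, total,
                             proportionMethod = c("ratio", "delta"),
                             secondOrder = FALSE) {
    proportionMethod <- match.arg(proportionMethod)
    for (e in list(step1, step2, total)) {
        if (!is(e, "MREstimate")) stop("inputs must be MREstimate objects")
        if (e@scale != "beta")
            stop("scale mismatch: estimate on '", e@scale,
                 "' scale passed where an additive beta is required")
    }
    ind <- indirectEffect(step1@beta, step1@se, step2@beta, step2@se,
                          secondOrder = secondOrder)
    if (total@beta == 0)
        stop("undefined proportion: total effect is zero")
    prop <- mediatedProportion(ind$beta, ind$se, total@beta, total@se,
                               method = proportionMethod)
    if (prop$inconsistent)
        warning("inconsistent mediation: indirect and total effects ",
                "disagree in sign; proportion reported as a magnitude")
    new("MediationResult",
        totalBeta = total@beta, totalSE = total@se,
        aBeta = step1@beta, aSE = step1@se,
        bBeta = step2@beta, bSE = step2@se,
        indirectBeta = ind$beta, indirectSE = ind$se,
        indirectCiLow = ind$ciLow, indirectCiHigh = ind$ciHigh,
        indirectPval = ind$pval,
        proportion = prop$proportion, proportionCiLow = prop$ciLow,
        proportionCiHigh = prop$ciHigh,
        inconsistent = prop$inconsistent,
        provenance = c(a = step1@method, b = step2@method,
                       total = total@method))
}

#' Write a mediation table as TSV
#'
#' One row per mediator/outcome pair in the layout of the package's
#' mediation report (total, A, B, indirect with CI and p, mediated
#' proportion with CI).
#'
#' @param rows data.frame of flattened [MediationResult-class] rows (see
#'   [as.data.frame.MediationResult()]), typically with mediator/outcome
#'   label columns prepended.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMediationTable <- function(rows, path) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
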