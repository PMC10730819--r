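setMethod("show", "SummaryStats", function(object) {
    d <- object@data
    cat(sprintf("SummaryStats: %d SNP(s)\n", nrow(d)))
    print(utils::head(d, 6L), row.names = FALSE)
    if (nrow(d) > 6L) cat(sprintf("... and %d more row(s)\n", nrow(d) - 6L))
})

setMethod("show", "LDMatrix", function(object) {
    cat(sprintf("LDMatrix: %d SNP(s), mean off-diagonal r2 = %.3g\n",
        length(object@snpIds),
        if (length(object@snpIds) > 1L)
            mean(object@r2[upper.tri(object@r2)]) else 0))
})

setMethod("show", "HarmonizedSet", function(object) {
    cat(sprintf(
        "HarmonizedSet: %d SNP(s) (dropped %d palindromic, %d incompatible)\n",
        length(object@snpIds), object@nDroppedPalindromic,
        object@nDroppedIncompatible))
})

setMethod("show", "MREstimate", function(object) {
    cat(sprintf("MREstimate [%s], %d SNP(s)\n", object@method, object@nSNPs))
    cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
        object@beta, object@se, object@ciLow, object@ciHigh, object@pval))
    if (!is.na(object@orValue))
        cat(sprintf("  OR = %.3f, 95%% CI [%.3f, %.3f]\n",
            object@orValue, object@orCiLow, object@orCiHigh))
})

setMethod("show", "EggerResult", function(object) {
    cat("MR-Egger\n  slope: ")
    cat(sprintf("beta = %.4g (se %.4g), p = %.3g, %d SNP(s)\n",
        object@slope@beta, object@slope@se, object@slope@pval,
        object@slope@nSNPs))
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
        object@intercept, object@interceptSE, object@interceptPval))
})

setMethod("show", "PressoResult", function(object) {
    cat(sprintf("MR-PRESSO (n_sim = %d, seed = %d)\n",
        object@nSim, object@seed))
    cat(sprintf("  global RSS = %.4g, p = %.4g\n",
        object@globalRSS, object@globalPval))
    if (length(object@outlierIds) > 0L) {
        cat(sprintf("  outliers: %s\n",
            paste(object@outlierIds, collapse = ", ")))
        cat(sprintf("  distortion p = %.3g\n", object@distortionPval))
    } else cat("  no outliers detected\n")
    cat(sprintf("  corrected IVW beta = %.4g (se %.4g), %d SNP(s)\n",
        object@corrected@beta, object@corrected@se, object@corrected@nSNPs))
})

setMethod("show", "MVHarmonizedSet", function(object) {
    cat(sprintf("MVHarmonizedSet: %d SNP(s) x %d exposures (%s)\n",
        length(object@snpIds), ncol(object@betaExposures),
        paste(colnames(object@betaExposures), collapse = ", ")))
})

setMethod("show", "MVMRResult", function(object) {
    cat(sprintf("Multivariable IVW, %d SNP(s)\n", object@nSNPs))
    for (nm in names(object@estimates)) {
        e <- object@estimates[[nm]]
        cat(sprintf(
            "  %s: beta = %.4g (se %.4g), p = %.3g, conditional F = %.1f\n",
            nm, e@beta, e@se, e@pval, object@conditionalF[[nm]]))
    }
    cat(sprintf("  residual heterogeneity Q = %.3g\n", object@heterogeneity))
})

setMethod("show", "MediationResult", function(object) {
    cat("Two-step MR mediation\n")
    cat(sprintf("  total = %.4g (se %.4g); A = %.4g (se %.4g); B = %.4g (se %.4g)\n",
        object@totalBeta, object@totalSE, object@aBeta, object@aSE,
        object@bBeta, object@bSE))
    cat(sprintf("  indirect = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
        object@indirectBeta, object@indirectSE, object@indirectCiLow,
        object@indirectCiHigh, object@indirectPval))
    cat(sprintf("  mediated proportion = %.2f%% [%.2f%%, %.2f%%]%s\n",
        object@proportion, object@proportionCiLow, object@proportionCiHigh,
        if (object@inconsistent) " (inconsistent mediation: signs differ)"
        else ""))
})

setMethod("show", "InstrumentSelection", function(object) {
    cat(sprintf(
        "InstrumentSelection: %d SNP(s) (p < %.3g, r2 < %.3g)\n",
        length(object@selectedIds), object@pThreshold, object@r2Threshold))
    cat(sprintf("  mean F = %.1f; %d weak (F < %g)\n",
        object@meanF, object@nWeakFlagged, object@weakFThreshold))
})

setMethod("show", "StudyReport", function(object) {
    cat(sprintf(
        "StudyReport: %d estimate row(s), %d PRESSO run(s), %d MVMR set(s), %d mediation row(s), %d failure(s)\n",
        nrow(object@estimates), length(object@presso), length(object@mvmr),
        nrow(object@mediation), nrow(object@failures)))
})

#' Flatten an MREstimate to a one-row data.frame
#'
#' @param x an [MREstimate-class].
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return one-row data.frame with method, beta, se, ci_low, ci_high, pval,
#'   n_snps, or, or_ci_low, or_ci_high — the results-table dialect written by
#'   [writeResultsTable()].
#' @export
as.data.frame.MREstimate <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    data.frame(method = x@method, beta = x@beta, se = x@se,
               ci_low = x@ciLow, ci_high = x@ciHigh, pval = x@pval,
               n_snps = x@nSNPs, or = x@orValue, or_ci_low = x@orCiLow,
               or_ci_high = x@orCiHigh, stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "MREstimate", as.data.frame.MREstimate)

#' Flatten a MediationResult to a one-row data.frame
#'
#' @param x a [MediationResult-class].
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return one-row data.frame mirroring the mediation table columns (total,
#'   A, B, indirect effect with CI and p, mediated proportion with CI).
#' @export
as.data.frame.MediationResult <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    data.frame(total_beta = x@totalBeta, total_se = x@totalSE,
               a_beta = x@aBeta, a_se = x@aSE,
               b_beta = x@bBeta, b_se = x@bSE,
               indirect_beta = x@indirectBeta, indirect_se = x@indirectSE,
               indirect_ci_low = x@indirectCiLow,
               indirect_ci_high = x@indirectCiHigh,
               indirect_pval = x@indirectPval,
               proportion = x@proportion,
               proportion_ci_low = x@proportionCiLow,
               proportion_ci_high = x@proportionCiHigh,
               inconsistent = x@inconsistent, stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "MediationResult", as.data.frame.MediationResult)
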