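#' @import methods
NULL

.VALID_ALLELES <- c("A", "C", "G", "T")

#' SummaryStats: per-SNP GWAS associations for one trait
#'
#' Container for GWAS summary statistics, one row per SNP: identifier,
#' effect/other allele, effect-allele frequency, per-allele effect (beta on
#' the trait scale, log-odds for binary traits), its standard error, p-value
#' and sample size. Validity enforces the per-record invariants: distinct
#' alleles from \{A,C,G,T\}, se > 0, p in (0,1], eaf in [0,1] when present,
#' n >= 1, and unique SNP identifiers.
#'
#' @slot data data.frame with columns SNP, EA, OA, EAF, BETA, SE, P, N.
#' @seealso [SummaryStats()], [readSummaryStats()], [harmonize()]
#' @export
setClass("SummaryStats", representation(data = "data.frame"))

setValidity("SummaryStats", function(object) {
    d <- object@data
    req <- c("SNP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
    miss <- setdiff(req, names(d))
    if (length(miss) > 0L)
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    msgs <- character(0)
    if (anyDuplicated(d$SNP))
        msgs <- c(msgs, sprintf("duplicated snp_id(s): %s",
                  paste(unique(d$SNP[duplicated(d$SNP)]), collapse = ", ")))
    bad <- .badRecordReasons(d)
    if (length(bad) > 0L)
        msgs <- c(msgs, bad)
    if (length(msgs) > 0L) paste(msgs, collapse = "; ") else TRUE
})

# Per-row invariant check shared by the class validity and the reader (which
# needs row numbers for its rejection report). Returns character(0) if clean.
.badRecordReasons <- function(d) {
    out <- character(0)
    chk <- function(bad, what) {
        if (any(bad, na.rm = TRUE)) {
            rows <- which(bad)
            out <<- c(out, sprintf("row %d: %s", rows, what[if (length(what) > 1L) rows else 1L]))
        }
    }
    chk(!(d$EA %in% .VALID_ALLELES), "effect allele not one of A,C,G,T")
    chk(!(d$OA %in% .VALID_ALLELES), "other allele not one of A,C,G,T")
    chk(d$EA == d$OA, "effect_allele equals other_allele")
    chk(!is.finite(d$BETA), "beta is not numeric/finite")
    chk(!is.finite(d$SE) | d$SE <= 0, "se must be > 0")
    chk(!is.finite(d$P) | d$P <= 0 | d$P > 1, "pval must be in (0,1]")
    chk(!is.na(d$EAF) & (d$EAF < 0 | d$EAF > 1), "eaf must be in [0,1]")
    chk(!is.na(d$N) & d$N < 1, "n must be >= 1")
    out
}

#' LDMatrix: squared-correlation matrix between SNPs
#'
#' Symmetric matrix of pairwise squared LD correlations (r\eqn{^2}) with unit
#' diagonal, used for greedy p-value clumping.
#'
#' @slot snpIds character vector naming rows/columns in order.
#' @slot r2 numeric matrix of squared correlations in [0,1].
#' @seealso [makeLDMatrix()], [clumpInstruments()]
#' @export
setClass("LDMatrix", representation(snpIds = "character", r2 = "matrix"))

setValidity("LDMatrix", function(object) {
    r2 <- object@r2
    if (nrow(r2) != ncol(r2)) return("r2 matrix must be square")
    if (length(object@snpIds) != nrow(r2))
        return("snpIds length must match r2 dimension")
    if (anyDuplicated(object@snpIds)) return("duplicated snp ids")
    if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1))
        return("r2 values must lie in [0,1]")
    if (max(abs(r2 - t(r2))) > 1e-12) return("r2 matrix must be symmetric")
    if (any(abs(diag(r2) - 1) > 1e-12)) return("r2 diagonal must be exactly 1")
    TRUE
})

#' HarmonizedSet: aligned exposure/outcome effects ready for MR
#'
#' Per-SNP exposure and outcome associations expressed on a shared
#' effect-allele convention, with counts of SNPs dropped during
#' harmonization (palindromic A/T, C/G variants whose strand cannot be
#' resolved; allele-incompatible pairs).
#'
#' @slot snpIds ordered SNP identifiers.
#' @slot betaExposure,seExposure per-SNP exposure effect and SE.
#' @slot betaOutcome,seOutcome per-SNP outcome effect and SE.
#' @slot nDroppedPalindromic,nDroppedIncompatible integer drop counts.
#' @seealso [harmonize()], [mrIVW()], [mrEgger()]
#' @export
setClass("HarmonizedSet", representation(
    snpIds = "character",
    betaExposure = "numeric", seExposure = "numeric",
    betaOutcome = "numeric", seOutcome = "numeric",
    nDroppedPalindromic = "integer", nDroppedIncompatible = "integer"))

setValidity("HarmonizedSet", function(object) {
    J <- length(object@snpIds)
    if (J < 1L) return("a HarmonizedSet needs at least one SNP")
    lens <- c(length(object@betaExposure), length(object@seExposure),
              length(object@betaOutcome), length(object@seOutcome))
    if (any(lens != J)) return("all effect arrays must share the SNP count")
    if (any(object@seExposure <= 0) || any(object@seOutcome <= 0))
        return("standard errors must be > 0")
    if (object@nDroppedPalindromic < 0L || object@nDroppedIncompatible < 0L)
        return("drop counts must be non-negative")
    TRUE
})

#' MREstimate: one causal effect estimate
#'
#' A causal effect of the exposure on the outcome (per unit exposure, on the
#' outcome's additive scale) with its standard error, 95\% confidence
#' interval, two-sided p-value, the estimator that produced it and the number
#' of SNP instruments used. For binary outcomes the odds-ratio scale
#' (exp(beta) and its CI) is populated alongside.
#'
#' @slot method one of wald, ivw_fixed, ivw_mre, weighted_median, egger_slope.
#' @slot beta,se point estimate and standard error.
#' @slot ciLow,ciHigh 95\% interval bounds.
#' @slot pval two-sided p-value.
#' @slot nSNPs instrument count.
#' @slot orValue,orCiLow,orCiHigh exponentiated scale (NA when not populated).
#' @slot scale "beta" (additive / log-odds); "or" marks an odds-ratio scale
#'   value that must not enter mediation arithmetic.
#' @seealso [mrIVW()], [waldRatio()], [weightedMedian()], [toOddsRatio()]
#' @export
setClass("MREstimate", representation(
    method = "character", beta = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
    nSNPs = "integer", orValue = "numeric", orCiLow = "numeric",
    orCiHigh = "numeric", scale = "character"))

.MR_METHODS <- c("wald", "ivw_fixed", "ivw_mre", "weighted_median",
                 "egger_slope", "mvmr_ivw")

setValidity("MREstimate", function(object) {
    if (!object@method %in% .MR_METHODS)
        return(sprintf("unknown method label '%s'", object@method))
    if (!is.finite(object@se) || object@se <= 0) return("se must be > 0")
    if (object@ciLow > object@beta || object@beta > object@ciHigh)
        return("ci_low <= beta <= ci_high violated")
    if (!is.na(object@orValue) &&
        abs(object@orValue - exp(object@beta)) > 1e-8 * max(1, object@orValue))
        return("or_value must equal exp(beta)")
    if (!object@scale %in% c("beta", "or")) return("scale must be beta or or")
    TRUE
})

#' EggerResult: MR-Egger slope and pleiotropy intercept
#'
#' The MR-Egger regression slope (causal estimate robust to directional
#' pleiotropy under the InSIDE assumption) together with the intercept, which
#' estimates the average directional pleiotropic effect; a non-zero intercept
#' flags violation of the exclusion-restriction assumption.
#'
#' @slot slope an [MREstimate-class] with method "egger_slope".
#' @slot intercept,interceptSE average directional pleiotropy and its SE.
#' @slot interceptPval two-sided p for intercept = 0 (t with J-2 df).
#' @seealso [mrEgger()]
#' @export
setClass("EggerResult", representation(
    slope = "MREstimate", intercept = "numeric",
    interceptSE = "numeric", interceptPval = "numeric"))

setValidity("EggerResult", function(object) {
    if (!is.finite(object@interceptPval) ||
        object@interceptPval <= 0 || object@interceptPval > 1)
        return("intercept_pval must be in (0,1]")
    TRUE
})

#' PressoResult: MR-PRESSO global, outlier and distortion tests
#'
#' Result of the simulation-based horizontal-pleiotropy analysis: the observed
#' leave-one-out residual sum of squares with its empirical global p-value,
#' the SNPs flagged as pleiotropic outliers after Bonferroni correction, the
#' distortion test comparing raw and outlier-corrected estimates, and the
#' outlier-corrected IVW re-estimate.
#'
#' @slot globalRSS observed residual sum of squares.
#' @slot globalPval add-one empirical p-value (never exactly 0).
#' @slot outlierIds SNPs failing the per-SNP outlier test.
#' @slot distortionPval p for the raw-vs-corrected difference (NA when no
#'   outliers were removed).
#' @slot raw,corrected IVW estimates before/after outlier removal.
#' @slot perSNP data.frame of per-SNP RSS contributions and empirical p.
#' @slot nSim simulation count. @slot seed the seed used.
#' @seealso [mrPresso()]
#' @export
setClass("PressoResult", representation(
    globalRSS = "numeric", globalPval = "numeric", outlierIds = "character",
    distortionPval = "numeric", raw = "MREstimate", corrected = "MREstimate",
    perSNP = "data.frame", nSim = "integer", seed = "integer"))

setValidity("PressoResult", function(object) {
    if (!is.finite(object@globalPval) ||
        object@globalPval <= 0 || object@globalPval > 1)
        return("global_pval must be in (0,1]")
    if (!all(object@outlierIds %in% object@perSNP$SNP))
        return("outlier_ids must be a subset of the instrument ids")
    if (object@corrected@nSNPs !=
        nrow(object@perSNP) - length(object@outlierIds))
        return("corrected n_snps must equal n_snps - n_outliers")
    TRUE
})

#' MVHarmonizedSet: multi-exposure harmonized effects
#'
#' Per-SNP effects on K exposures and one outcome, all expressed on one
#' effect-allele convention, for multivariable MR.
#'
#' @slot snpIds ordered SNP identifiers (length J).
#' @slot betaExposures,seExposures J x K matrices (columns named by exposure).
#' @slot betaOutcome,seOutcome per-SNP outcome effect and SE.
#' @seealso [mvmrIVW()], [harmonizeMV()]
#' @export
setClass("MVHarmonizedSet", representation(
    snpIds = "character",
    betaExposures = "matrix", seExposures = "matrix",
    betaOutcome = "numeric", seOutcome = "numeric"))

setValidity("MVHarmonizedSet", function(object) {
    J <- length(object@snpIds); K <- ncol(object@betaExposures)
    if (K < 2L) return("multivariable MR needs K >= 2 exposures")
    if (J <= K) return("needs more SNPs than exposures (J > K)")
    if (nrow(object@betaExposures) != J || nrow(object@seExposures) != J ||
        ncol(object@seExposures) != K ||
        length(object@betaOutcome) != J || length(object@seOutcome) != J)
        return("dimension mismatch between slots")
    if (is.null(colnames(object@betaExposures)))
        return("exposure columns must be named")
    if (any(object@seExposures <= 0) || any(object@seOutcome <= 0))
        return("standard errors must be > 0")
    TRUE
})

#' MVMRResult: direct effects from multivariable IVW
#'
#' One direct-effect estimate per exposure, conditional on the co-exposures,
#' with per-exposure conditional F statistics (instrument strength given the
#' other exposures) and a residual heterogeneity statistic.
#'
#' @slot estimates named list of [MREstimate-class], one per exposure.
#' @slot conditionalF named numeric, conditional F per exposure.
#' @slot heterogeneity residual heterogeneity (Cochran-type Q on J-K df).
#' @slot nSNPs instrument count shared by all estimates.
#' @seealso [mvmrIVW()]
#' @export
setClass("MVMRResult", representation(
    estimates = "list", conditionalF = "numeric",
    heterogeneity = "numeric", nSNPs = "integer"))

setValidity("MVMRResult", function(object) {
    if (length(object@estimates) != length(object@conditionalF))
        return("one conditional F per exposure required")
    if (!all(vapply(object@estimates, is, logical(1), "MREstimate")))
        return("estimates must be MREstimate objects")
    if (!all(vapply(object@estimates, function(e) e@nSNPs, integer(1)) ==
             object@nSNPs))
        return("all estimates must carry the same SNP count")
    TRUE
})

#' MediationResult: two-step MR mediation decomposition
#'
#' Product-of-coefficients mediation of an exposure's effect on an outcome
#' through one mediator: the total effect, the exposure-to-mediator effect A,
#' the mediator-to-outcome effect B, the indirect effect A*B with its
#' delta-method standard error and normal CI, and the mediated proportion
#' (percent of the total effect, clipped to [0,100]).
#'
#' @slot totalBeta,totalSE total exposure-to-outcome effect (log-odds scale
#'   for binary outcomes).
#' @slot aBeta,aSE,bBeta,bSE the two step estimates.
#' @slot indirectBeta,indirectSE product of coefficients and delta-method SE.
#' @slot indirectCiLow,indirectCiHigh,indirectPval normal 95\% CI and p.
#' @slot proportion,proportionCiLow,proportionCiHigh mediated proportion in
#'   percent with its CI, all clipped to [0,100].
#' @slot inconsistent TRUE when indirect and total effects disagree in sign
#'   ("inconsistent mediation"); the proportion is then a magnitude ratio.
#' @slot provenance labels of the estimators that produced A, B and total.
#' @seealso [twoStepMediation()], [indirectEffect()], [mediatedProportion()]
#' @export
setClass("MediationResult", representation(
    totalBeta = "numeric", totalSE = "numeric",
    aBeta = "numeric", aSE = "numeric", bBeta = "numeric", bSE = "numeric",
    indirectBeta = "numeric", indirectSE = "numeric",
    indirectCiLow = "numeric", indirectCiHigh = "numeric",
    indirectPval = "numeric",
    proportion = "numeric", proportionCiLow = "numeric",
    proportionCiHigh = "numeric",
    inconsistent = "logical", provenance = "character"))

setValidity("MediationResult", function(object) {
    if (abs(object@indirectBeta - object@aBeta * object@bBeta) >
        1e-12 * max(1, abs(object@indirectBeta)))
        return("indirect_beta must equal a_beta * b_beta exactly")
    p <- c(object@proportion, object@proportionCiLow, object@proportionCiHigh)
    if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
        return("proportion and its CI must lie in [0,100]")
    TRUE
})

#' InstrumentSelection: report of instrument screening
#'
#' The outcome of p-value filtering, LD clumping and instrument-strength
#' assessment for one exposure: the retained SNPs, the thresholds used,
#' per-SNP F statistics (squared z-scores), their mean, and how many fell
#' below the weak-instrument bound (conventionally F < 10).
#'
#' @slot selectedIds retained SNP identifiers, in clump acceptance order.
#' @slot pThreshold,r2Threshold,weakFThreshold thresholds applied.
#' @slot fStats named per-SNP F statistics of the retained SNPs.
#' @slot meanF arithmetic mean of fStats.
#' @slot nWeakFlagged count of retained SNPs with F < weakFThreshold.
#' @slot table per-SNP report (SNP, pval, F, weak flag).
#' @seealso [selectInstruments()], [fStatistic()]
#' @export
setClass("InstrumentSelection", representation(
    selectedIds = "character", pThreshold = "numeric",
    r2Threshold = "numeric", weakFThreshold = "numeric",
    fStats = "numeric", meanF = "numeric", nWeakFlagged = "integer",
    table = "data.frame"))

setValidity("InstrumentSelection", function(object) {
    if (length(object@fStats) != length(object@selectedIds))
        return("one F statistic per selected SNP required")
    TRUE
})

#' StudyReport: full study results and provenance
#'
#' Output of [runStudy()]: per exposure-outcome pair the univariable
#' estimates (all methods), Egger intercepts, MR-PRESSO results, optional
#' multivariable results, mediation rows for mediators passing the step-1
#' screen, significance flags at the Bonferroni threshold, failures isolated
#' per pair, and a provenance log (seeds, thresholds, settings) sufficient to
#' re-execute the run bit-identically.
#'
#' @slot estimates data.frame of univariable results, one row per method per
#'   pair, with Bonferroni significance flags.
#' @slot presso named list of [PressoResult-class] per pair.
#' @slot mvmr named list of [MVMRResult-class] per adjustment set.
#' @slot mediation data.frame of mediation rows (Table-1 layout).
#' @slot failures data.frame of per-pair failures (stage, pair, message).
#' @slot provenance list of seeds, thresholds and settings.
#' @seealso [runStudy()]
#' @export
setClass("StudyReport", representation(
    estimates = "data.frame", presso = "list", mvmr = "list",
    mediation = "data.frame", failures = "data.frame", provenance = "list"))
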