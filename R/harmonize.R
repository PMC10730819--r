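.isPalindromic <- function(ea, oa) {
    (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two studies' per-SNP effects onto the exposure's effect-allele
#' convention so the Wald ratio beta_outcome / beta_exposure refers to the
#' same allele in both studies. SNPs are matched by identifier; where the
#' outcome's effect allele equals the exposure's other allele (and vice
#' versa) the outcome beta is negated and its effect-allele frequency
#' replaced by 1 - eaf. Palindromic variants (A/T or C/G), whose strand
#' cannot be resolved from alleles alone, are always removed, as are SNPs
#' whose allele pairs are incompatible between the studies; both drop counts
#' are recorded.
#'
#' @param exposure,outcome [SummaryStats-class] (or canonical data.frames)
#'   for the exposure and outcome studies; SNP ids must be unique in each.
#' @return a [HarmonizedSet-class] in the exposure's SNP order.
#' @examples
#' exp <- SummaryStats(data.frame(SNP = "rs1", EA = "A", OA = "G",
#'                                BETA = 0.10, SE = 0.02, P = 1e-9))
#' out <- SummaryStats(data.frame(SNP = "rs1", EA = "G", OA = "A",
#'                                BETA = -0.05, SE = 0.01, P = 1e-4))
#' h <- harmonize(exp, out)   # outcome beta flipped to +0.05
#' @export
harmonize <- function(exposure, outcome) {
    e <- asSummaryData(exposure)
    o <- asSummaryData(outcome)
    if (nrow(e) == 0L || nrow(o) == 0L)
        stop("both exposure and outcome must contain records")
    shared <- e$SNP[e$SNP %in% o$SNP]
    if (length(shared) == 0L) stop("no shared instruments")
    e <- e[match(shared, e$SNP), , drop = FALSE]
    o <- o[match(shared, o$SNP), , drop = FALSE]

    pal <- .isPalindromic(e$EA, e$OA) | .isPalindromic(o$EA, o$OA)
    same <- o$EA == e$EA & o$OA == e$OA
    flip <- o$EA == e$OA & o$OA == e$EA
    incompat <- !pal & !same & !flip
    keep <- !pal & !incompat

    if (!any(keep))
        stop("no shared instruments survive harmonization (",
             sum(pal), " palindromic, ", sum(incompat), " incompatible)")

    betaOut <- ifelse(flip, -o$BETA, o$BETA)
    new("HarmonizedSet",
        snpIds = shared[keep],
        betaExposure = e$BETA[keep], seExposure = e$SE[keep],
        betaOutcome = betaOut[keep], seOutcome = o$SE[keep],
        nDroppedPalindromic = as.integer(sum(pal)),
        nDroppedIncompatible = as.integer(sum(incompat)))
}

#' Harmonize several exposures and one outcome for multivariable MR
#'
#' Aligns every exposure's per-SNP effects onto the outcome study's
#' effect-allele convention (so all K exposure columns and the outcome share
#' one convention), dropping palindromic and allele-incompatible variants per
#' trait via [harmonize()], and keeps the SNPs retained for every trait.
#'
#' @param exposures named list of [SummaryStats-class] (K >= 2).
#' @param outcome a [SummaryStats-class].
#' @param snpIds optional instrument pool to restrict to (e.g. the union of
#'   each exposure's selected instruments).
#' @return an [MVHarmonizedSet-class].
#' @export
harmonizeMV <- function(exposures, outcome, snpIds = NULL) {
    if (is.null(names(exposures)) || any(names(exposures) == ""))
        stop("exposures must be a named list")
    if (length(exposures) < 2L)
        stop("multivariable harmonization needs K >= 2 exposures")
    # harmonize with the outcome as the reference study: the "outcome" slots
    # then hold each exposure's effects signed to the outcome's effect allele
    hs <- lapply(exposures, function(x) harmonize(outcome, x))
    ids <- Reduce(intersect, lapply(hs, function(h) h@snpIds))
    if (!is.null(snpIds)) ids <- ids[ids %in% snpIds]
    K <- length(exposures)
    if (length(ids) <= K)
        stop("only ", length(ids), " SNP(s) shared across all traits; ",
             "need J > K = ", K)
    betaX <- vapply(hs, function(h) h@betaOutcome[match(ids, h@snpIds)],
                    numeric(length(ids)))
    seX <- vapply(hs, function(h) h@seOutcome[match(ids, h@snpIds)],
                  numeric(length(ids)))
    h1 <- hs[[1L]]
    idx <- match(ids, h1@snpIds)
    new("MVHarmonizedSet", snpIds = ids,
        betaExposures = matrix(betaX, ncol = K,
                               dimnames = list(NULL, names(exposures))),
        seExposures = matrix(seX, ncol = K,
                             dimnames = list(NULL, names(exposures))),
        betaOutcome = h1@betaExposure[idx], seOutcome = h1@seExposure[idx])
}
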