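#' Filter summary statistics by association p-value
#'
#' Keeps exactly the records with p strictly below the threshold (genome-wide
#' significance is conventionally p < 5e-8), preserving input order. An empty
#' result is legal.
#'
#' @param x a [SummaryStats-class] or canonical data.frame.
#' @param pThreshold significance cutoff in (0,1); strict inequality.
#' @return a [SummaryStats-class] with the passing records.
#' @export
selectByPvalue <- function(x, pThreshold = 5e-8) {
    stopifnot(is.numeric(pThreshold), length(pThreshold) == 1L,
              pThreshold > 0, pThreshold < 1)
    d <- asSummaryData(x)
    new("SummaryStats", data = d[d$P < pThreshold, , drop = FALSE])
}

#' Greedy LD clumping by p-value rank
#'
#' Orders records by ascending p-value (ties broken lexicographically by SNP
#' id, for determinism) and accepts a SNP iff its squared correlation with
#' every already-accepted SNP is strictly below `r2Threshold` — the PLINK
#' clumping rule applied to a supplied LD matrix. The output is therefore
#' invariant to the input ordering.
#'
#' @param x a [SummaryStats-class] or canonical data.frame.
#' @param ld an [LDMatrix-class] covering every record's SNP id.
#' @param r2Threshold clumping cutoff in (0,1); strict inequality
#'   (r\eqn{^2} < 0.001 in standard practice).
#' @return a [SummaryStats-class] with the retained records, in acceptance
#'   (p-value) order.
#' @export
clumpInstruments <- function(x, ld, r2Threshold = 0.001) {
    stopifnot(is(ld, "LDMatrix"),
              is.numeric(r2Threshold), length(r2Threshold) == 1L,
              r2Threshold > 0, r2Threshold < 1)
    d <- asSummaryData(x)
    if (nrow(d) == 0L) return(new("SummaryStats", data = d))
    missing <- setdiff(d$SNP, ld@snpIds)
    if (length(missing) > 0L)
        stop("SNP(s) absent from the LD matrix: ",
             paste(missing, collapse = ", "))
    ord <- order(d$P, d$SNP)
    d <- d[ord, , drop = FALSE]
    r2 <- ld@r2[match(d$SNP, ld@snpIds), match(d$SNP, ld@snpIds),
                drop = FALSE]
    accepted <- integer(0)
    for (j in seq_len(nrow(d))) {
        if (length(accepted) == 0L ||
            all(r2[j, accepted] < r2Threshold))
            accepted <- c(accepted, j)
    }
    res <- d[accepted, , drop = FALSE]
    rownames(res) <- NULL
    new("SummaryStats", data = res)
}

#' Per-SNP instrument-strength F statistic
#'
#' The single-SNP approximation F = (beta/se)^2, the squared z-score of the
#' SNP-exposure association. F < 10 conventionally flags weak-instrument
#' bias. Scale-invariant under joint rescaling of beta and se.
#'
#' @param beta SNP-exposure effect(s).
#' @param se standard error(s), > 0; recycled against `beta`.
#' @return numeric vector of F statistics.
#' @examples
#' fStatistic(0.10, 0.01)  # 100
#' @export
fStatistic <- function(beta, se) {
    if (any(!is.finite(se)) || any(se <= 0))
        stop("se must be > 0")
    (beta / se)^2
}

#' Select instruments for an exposure
#'
#' Full screening chain: genome-wide significance filter
#' ([selectByPvalue()]), greedy LD clumping ([clumpInstruments()]), and
#' per-SNP F statistics with weak-instrument flagging. Weak instruments
#' (F below `weakFThreshold`) are flagged, and dropped only when
#' `dropWeak = TRUE`.
#'
#' @param x a [SummaryStats-class] for the exposure.
#' @param ld an [LDMatrix-class] covering the significant SNPs.
#' @param pThreshold significance cutoff (default 5e-8, strict).
#' @param r2Threshold clumping cutoff (default 0.001, strict).
#' @param weakFThreshold weak-instrument bound (default 10).
#' @param dropWeak drop flagged SNPs instead of only flagging (default
#'   FALSE: the selection reports weakness, it does not act on it).
#' @return an [InstrumentSelection-class].
#' @export
selectInstruments <- function(x, ld, pThreshold = 5e-8, r2Threshold = 0.001,
                              weakFThreshold = 10, dropWeak = FALSE) {
    sig <- selectByPvalue(x, pThreshold)
    clumped <- clumpInstruments(sig, ld, r2Threshold)
    d <- clumped@data
    f <- if (nrow(d) > 0L) fStatistic(d$BETA, d$SE) else numeric(0)
    names(f) <- d$SNP
    weak <- f < weakFThreshold
    if (dropWeak && any(weak)) {
        d <- d[!weak, , drop = FALSE]
        f <- f[!weak]
        weak <- weak[!weak]
    }
    tab <- data.frame(SNP = d$SNP, pval = d$P, F = unname(f),
                      weak = unname(f < weakFThreshold),
                      stringsAsFactors = FALSE)
    new("InstrumentSelection",
        selectedIds = d$SNP, pThreshold = pThreshold,
        r2Threshold = r2Threshold, weakFThreshold = weakFThreshold,
        fStats = f, meanF = if (length(f) > 0L) mean(f) else NA_real_,
        nWeakFlagged = as.integer(sum(tab$weak)), table = tab)
}

#' Write an instrument-selection report as TSV
#'
#' @param sel an [InstrumentSelection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSelectionReport <- function(sel, path) {
    stopifnot(is(sel, "InstrumentSelection"))
    utils::write.table(sel@table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
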