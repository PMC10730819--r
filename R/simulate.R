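#' Simulation configuration for the summary-statistics generator
#'
#' Builds and validates the configuration for [simulateSummaryStats()].
#' Statistics are simulated directly at the summary level (no genotypes):
#' each instrument SNP gets a true SNP-exposure effect gamma drawn from a
#' normal distribution, observed effects are the truth plus Gaussian noise
#' at the study's SE scale, and exposure and outcome studies are simulated
#' independently (the two-sample design, no sample overlap).
#'
#' @param seed mandatory integer seed; the generator has no implicit seeds.
#' @param J number of instrument SNPs (true SNP-exposure effect non-zero).
#' @param K number of exposures; for K > 1 every instrument affects all K
#'   (shared-instrument design) and `theta` must have length K.
#' @param gammaMean,gammaSD normal distribution of true SNP-exposure
#'   effects (defaults 0.1 and 0.02: strong instruments, typical per-SNP
#'   F around 100 at the default SE scales).
#' @param theta true direct exposure-to-outcome effect(s), length K.
#'   Ignored when `mediatorChain` is given (the chain's `cPrime` is the
#'   direct effect).
#' @param seExposure,seMediator,seOutcome per-study SE scales; each may be
#'   overridden by a nominal sample size via `nExposure`/`nMediator`/
#'   `nOutcome` (then se = 1/sqrt(n)).
#' @param nExposure,nMediator,nOutcome optional nominal sample sizes; also
#'   echoed into the N column of the emitted tables.
#' @param mediatorChain optional list(a, b, cPrime, J) describing an
#'   exposure -> mediator -> outcome chain: `a` is the exposure-to-mediator
#'   effect, `b` the mediator-to-outcome effect, `cPrime` the direct
#'   exposure-to-outcome effect, and `J` the number of SNPs instrumenting
#'   the mediator directly (defaults to the exposure's J). Requires K = 1.
#' @param pleiotropy list(mode, magnitude, frac): mode one of "none",
#'   "balanced" (offsets N(0, magnitude)), "directional" (constant offset
#'   = magnitude) or "inside_violating" (offset = magnitude * gamma,
#'   correlated with instrument strength); frac is the fraction of
#'   instrument SNPs affected (default 1).
#' @param nNullSNPs SNPs with zero true effect on everything, for
#'   selection testing.
#' @param palindromicFrac fraction of SNPs given A/T or C/G alleles, to
#'   exercise harmonization's palindromic filter.
#' @param flipFrac fraction of outcome/mediator records emitted on the
#'   opposite effect-allele convention (beta negated, alleles swapped), to
#'   exercise harmonization's allele alignment.
#' @param ldBlocks optional list(sizes, r2): block sizes and within-block
#'   squared correlation for the leading SNPs of the panel; the rest of the
#'   LD matrix is identity.
#' @return validated configuration list (class `simConfig`).
#' @export
simConfig <- function(seed, J = 30L, K = 1L,
                      gammaMean = 0.1, gammaSD = 0.02,
                      theta = 0.2,
                      seExposure = 0.01, seMediator = 0.01,
                      seOutcome = 0.05,
                      nExposure = NULL, nMediator = NULL, nOutcome = NULL,
                      mediatorChain = NULL,
                      pleiotropy = list(mode = "none", magnitude = 0,
                                        frac = 1),
                      nNullSNPs = 0L, palindromicFrac = 0,
                      flipFrac = 0.3, ldBlocks = NULL) {
    if (missing(seed)) stop("an explicit integer seed is required")
    stopifnot(J >= 1L, K >= 1L, gammaSD > 0,
              seExposure > 0, seMediator > 0, seOutcome > 0,
              nNullSNPs >= 0L, palindromicFrac >= 0, palindromicFrac <= 1,
              flipFrac >= 0, flipFrac <= 1)
    if (!is.null(mediatorChain)) {
        if (K != 1L) stop("mediatorChain requires K = 1")
        need <- c("a", "b", "cPrime")
        if (!all(need %in% names(mediatorChain)))
            stop("mediatorChain needs fields a, b, cPrime")
        if (is.null(mediatorChain$J)) mediatorChain$J <- J
        theta <- mediatorChain$cPrime + mediatorChain$a * mediatorChain$b
    }
    if (length(theta) != K)
        stop("theta must have length K = ", K)
    pleiotropy <- utils::modifyList(
        list(mode = "none", magnitude = 0, frac = 1), pleiotropy)
    if (!pleiotropy$mode %in% c("none", "balanced", "directional",
                                "inside_violating"))
        stop("unknown pleiotropy mode '", pleiotropy$mode, "'")
    if (pleiotropy$magnitude < 0) stop("pleiotropy magnitude must be >= 0")
    if (!is.null(ldBlocks)) {
        if (any(ldBlocks$sizes < 1L)) stop("ld block sizes must be >= 1")
        if (ldBlocks$r2 < 0 || ldBlocks$r2 >= 1)
            stop("within-block r2 must be in [0,1)")
    }
    if (!is.null(nExposure)) seExposure <- 1 / sqrt(nExposure)
    if (!is.null(nMediator)) seMediator <- 1 / sqrt(nMediator)
    if (!is.null(nOutcome)) seOutcome <- 1 / sqrt(nOutcome)
    structure(list(seed = as.integer(seed), J = as.integer(J),
                   K = as.integer(K), gammaMean = gammaMean,
                   gammaSD = gammaSD, theta = theta,
                   seExposure = seExposure, seMediator = seMediator,
                   seOutcome = seOutcome, nExposure = nExposure,
                   nMediator = nMediator, nOutcome = nOutcome,
                   mediatorChain = mediatorChain, pleiotropy = pleiotropy,
                   nNullSNPs = as.integer(nNullSNPs),
                   palindromicFrac = palindromicFrac, flipFrac = flipFrac,
                   ldBlocks = ldBlocks),
              class = "simConfig")
}

#' Block-diagonal LD matrix
#'
#' @param sizes block sizes (each >= 1).
#' @param withinR2 squared correlation inside each block, in [0,1);
#'   between-block entries are 0 and the diagonal is exactly 1.
#' @param snpIds identifiers for the SNPs (defaults to snp001, ...).
#' @return an [LDMatrix-class].
#' @examples
#' makeLDMatrix(c(2, 2), 0.8)
#' @export
makeLDMatrix <- function(sizes, withinR2 = 0,
                         snpIds = sprintf("snp%03d", seq_len(sum(sizes)))) {
    if (any(sizes < 1L)) stop("block sizes must be >= 1")
    if (withinR2 < 0 || withinR2 >= 1)
        stop("off-diagonal r2 must be in [0,1)")
    n <- sum(sizes)
    r2 <- matrix(0, n, n)
    at <- 0L
    for (s in sizes) {
        idx <- at + seq_len(s)
        r2[idx, idx] <- withinR2
        at <- at + s
    }
    diag(r2) <- 1
    LDMatrix(r2, snpIds = snpIds)
}

.pickAlleles <- function(n, palindromic) {
    nonPal <- list(c("A", "G"), c("A", "C"), c("G", "T"), c("C", "T"))
    pal <- list(c("A", "T"), c("C", "G"))
    ea <- character(n); oa <- character(n)
    for (i in seq_len(n)) {
        pair <- if (palindromic[i]) pal[[sample.int(2L, 1L)]]
                else nonPal[[sample.int(4L, 1L)]]
        if (stats::runif(1) < 0.5) pair <- rev(pair)
        ea[i] <- pair[1L]; oa[i] <- pair[2L]
    }
    list(ea = ea, oa = oa)
}

# Emit one trait's table on a possibly flipped allele convention per SNP.
.traitTable <- function(ids, ea, oa, eaf, trueBeta, se, n, flip) {
    beta <- trueBeta + stats::rnorm(length(ids), 0, se)
    EA <- ifelse(flip, oa, ea); OA <- ifelse(flip, ea, oa)
    b <- ifelse(flip, -beta, beta)
    f <- ifelse(flip, 1 - eaf, eaf)
    p <- 2 * stats::pnorm(-abs(b / se))
    SummaryStats(data.frame(SNP = ids, EA = EA, OA = OA, EAF = f,
                            BETA = b, SE = se, P = pmax(p, 1e-300),
                            N = if (is.null(n)) NA_real_ else n,
                            stringsAsFactors = FALSE))
}

#' Generate two-sample GWAS summary statistics under a known truth
#'
#' Simulates, at the summary level, an exposure study, an outcome study,
#' optionally a mediator study, and an LD matrix, under the causal model of
#' the configuration: instrument SNP j has true exposure effect gamma_j;
#' the true outcome effect is theta * gamma_j plus any pleiotropic offset
#' (plus the mediated contribution a*b*gamma_j when a mediator chain is
#' configured); mediator-instrument SNPs affect the mediator directly and
#' the outcome through b; null SNPs affect nothing. Observed effects add
#' independent Gaussian noise at each study's SE scale. All tables cover
#' the full SNP panel, so instrument selection, harmonization (including
#' palindromic and flipped-convention records) and every estimator can be
#' exercised end to end.
#'
#' @param config a configuration from [simConfig()].
#' @return list with components `exposures` (named list of
#'   [SummaryStats-class], length K), `exposure` (the first, for the common
#'   K = 1 case), `mediator` (NULL without a chain), `outcome`, `ld` (an
#'   [LDMatrix-class] over the whole panel) and `truth` (the ground-truth
#'   record: theta, a, b, cPrime, total, per-SNP gammas and pleiotropy
#'   offsets, instrument/null id sets, seed echo).
#' @examples
#' sim <- simulateSummaryStats(simConfig(seed = 1, J = 10))
#' h <- harmonize(sim$exposure, sim$outcome)
#' mrIVW(h)
#' @export
simulateSummaryStats <- function(config) {
    if (!inherits(config, "simConfig"))
        stop("config must come from simConfig()")
    c_ <- config
    .withSeed(c_$seed, {
        J <- c_$J; K <- c_$K
        JM <- if (!is.null(c_$mediatorChain)) c_$mediatorChain$J else 0L
        JN <- c_$nNullSNPs
        n <- J + JM + JN
        ids <- sprintf("snp%03d", seq_len(n))
        ivIds <- ids[seq_len(J)]
        mvIds <- if (JM > 0L) ids[J + seq_len(JM)] else character(0)
        nullIds <- if (JN > 0L) ids[J + JM + seq_len(JN)] else character(0)

        gamma <- matrix(stats::rnorm(J * K, c_$gammaMean, c_$gammaSD), J, K)
        gammaM <- if (JM > 0L) stats::rnorm(JM, c_$gammaMean, c_$gammaSD)
                  else numeric(0)

        alpha <- numeric(J)
        pl <- c_$pleiotropy
        if (pl$mode != "none" && pl$magnitude > 0 && pl$frac > 0) {
            m <- max(1L, round(pl$frac * J))
            hit <- sample.int(J, m)
            alpha[hit] <- switch(pl$mode,
                balanced = stats::rnorm(m, 0, pl$magnitude),
                directional = pl$magnitude,
                inside_violating = pl$magnitude * gamma[hit, 1L])
        }

        chain <- c_$mediatorChain
        # true outcome effects over the whole panel
        thetaTotal <- c_$theta   # includes a*b + cPrime when chain set
        trueOut <- c(drop(gamma %*% thetaTotal) + alpha,
                     if (JM > 0L) chain$b * gammaM,
                     rep(0, JN))
        trueExp <- rbind(gamma,
                         matrix(0, JM + JN, K))
        trueMed <- if (!is.null(chain))
            c(chain$a * gamma[, 1L], gammaM, rep(0, JN)) else NULL

        pal <- stats::runif(n) < c_$palindromicFrac
        al <- .pickAlleles(n, pal)
        eaf <- stats::runif(n, 0.05, 0.95)
        flipOut <- stats::runif(n) < c_$flipFrac
        flipMed <- stats::runif(n) < c_$flipFrac

        exposures <- lapply(seq_len(K), function(k)
            .traitTable(ids, al$ea, al$oa, eaf, trueExp[, k],
                        c_$seExposure, c_$nExposure, rep(FALSE, n)))
        names(exposures) <- sprintf("exposure%d", seq_len(K))
        outcome <- .traitTable(ids, al$ea, al$oa, eaf, trueOut,
                               c_$seOutcome, c_$nOutcome, flipOut)
        mediator <- if (!is.null(trueMed))
            .traitTable(ids, al$ea, al$oa, eaf, trueMed,
                        c_$seMediator, c_$nMediator, flipMed) else NULL

        ld <- if (is.null(c_$ldBlocks)) {
            makeLDMatrix(rep(1L, n), 0, snpIds = ids)
        } else {
            sizes <- c_$ldBlocks$sizes
            rest <- n - sum(sizes)
            if (rest < 0L) stop("ld blocks exceed the SNP panel")
            makeLDMatrix(c(sizes, rep(1L, rest)), c_$ldBlocks$r2,
                         snpIds = ids)
        }
        # within-r2 applies only to the leading blocks; trailing singleton
        # blocks are independent by construction

        truth <- list(
            seed = c_$seed, theta = thetaTotal,
            a = if (!is.null(chain)) chain$a else NA_real_,
            b = if (!is.null(chain)) chain$b else NA_real_,
            cPrime = if (!is.null(chain)) chain$cPrime else NA_real_,
            total = if (!is.null(chain))
                chain$a * chain$b + chain$cPrime else thetaTotal,
            gammas = gamma, gammaM = gammaM, alpha = alpha,
            instrumentIds = ivIds, mediatorInstrumentIds = mvIds,
            nullIds = nullIds)
        list(exposures = exposures, exposure = exposures[[1L]],
             mediator = mediator, outcome = outcome, ld = ld,
             truth = truth)
    })
}

#' Write a simulated dataset to a directory
#'
#' Emits each trait in the tab-separated summary-statistics dialect, the LD
#' matrix, and the ground-truth record as JSON (full precision, so truth
#' round-trips through serialization).
#'
#' @param sim result of [simulateSummaryStats()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimDataset <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(sim$exposures))
        writeSummaryStats(sim$exposures[[nm]],
                          file.path(dir, paste0(nm, ".tsv")))
    writeSummaryStats(sim$outcome, file.path(dir, "outcome.tsv"))
    if (!is.null(sim$mediator))
        writeSummaryStats(sim$mediator, file.path(dir, "mediator.tsv"))
    writeLDMatrix(sim$ld, file.path(dir, "ld.tsv"))
    writeSimTruth(sim$truth, file.path(dir, "truth.json"))
    invisible(dir)
}

#' Serialize / read back a simulation truth record
#'
#' @param truth the `truth` component of [simulateSummaryStats()] output.
#' @param path JSON file path.
#' @return for `writeSimTruth`, `path` invisibly; for `readSimTruth`, the
#'   truth list (matrices restored).
#' @export
writeSimTruth <- function(truth, path) {
    truth$gammasDim <- dim(truth$gammas)
    truth$gammas <- as.vector(truth$gammas)
    jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
    out <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!is.null(out$gammasDim) && length(out$gammasDim) == 2L)
        out$gammas <- matrix(out$gammas, nrow = out$gammasDim[1L])
    else if (!is.null(out$gammas))
        out$gammas <- matrix(out$gammas, ncol = 1L)
    out$gammasDim <- NULL
    out
}
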