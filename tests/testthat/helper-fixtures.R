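# Build a HarmonizedSet directly from effect vectors (skips the table I/O,
# for estimator-level tests).
hset <- function(bx, by, sx = rep(0.01, length(bx)),
                 sy = rep(0.05, length(bx)),
                 ids = sprintf("snp%03d", seq_along(bx))) {
    new("HarmonizedSet", snpIds = ids,
        betaExposure = bx, seExposure = sx,
        betaOutcome = by, seOutcome = sy,
        nDroppedPalindromic = 0L, nDroppedIncompatible = 0L)
}

# A harmonized exposure/outcome pair simulated under known truth, with no
# harmonization losses (instruments only, no palindromic or flipped rows)
# so every instrument SNP survives.
simPair <- function(seed, J = 30L, theta = 0.2, seOutcome = 0.05,
                    pleiotropy = list(mode = "none", magnitude = 0)) {
    sim <- simulateSummaryStats(simConfig(
        seed = seed, J = J, theta = theta, seOutcome = seOutcome,
        pleiotropy = pleiotropy, palindromicFrac = 0, flipFrac = 0))
    list(h = harmonize(sim$exposure, sim$outcome), truth = sim$truth)
}

# Deterministic study bundle: one exposure, three mediators (true
# exposure->mediator effects a), two outcomes, identity LD. Mediators have
# their own instruments; outcome effects follow the mediation chain
# outcome = (c' + sum a_m b_m) * gamma + b_m * gammaM_m + noise.
makeStudyBundle <- function(seed, a = c(m1 = 0.5, m2 = 0, m3 = 0.25),
                            b = c(m1 = 0.4, m2 = 0.3, m3 = 0.4),
                            cPrime = 0.05) {
    set.seed(seed)
    J <- 12L; JM <- 8L; JN <- 4L
    nm <- names(a)
    n <- J + JM * length(a) + JN
    ids <- sprintf("snp%03d", seq_len(n))
    ivE <- ids[1:J]
    ivM <- lapply(seq_along(a), function(m)
        ids[J + (m - 1L) * JM + seq_len(JM)])
    names(ivM) <- nm
    gamma <- rnorm(J, 0.1, 0.02)
    gammaM <- lapply(nm, function(m) rnorm(JM, 0.1, 0.02))
    names(gammaM) <- nm
    tab <- function(beta, se) {
        obs <- beta + rnorm(n, 0, se)
        p <- pmax(2 * pnorm(-abs(obs / se)), 1e-300)
        SummaryStats(data.frame(SNP = ids, EA = "A", OA = "G", EAF = 0.5,
                                BETA = obs, SE = se, P = p, N = 1e5))
    }
    trueExp <- c(gamma, rep(0, n - J))
    exposure <- tab(trueExp, 0.01)
    mediators <- lapply(nm, function(m) {
        t <- numeric(n)
        t[1:J] <- a[[m]] * gamma
        t[match(ivM[[m]], ids)] <- gammaM[[m]]
        tab(t, 0.01)
    })
    names(mediators) <- nm
    thetaTot <- cPrime + sum(a * b)
    trueOut <- numeric(n)
    trueOut[1:J] <- thetaTot * gamma
    for (m in nm) trueOut[match(ivM[[m]], ids)] <- b[[m]] * gammaM[[m]]
    outcomes <- list(out90 = tab(trueOut, 0.03),
                     out99 = tab(trueOut, 0.05))
    ld <- makeLDMatrix(rep(1L, n), 0, snpIds = ids)
    list(exposure = exposure, mediators = mediators,
         outcomes = outcomes, ld = ld,
         truth = list(a = a, b = b, cPrime = cPrime))
}

# bare MREstimate for assembling mediation inputs in tests
mkEst <- function(beta, se, method = "ivw_fixed", scale = "beta",
                  nSNPs = 5L) {
    new("MREstimate", method = method, beta = beta, se = se,
        ciLow = beta - 1.96 * se, ciHigh = beta + 1.96 * se,
        pval = 2 * stats::pnorm(-abs(beta / se)), nSNPs = nSNPs,
        orValue = NA_real_, orCiLow = NA_real_, orCiHigh = NA_real_,
        scale = scale)
}

# strand-ambiguous allele pair (test-local copy, independent of the package)
.isPal <- function(ea, oa) {
    paste0(pmin(ea, oa), pmax(ea, oa)) %in% c("AT", "CG")
}

# Canonical small summary table used by the I/O tests.
smallTable <- function() {
    data.frame(SNP = c("rs1", "rs2", "rs3"),
               EA = c("A", "G", "C"), OA = c("G", "T", "T"),
               EAF = c(0.30, 0.55, 0.12),
               BETA = c(0.10, -0.05, 0.02),
               SE = c(0.01, 0.02, 0.005),
               P = c(1e-12, 1e-9, 3e-8),
               N = c(10000, 10000, 9000),
               stringsAsFactors = FALSE)
}
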