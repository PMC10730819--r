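test_that("identical config and seed give byte-identical outputs", {
    cfg <- simConfig(seed = 77, J = 15, nNullSNPs = 5,
                     palindromicFrac = 0.2,
                     mediatorChain = list(a = 0.5, b = 0.4, cPrime = 0.1))
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeSimDataset(simulateSummaryStats(cfg), d1)
    writeSimDataset(simulateSummaryStats(cfg), d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
})

test_that("the generator does not disturb the session RNG", {
    set.seed(123)
    before <- .Random.seed
    invisible(simulateSummaryStats(simConfig(seed = 1, J = 5)))
    expect_identical(.Random.seed, before)
})

test_that("truth records round-trip through serialization", {
    sim <- simulateSummaryStats(simConfig(
        seed = 5, J = 8, mediatorChain = list(a = 0.5, b = 0.4,
                                              cPrime = 0.1)))
    tf <- withr::local_tempfile(fileext = ".json")
    writeSimTruth(sim$truth, tf)
    back <- readSimTruth(tf)
    expect_equal(back$gammas, sim$truth$gammas, tolerance = 1e-12)
    expect_equal(back$total, sim$truth$total)
    expect_identical(back$instrumentIds, sim$truth$instrumentIds)
    # the law of the total effect holds exactly in the truth record
    expect_identical(sim$truth$total,
                     sim$truth$a * sim$truth$b + sim$truth$cPrime)
})

test_that("LD matrix construction follows the block spec", {
    one <- makeLDMatrix(1, 0)
    expect_equal(one@r2, matrix(1, 1, 1, dimnames = list("snp001",
                                                         "snp001")))
    two <- makeLDMatrix(c(2, 2), 0.8)
    off <- two@r2[upper.tri(two@r2)]
    expect_identical(sum(off == 0.8), 2L)   # one pair inside each block
    expect_identical(sum(off == 0), 4L)
    expect_error(makeLDMatrix(c(2, 2), 1), "r2 must be in")
})

test_that("clumping a correlated block keeps exactly one SNP per block", {
    sim <- simulateSummaryStats(simConfig(
        seed = 9, J = 12, ldBlocks = list(sizes = c(4, 4), r2 = 0.6),
        palindromicFrac = 0, flipFrac = 0))
    kept <- clumpInstruments(sim$exposure, sim$ld, 0.1)
    ids <- snpIds(kept)
    blockOf <- function(id) {
        i <- as.integer(sub("snp", "", id))
        if (i <= 4) 1L else if (i <= 8) 2L else 2L + i
    }
    expect_identical(length(ids), 1L + 1L + 4L)  # one per block + singles
    expect_identical(anyDuplicated(vapply(ids, blockOf, integer(1))), 0L)
})

test_that("the mediator chain obeys the law of total effect in expectation", {
    tot <- vapply(1:200, function(s) {
        sim <- simulateSummaryStats(simConfig(
            seed = s, J = 20,
            mediatorChain = list(a = 0.5, b = 0.4, cPrime = 0.1),
            palindromicFrac = 0, flipFrac = 0))
        g <- sim$truth$gammas[, 1]
        iv <- match(sim$truth$instrumentIds, snpIds(sim$outcome))
        by <- asSummaryData(sim$outcome)$BETA[iv]
        # regression-free: project observed outcome effects on true gammas
        sum(g * by) / sum(g^2)
    }, numeric(1))
    mc <- sd(tot) / sqrt(length(tot))
    expect_lt(abs(mean(tot) - 0.3), 3 * mc)
})

test_that("wider outcome noise widens downstream IVW intervals", {
    width <- function(seOut) mean(vapply(1:20, function(s) {
        sp <- simPair(seed = s, J = 25, seOutcome = seOut)
        ci <- confInt(mrIVW(sp$h))
        ci[2] - ci[1]
    }, numeric(1)))
    expect_lt(width(0.02), width(0.08))
})

test_that("balanced pleiotropy leaves IVW and the Egger intercept centred; directional shifts the intercept", {
    runs <- function(mode, mag) {
        vapply(1:60, function(s) {
            sp <- simPair(seed = 400 + s, J = 60, theta = 0.2,
                          pleiotropy = list(mode = mode, magnitude = mag))
            eg <- mrEgger(sp$h)
            c(ivw = estimate(mrIVW(sp$h)), int = eg@intercept)
        }, numeric(2))
    }
    bal <- runs("balanced", 0.05)
    expect_lt(abs(mean(bal["ivw", ]) - 0.2),
              3 * sd(bal["ivw", ]) / sqrt(ncol(bal)))
    expect_lt(abs(mean(bal["int", ])),
              3 * sd(bal["int", ]) / sqrt(ncol(bal)))
    dir <- runs("directional", 0.05)
    expect_lt(abs(mean(dir["int", ]) - 0.05),
              3 * sd(dir["int", ]) / sqrt(ncol(dir)))
})

test_that("config validation rejects bad inputs", {
    expect_error(simConfig(seed = 1, J = 2, K = 2, theta = 0.2), "length K")
    expect_error(simConfig(seed = 1, pleiotropy = list(mode = "odd")),
                 "unknown pleiotropy")
    expect_error(simConfig(seed = 1,
                           mediatorChain = list(a = 1, b = 2), K = 1),
                 "cPrime")
    expect_error(simConfig(seed = 1, ldBlocks = list(sizes = 2, r2 = 1)),
                 "r2 must be in")
    expect_error(simulateSummaryStats(list(seed = 1)), "simConfig")
})
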