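test_that("summary statistics round-trip through write and read", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    x <- SummaryStats(smallTable())
    writeSummaryStats(x, tf)
    y <- readSummaryStats(tf)
    expect_equal(asSummaryData(y), asSummaryData(x), tolerance = 1e-12)
})

test_that("invalid rows are rejected with their line numbers", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    d <- smallTable()
    d$SE[2] <- 0
    utils::write.table(d, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_warning(x <- readSummaryStats(tf), "line 3.*se must be > 0")
    expect_equal(snpIds(x), c("rs1", "rs3"))
})

test_that("aliased headers via columnMap give identical records", {
    t1 <- withr::local_tempfile(fileext = ".tsv")
    t2 <- withr::local_tempfile(fileext = ".tsv")
    d <- smallTable()
    utils::write.table(d, t1, sep = "\t", quote = FALSE, row.names = FALSE)
    names(d) <- c("rsid", "a1", "a2", "freq", "b", "stderr", "pv", "size")
    utils::write.table(d, t2, sep = "\t", quote = FALSE, row.names = FALSE)
    canonical <- readSummaryStats(t1)
    mapped <- readSummaryStats(t2, columnMap = c(
        SNP = "rsid", EA = "a1", OA = "a2", EAF = "freq", BETA = "b",
        SE = "stderr", P = "pv", N = "size"))
    expect_identical(asSummaryData(mapped), asSummaryData(canonical))
})

test_that("reader errors are specific", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    d <- smallTable()
    d$BETA <- as.character(d$BETA); d$BETA[2] <- "xx"
    utils::write.table(d, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readSummaryStats(tf), "parse error.*BETA.*row\\(s\\) 3")
    d2 <- smallTable()[, -1]
    utils::write.table(d2, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readSummaryStats(tf), "configuration error.*SNP")
})

test_that("allele flip is applied and is an involution", {
    exp <- SummaryStats(data.frame(SNP = "rs1", EA = "A", OA = "G",
                                   EAF = 0.3, BETA = 0.10, SE = 0.02,
                                   P = 1e-9))
    outFlipped <- SummaryStats(data.frame(SNP = "rs1", EA = "G", OA = "A",
                                          EAF = 0.8, BETA = -0.05,
                                          SE = 0.01, P = 1e-4))
    h <- harmonize(exp, outFlipped)
    expect_equal(h@betaOutcome, 0.05)
    expect_identical(h@nDroppedPalindromic, 0L)
    # flipping the already-flipped record back restores the original effect
    d <- asSummaryData(outFlipped)
    d2 <- d
    d2$EA <- d$OA; d2$OA <- d$EA; d2$BETA <- -d$BETA; d2$EAF <- 1 - d$EAF
    h2 <- harmonize(exp, SummaryStats(d2))
    expect_equal(h2@betaOutcome, h@betaOutcome)
})

test_that("palindromic and incompatible SNPs are dropped and counted", {
    exp <- SummaryStats(data.frame(
        SNP = c("rs1", "rs2", "rs3"),
        EA = c("A", "A", "A"), OA = c("T", "G", "G"),
        BETA = c(0.1, 0.1, 0.1), SE = 0.01, P = 1e-9))
    out <- SummaryStats(data.frame(
        SNP = c("rs1", "rs2", "rs3"),
        EA = c("A", "A", "A"), OA = c("T", "C", "G"),
        BETA = c(0.05, 0.05, 0.05), SE = 0.01, P = 1e-4))
    h <- harmonize(exp, out)
    expect_identical(h@snpIds, "rs3")
    expect_identical(h@nDroppedPalindromic, 1L)   # rs1 is A/T
    expect_identical(h@nDroppedIncompatible, 1L)  # rs2: A/G vs A/C
})

test_that("harmonization accounting identity holds and it is idempotent", {
    set.seed(42)
    pairs <- list(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"),
                  c("A", "C"), c("G", "T"))
    n <- 40
    pick <- sample(length(pairs), n, replace = TRUE)
    ea <- vapply(pick, function(i) pairs[[i]][1], character(1))
    oa <- vapply(pick, function(i) pairs[[i]][2], character(1))
    exp <- SummaryStats(data.frame(
        SNP = sprintf("rs%02d", 1:n), EA = ea, OA = oa,
        BETA = rnorm(n, 0.1, 0.02), SE = 0.01, P = 1e-9))
    flip <- runif(n) < 0.5
    mismatch <- seq_len(n) %in% sample(n, 5)
    out <- data.frame(SNP = sprintf("rs%02d", 1:n),
                      EA = ifelse(flip, oa, ea), OA = ifelse(flip, ea, oa),
                      BETA = rnorm(n, 0.02, 0.05) * ifelse(flip, -1, 1),
                      SE = 0.05, P = 0.5)
    out$OA[mismatch & !.isPal(out$EA, out$OA)] <- "A"
    out$OA[out$EA == out$OA] <- "C"
    onlyExp <- SummaryStats(data.frame(SNP = "rsX", EA = "A", OA = "G",
                                       BETA = 0.1, SE = 0.01, P = 1e-9))
    exp2 <- SummaryStats(rbind(asSummaryData(exp), asSummaryData(onlyExp)))
    h <- harmonize(exp2, SummaryStats(out))
    shared <- sum(snpIds(exp2) %in% out$SNP)
    nIncompat <- h@nDroppedIncompatible
    expect_identical(length(h@snpIds) + h@nDroppedPalindromic +
                     nIncompat, shared)
    # idempotence: harmonizing the aligned pair changes nothing
    expd <- asSummaryData(exp2)
    expd <- expd[match(h@snpIds, expd$SNP), ]
    aligned <- data.frame(SNP = h@snpIds, EA = expd$EA, OA = expd$OA,
                          BETA = h@betaOutcome, SE = h@seOutcome, P = 0.5)
    h2 <- harmonize(SummaryStats(expd), SummaryStats(aligned))
    expect_identical(h2@snpIds, h@snpIds)
    expect_equal(h2@betaOutcome, h@betaOutcome)
    expect_identical(h2@nDroppedPalindromic, 0L)
    expect_identical(h2@nDroppedIncompatible, 0L)
})

test_that("harmonize refuses disjoint studies and duplicates are caught", {
    a <- SummaryStats(data.frame(SNP = "rs1", EA = "A", OA = "G",
                                 BETA = 0.1, SE = 0.01, P = 1e-9))
    b <- SummaryStats(data.frame(SNP = "rs2", EA = "A", OA = "G",
                                 BETA = 0.1, SE = 0.01, P = 1e-9))
    expect_error(harmonize(a, b), "no shared instruments")
    expect_error(SummaryStats(data.frame(
        SNP = c("rs1", "rs1"), EA = "A", OA = "G", BETA = 0.1,
        SE = 0.01, P = 1e-9)), "duplicated")
})

test_that("LD matrices round-trip and are validated", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    ld <- makeLDMatrix(c(2, 1), 0.5, snpIds = c("rs1", "rs2", "rs3"))
    writeLDMatrix(ld, tf)
    ld2 <- readLDMatrix(tf)
    expect_identical(snpIds(ld2), snpIds(ld))
    expect_equal(ld2@r2, ld@r2)
    bad <- matrix(c(1, 0.5, 0.4, 1), 2, 2)
    expect_error(LDMatrix(bad, c("a", "b")), "symmetric")
})
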