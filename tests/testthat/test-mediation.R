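# Published two-step MR decompositions of PM2.5 -> mediator -> longevity
# (direct effects A and B on the log-odds scale, as printed at 2-3
# significant figures) used as fixed arithmetic fixtures.
TAB <- data.frame(
    mediator = c("DBP", "hypertension", "hypertension",
                 "hypercholesterolaemia", "hypothyroidism",
                 "hypothyroidism", "AD", "AD"),
    pct = c("90th", "90th", "99th", "90th", "90th", "99th", "90th",
            "99th"),
    a = c(-2.65, 0.081, 0.081, 0.072, 0.092, 0.092, 0.48, 0.48),
    b = c(-0.068, -5.01, -5.70, -9.61, -3.69, -1.48, -0.29, -0.39),
    printed = c(0.18, -0.41, -0.46, -0.69, -0.34, -0.14, -0.14, -0.19),
    stringsAsFactors = FALSE)

test_that("product of printed coefficients reproduces the printed mediation effects", {
    for (i in seq_len(nrow(TAB))) {
        ie <- indirectEffect(TAB$a[i], 0.1, TAB$b[i], 0.1)
        expect_equal(round(ie$beta, 2), TAB$printed[i],
                     info = paste(TAB$mediator[i], TAB$pct[i]))
    }
    # rows the source computed from unrounded inputs: looser, +/-0.01
    loose <- data.frame(a = c(-2.65, 0.072, 0.045, 0.045),
                        b = c(-0.077, -13.13, -0.36, -0.39),
                        printed = c(0.21, -0.94, -0.014, -0.017))
    for (i in seq_len(nrow(loose)))
        expect_lt(abs(loose$a[i] * loose$b[i] - loose$printed[i]), 0.011)
})

test_that("indirect effect is symmetric, null at a = 0, and delta SE matches a Monte-Carlo oracle", {
    ab <- indirectEffect(0.3, 0.1, -0.5, 0.2)
    ba <- indirectEffect(-0.5, 0.2, 0.3, 0.1)
    expect_equal(ab$beta, ba$beta)
    expect_equal(ab$se, ba$se)
    z <- indirectEffect(0, 0.1, 0.7, 0.2)
    expect_equal(z$beta, 0)
    expect_equal(z$ciLow, -z$ciHigh)
    set.seed(99)
    draws <- rnorm(1e5, 0.3, 0.1) * rnorm(1e5, -0.5, 0.2)
    expect_lt(abs(ab$se - sd(draws)) / sd(draws), 0.10)
    expect_error(indirectEffect(0.3, 0, 0.5, 0.1), "must be > 0")
    expect_error(indirectEffect(0, 0.1, 0, 0.2), "degenerate")
})

test_that("mediated proportions match the printed percentages within rounding", {
    p1 <- mediatedProportion(0.18, 0.05, -0.57, 0.79)
    expect_lt(abs(p1$proportion - 31.48), 1.5)
    expect_true(p1$inconsistent)
    p2 <- mediatedProportion(-0.014, 0.006, -0.57, 0.79)
    expect_lt(abs(p2$proportion - 2.45), 1.5)
    expect_false(p2$inconsistent)
    # a ratio above 1 clips to exactly 100
    p3 <- mediatedProportion(-0.69, 0.34, -0.57, 0.79)
    expect_identical(p3$proportion, 100)
    expect_identical(p3$ciHigh, 100)
})

test_that("proportion CI propagates the indirect CI with clipping rules", {
    # indirect CI entirely one-signed: both bounds are |ratio| bounds
    se <- (0.74 - 0.070) / (2 * 1.96)
    p <- mediatedProportion(-0.405, se, -0.57, 0.79)
    expect_identical(p$ciHigh, 100)   # upper ratio exceeds the total
    expect_lt(abs(p$ciLow - 12.23), 2)
    # indirect CI spanning zero: the magnitude lower bound is 0
    p0 <- mediatedProportion(-0.34, 0.18, -0.57, 0.79)
    expect_identical(p0$ciLow, 0)
    expect_identical(p0$ciHigh, 100)
    # zero indirect effect gives 0%
    expect_equal(mediatedProportion(0, 0.1, -0.5, 0.1)$proportion, 0)
    expect_error(mediatedProportion(0.1, 0.1, 0, 0.1), "undefined")
    # the bivariate delta CI is available behind the flag
    pd <- mediatedProportion(0.2, 0.05, 0.5, 0.05, method = "delta")
    expect_true(pd$ciLow > 0 && pd$ciHigh < 100)
})

test_that("clipping preserves the ordering of proportions below 100", {
    set.seed(17)
    total <- -0.6
    ind <- runif(20, 0, 0.59)
    props <- vapply(ind, function(i)
        mediatedProportion(i, 0.05, total, 0.1)$proportion, numeric(1))
    expect_identical(order(props), order(ind / abs(total) * 100))
})

test_that("two-step assembly reproduces the hypertension row and enforces scale", {
    med <- twoStepMediation(mkEst(0.081, 0.033), mkEst(-5.01, 0.55),
                            mkEst(-0.57, 0.79))
    expect_equal(round(estimate(med), 2), -0.41)
    expect_equal(med@indirectBeta, med@aBeta * med@bBeta)
    expect_false(med@inconsistent)
    expect_identical(unname(med@provenance), rep("ivw_fixed", 3))
    z <- twoStepMediation(mkEst(0.081, 0.033), mkEst(0, 0.5),
                          mkEst(-0.57, 0.79))
    expect_equal(estimate(z), 0)
    expect_equal(z@proportion, 0)
    expect_error(
        twoStepMediation(mkEst(0.081, 0.033, scale = "or"),
                         mkEst(-5.01, 0.55), mkEst(-0.57, 0.79)),
        "scale mismatch")
    expect_warning(
        twoStepMediation(mkEst(-2.65, 0.68), mkEst(-0.068, 0.007),
                         mkEst(-0.57, 0.79)),
        "inconsistent mediation")
})
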