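test_that("Wald ratio arithmetic and first-order SE", {
    e <- waldRatio(0.05, 0.01, 0.10)
    expect_equal(estimate(e), 0.5)
    expect_equal(stdError(e), 0.1)
    expect_equal(estimate(waldRatio(0, 0.01, 0.10)), 0)
    expect_error(waldRatio(0.05, 0.01, 0), "degenerate")
})

test_that("first-order Wald SE agrees with the second-order delta form for strong instruments", {
    # second-order delta oracle includes the exposure uncertainty term
    secondOrderSE <- function(by, sy, bx, sx)
        sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
    set.seed(3)
    for (i in 1:20) {
        bx <- runif(1, 0.11, 0.3); sx <- 0.01   # F > 100
        by <- rnorm(1, 0.05, 0.02); sy <- runif(1, 0.005, 0.05)
        first <- stdError(waldRatio(by, sy, bx))
        second <- secondOrderSE(by, sy, bx, sx)
        expect_lt(abs(first - second) / second, 0.05)
    }
})

test_that("IVW reduces to the Wald ratio for one SNP and averages equal-weight ratios", {
    h1 <- hset(bx = 0.10, by = 0.05, sx = 0.01, sy = 0.01)
    expect_equal(estimate(mrIVW(h1)), estimate(waldRatio(0.05, 0.01, 0.10)))
    expect_equal(stdError(mrIVW(h1)), stdError(waldRatio(0.05, 0.01, 0.1)))
    h2 <- hset(bx = c(1, 1), by = c(0.4, 0.6), sy = c(0.05, 0.05))
    expect_equal(estimate(mrIVW(h2, mode = "fixed")), 0.5)
})

test_that("IVW is invariant to SNP order and joint sign flips; fixed se <= mre se", {
    sp <- simPair(seed = 21, J = 12)
    h <- sp$h
    base <- mrIVW(h, mode = "fixed")
    ord <- sample(length(h@snpIds))
    hshuf <- hset(h@betaExposure[ord], h@betaOutcome[ord],
                  h@seExposure[ord], h@seOutcome[ord], h@snpIds[ord])
    expect_equal(estimate(mrIVW(hshuf, mode = "fixed")), estimate(base))
    s <- rep(c(1, -1), length.out = length(h@snpIds))
    hflip <- hset(s * h@betaExposure, s * h@betaOutcome,
                  h@seExposure, h@seOutcome, h@snpIds)
    expect_equal(estimate(mrIVW(hflip, mode = "fixed")), estimate(base))
    expect_lte(stdError(base), stdError(mrIVW(h, mode = "mre")))
    expect_error(mrIVW(hset(c(0, 0), c(0.1, 0.2))), "degenerate")
})

test_that("weighted median reduces to the middle ratio and stays inside the ratio range", {
    h <- hset(bx = c(1, 1, 1), by = c(0.1, 0.5, 0.9),
              sy = c(0.05, 0.05, 0.05))
    wm <- weightedMedian(h, nBoot = 50, seed = 1)
    expect_equal(estimate(wm), 0.5)
    expect_identical(wm@method, "weighted_median")
    for (seed in 1:8) {
        sp <- simPair(seed = seed, J = 9)
        ratios <- sp$h@betaOutcome / sp$h@betaExposure
        est <- estimate(weightedMedian(sp$h, nBoot = 20, seed = seed))
        expect_gte(est, min(ratios))
        expect_lte(est, max(ratios))
    }
    expect_error(weightedMedian(hset(c(1, 1), c(0.1, 0.2)), seed = 1),
                 "insufficient")
})

test_that("weighted median equals a root-finding oracle on the cumulative weight function", {
    for (seed in 1:20) {
        set.seed(1000 + seed)
        J <- 5
        r <- sort(rnorm(J, 0.3, 0.4))
        w <- runif(J, 0.5, 2)
        s <- (cumsum(w) - w / 2) / sum(w)
        # independent oracle: invert the piecewise-linear cumulative weight
        # function by bisection instead of interpolation
        f <- approxfun(r, s, rule = 2)
        oracle <- uniroot(function(t) f(t) - 0.5, range(r),
                          tol = 1e-12)$root
        h <- hset(bx = rep(1, J), by = r, sy = 1 / sqrt(w))
        expect_equal(estimate(weightedMedian(h, nBoot = 10, seed = seed)),
                     oracle, tolerance = 1e-8)
    }
})

test_that("MR-Egger with the intercept forced to zero matches fixed-effect IVW", {
    sp <- simPair(seed = 5, J = 20)
    eg <- mrEgger(sp$h, forceNullIntercept = TRUE)
    expect_equal(estimate(eg@slope), estimate(mrIVW(sp$h, mode = "fixed")))
    expect_equal(eg@intercept, 0)
})

test_that("MR-Egger detects planted directional pleiotropy", {
    sp <- simPair(seed = 8, J = 100, theta = 0.2,
                  pleiotropy = list(mode = "directional", magnitude = 0.05))
    eg <- mrEgger(sp$h)
    expect_lt(abs(eg@intercept - 0.05), 2 * eg@interceptSE)
    expect_lt(abs(estimate(eg@slope) - 0.2), 2 * stdError(eg@slope))
    expect_error(mrEgger(hset(c(1, 1), c(0.1, 0.2))), "insufficient")
    expect_error(mrEgger(hset(rep(0.1, 5), rnorm(5))), "collinearity")
})

test_that("odds-ratio conversion is exp and round-trips", {
    or0 <- toOddsRatio(0, 0.1)
    expect_equal(or0$or, 1)
    expect_lt(or0$ci_low, 1); expect_gt(or0$ci_high, 1)
    or2 <- toOddsRatio(log(2), 1e-12)
    expect_equal(or2$or, 2, tolerance = 1e-9)
    expect_equal(log(toOddsRatio(0.123, 0.05)$or), 0.123)
    expect_error(toOddsRatio(0.1, 0), "se must be > 0")
})

test_that("the all-methods table carries one row per estimator", {
    sp <- simPair(seed = 13, J = 10)
    tab <- mrAllMethods(sp$h, seed = 2, nBoot = 50)
    expect_setequal(tab$method, c("ivw_mre", "weighted_median",
                                  "egger_slope", "egger_intercept"))
    expect_true(all(tab$n_snps == 10))
})
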