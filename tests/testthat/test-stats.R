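test_that("paired t matches stats::t.test and the closed form", {
    set.seed(101)
    for (i in 1:50) {
        n <- sample(3:20, 1)
        x <- rnorm(n); y <- rnorm(n)
        got <- pairedT(x, y)
        ref <- t.test(x, y, paired = TRUE)
        expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
        # symmetry under swapping the groups
        swp <- pairedT(y, x)
        expect_equal(swp$statistic, -got$statistic, tolerance = 1e-12)
        expect_equal(swp$p.value, got$p.value, tolerance = 1e-12)
    }
    # worked case: diffs (1, 1.2, 1.8)
    got <- pairedT(c(1, 1.2, 1.8), c(0, 0, 0))
    expect_equal(got$statistic, mean(c(1, 1.2, 1.8)) /
                     (sd(c(1, 1.2, 1.8)) / sqrt(3)), tolerance = 1e-12)
    expect_equal(got$p.value, 2 * pt(-abs(got$statistic), 2),
                 tolerance = 1e-12)
})

test_that("paired t degenerate rules are explicit, not NaN", {
    expect_equal(pairedT(c(1, 2, 3), c(1, 2, 3)),
                 list(statistic = 0, p.value = 1))
    up <- pairedT(c(2, 3, 4), c(1, 2, 3))      # constant +1 differences
    expect_equal(up$statistic, Inf)
    expect_equal(up$p.value, 0)
    dn <- pairedT(c(1, 2, 3), c(2, 3, 4))
    expect_equal(dn$statistic, -Inf)
    expect_error(pairedT(1, 2), "n >= 2")
})

test_that("rowPairedT agrees with per-row t.test on a matrix", {
    set.seed(5)
    d <- matrix(rnorm(200), nrow = 20)
    got <- rowPairedT(d)
    for (i in 1:20) {
        ref <- t.test(d[i, ])
        expect_equal(got$t[i], unname(ref$statistic), tolerance = 1e-10)
        expect_equal(got$p[i], ref$p.value, tolerance = 1e-10)
    }
})

test_that("signed-rank test is exact, ties included", {
    # all-positive differences at n = 5: 2 of 32 sign assignments
    got <- wilcoxonSignedRank(c(2, 3, 4, 5, 6), rep(1, 5))
    expect_equal(got$statistic, 15)
    expect_equal(got$p.value, 0.0625)
    # antisymmetric differences
    expect_equal(wilcoxonSignedRank(c(0, 2), c(1, 1))$p.value, 1)
    # all differences zero
    expect_equal(wilcoxonSignedRank(c(1, 2), c(1, 2)),
                 list(statistic = 0, p.value = 1, n.used = 0L))

    set.seed(202)
    for (i in 1:60) {
        n <- sample(3:10, 1)
        d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties likely
        got <- wilcoxonSignedRank(d, rep(0, n))
        expect_equal(got$p.value, enumSignedRankP(d), tolerance = 1e-12)
    }
    # no-tie cases also agree with stats::wilcox.test exact p
    for (i in 1:20) {
        n <- sample(4:12, 1)
        d <- rnorm(n)
        got <- wilcoxonSignedRank(d, rep(0, n))
        ref <- suppressWarnings(wilcox.test(d, exact = TRUE))
        expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
    }
})

test_that("signed-rank normal approximation tracks the exact tail", {
    set.seed(303)
    for (i in 1:10) {
        d <- rnorm(22, mean = 0.3)
        exact <- wilcoxonSignedRank(d, rep(0, 22))$p.value
        approx <- wilcoxonSignedRank(d, rep(0, 22), exact_max = 0L)$p.value
        expect_lt(abs(exact - approx), 0.01)
    }
})

test_that("rank-sum test matches enumeration and handles degenerate ties", {
    got <- wilcoxonRankSum(c(5, 6, 7), c(1, 2, 3))
    expect_equal(got$statistic, 9)
    expect_equal(got$p.value, 0.1)   # 2 * (1/20)
    expect_equal(wilcoxonRankSum(c(1, 1, 1), c(1, 1, 1))$p.value, 1)
    expect_error(wilcoxonRankSum(numeric(0), 1), "non-empty")

    set.seed(404)
    for (i in 1:40) {
        nx <- sample(2:8, 1); ny <- sample(2:8, 1)
        repeat {   # distinct values so the exact branch applies
            x <- round(rnorm(nx), 4); y <- round(rnorm(ny), 4)
            if (!anyDuplicated(c(x, y))) break
        }
        expect_equal(wilcoxonRankSum(x, y)$p.value, enumRankSumP(x, y),
                     tolerance = 1e-12)
    }
})

test_that("BH adjustment equals the step-up formula and p.adjust", {
    expect_equal(bhAdjust(c(0.001, 0.01, 0.02, 0.8)),
                 c(0.004, 0.02, 4 * 0.02 / 3, 0.8), tolerance = 1e-12)
    expect_equal(bhAdjust(0.4), 0.4)
    expect_equal(bhAdjust(rep(0.03, 10)), rep(0.03, 10))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

    set.seed(505)
    for (i in 1:30) {
        p <- runif(sample(c(3, 17, 100, 1000), 1))
        expect_equal(bhAdjust(p), stepUpBH(p), tolerance = 1e-12)
        # permutation invariance (up to reordering)
        o <- sample(length(p))
        expect_equal(bhAdjust(p[o]), bhAdjust(p)[o], tolerance = 1e-12)
    }
})

test_that("correlation test matches cor.test and flags zero variance", {
    set.seed(606)
    for (i in 1:25) {
        n <- sample(5:30, 1)
        x <- rnorm(n); y <- rnorm(n)
        got <- correlationTest(x, y)
        ref <- cor.test(x, y)
        expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
        expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
    }
    expect_equal(correlationTest(1:5, 1:5), list(r = 1, p.value = 0))
    expect_equal(correlationTest(1:5, 5:1)$r, -1)
    z <- correlationTest(rep(2, 5), rnorm(5))
    expect_true(is.na(z$r) && is.na(z$p.value))
})
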