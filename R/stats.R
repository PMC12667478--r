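## Statistical kernels used across the differential and funnel stages.
## Degenerate inputs follow explicit rules (stated in each function) so
## that all-zero regions and constant vectors never produce NaN p-values.

#' Paired t-test (closed form)
#'
#' Classical paired t on per-pair differences, two-sided p from the t
#' distribution with n-1 degrees of freedom. Degenerate rules: all
#' differences zero gives `(0, 1)`; zero variance with nonzero mean gives
#' `(sign * Inf, 0)`.
#'
#' @param x,y equal-length numeric vectors in pair order (n >= 2).
#' @return list with `statistic` (t) and `p.value`.
#' @examples
#' pairedT(c(2, 2.2, 2.8), c(1, 1, 1))
#' @export
pairedT <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 2L)
        stop("paired t requires n >= 2")
    res <- rowPairedT(matrix(x - y, nrow = 1L))
    list(statistic = res$t[1L], p.value = res$p[1L])
}

#' Row-wise paired t on a matrix of differences
#'
#' Vectorized paired t across many regions: each row of `d` holds one
#' region's per-pair differences. Degenerate rows follow [pairedT()]'s
#' rules.
#'
#' @param d numeric matrix, regions x pairs (>= 2 columns).
#' @return list of numeric vectors `t` and `p`, one entry per row.
#' @export
rowPairedT <- function(d) {
    d <- as.matrix(d)
    n <- ncol(d)
    if (n < 2L)
        stop("paired t requires n >= 2")
    m <- rowMeans(d)
    ss <- rowSums(d * d) - n * m * m
    ss[ss < 0] <- 0              # numerical guard
    s <- sqrt(ss / (n - 1L))
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
    zero_sd <- s == 0
    t[zero_sd & m == 0] <- 0
    p[zero_sd & m == 0] <- 1
    t[zero_sd & m != 0] <- sign(m[zero_sd & m != 0]) * Inf
    p[zero_sd & m != 0] <- 0
    list(t = t, p = p)
}

#' Wilcoxon signed-rank test
#'
#' Paired two-sided Wilcoxon signed-rank test. Zero differences are
#' dropped; ties receive mid-ranks. For up to 25 remaining pairs the
#' two-sided p is exact, computed from the full signed-rank distribution
#' (a generating-function convolution over doubled ranks, so mid-ranks are
#' handled exactly); above that a normal approximation with tie and
#' continuity corrections is used. All differences zero gives `(0, 1)`.
#'
#' @param x,y equal-length numeric vectors in pair order.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (W, sum of positive ranks), `p.value`,
#'   and `n.used` (pairs after dropping zeros).
#' @examples
#' wilcoxonSignedRank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))  # p = 0.0625
#' @export
wilcoxonSignedRank <- function(x, y, exact_max = 25L) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
        return(list(statistic = 0, p.value = 1, n.used = 0L))
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    if (n <= exact_max) {
        r2 <- as.integer(round(2 * r))
        tot <- sum(r2)
        f <- numeric(tot + 1L)
        f[1L] <- 1
        for (ri in r2) {
            g <- f
            g[(ri + 1L):(tot + 1L)] <- g[(ri + 1L):(tot + 1L)] +
                f[seq_len(tot + 1L - ri)]
            f <- g
        }
        f <- f / sum(f)
        w2 <- as.integer(round(2 * W))
        p_le <- sum(f[seq_len(w2 + 1L)])
        p_ge <- sum(f[(w2 + 1L):(tot + 1L)])
        p <- min(1, 2 * min(p_le, p_ge))
    } else {
        mu <- n * (n + 1) / 4
        tie_tab <- table(abs(d))
        sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(tie_tab^3 - tie_tab) / 48
        if (sigma2 <= 0) {
            p <- 1
        } else {
            z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
            p <- min(1, 2 * stats::pnorm(-abs(z)))
        }
    }
    list(statistic = W, p.value = p, n.used = n)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test of two independent groups. Exact p when both
#' groups have at most `exact_max` observations and there are no ties;
#' otherwise a normal approximation with tie and continuity corrections.
#' Two identical constant groups give p = 1.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max per-group size limit for the exact branch.
#' @return list with `statistic` (U for group `x`) and `p.value`.
#' @examples
#' wilcoxonRankSum(c(5, 6, 7), c(1, 2, 3))  # U = 9, p = 0.1
#' @export
wilcoxonRankSum <- function(x, y, exact_max = 12L) {
    nx <- length(x); ny <- length(y)
    if (nx == 0L || ny == 0L)
        stop("both groups must be non-empty")
    r <- rank(c(x, y))
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    ties <- anyDuplicated(c(x, y)) > 0L
    if (!ties && nx <= exact_max && ny <= exact_max) {
        p <- if (U > nx * ny / 2)
            2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
        else
            2 * stats::pwilcox(U, nx, ny)
        p <- min(1, p)
    } else {
        N <- nx + ny
        mu <- nx * ny / 2
        tie_tab <- table(r)
        sigma2 <- nx * ny / 12 *
            ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
        if (sigma2 <= 0) {
            p <- 1
        } else {
            z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
            p <- min(1, 2 * stats::pnorm(-abs(z)))
        }
    }
    list(statistic = U, p.value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] after validating the input).
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs not allowed).
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(pvals) {
    if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

#' Correlation with a two-sided p-value
#'
#' Pearson (default) or Spearman correlation with the t-transform p-value
#' (df = n - 2). A zero-variance vector yields `r = NA`, `p = NA` (callers
#' treat such pairs as failing, with a flag, rather than erroring).
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` and `p.value`.
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    n <- length(x)
    if (n != length(y))
        stop("x and y must have equal length")
    if (n < 3L)
        stop("correlation test requires n >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(r = NA_real_, p.value = NA_real_))
    if (method == "spearman") {
        x <- rank(x); y <- rank(y)
    }
    r <- stats::cor(x, y)
    if (abs(r) >= 1) {
        p <- 0
    } else {
        tstat <- r * sqrt((n - 2) / (1 - r * r))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    list(r = r, p.value = p)
}
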