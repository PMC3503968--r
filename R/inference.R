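#' Uniform test-result record
#'
#' All tests in the package return a list of class `TestResult` carrying the
#' statistic, one- and two-sided p-values, degrees of freedom where they
#' apply, and a direction label.
#'
#' @param method character label.
#' @param statistic numeric statistic (>= 0 for the chi-square family).
#' @param p_one_sided,p_two_sided p-values in [0, 1] (NA when undefined).
#' @param df degrees of freedom or NA.
#' @param direction direction label (e.g. `"row1_greater"`) or NA.
#' @param extra optional named list merged into the record.
#' @return list of class `TestResult`.
#' @keywords internal
testResult <- function(method, statistic, p_one_sided, p_two_sided,
                       df = NA_real_, direction = NA_character_,
                       extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p_one_sided = p_one_sided, p_two_sided = p_two_sided,
                   df = df, direction = direction), extra),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, df = %s\n  p (one-sided) = %.4g, p (two-sided) = %.4g, direction: %s\n",
              x$method, x$statistic,
              ifelse(is.na(x$df), "-", format(x$df)),
              x$p_one_sided, x$p_two_sided, x$direction))
  invisible(x)
}

.check2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0) || anyNA(tab))
    stopf("need a 2x2 table of nonnegative counts")
  tab
}

#' Yates continuity-corrected chi-square test for a 2x2 table
#'
#' Statistic sum over cells of (max(0, |o - e| - 1/2))^2 / e on 1 df.  The
#' one-sided p-value follows the direction-gated halving convention: half
#' the two-sided p when the observed association direction matches the
#' alternative, 1 minus that half otherwise.
#'
#' @param tab 2x2 count table (no zero margins).
#' @param alternative `"auto"` (the observed direction), `"row1_greater"`
#'   or `"row1_less"`: whether row 1 is tested for a greater or smaller
#'   success proportion (first column) than row 2.
#' @return a `TestResult`.
#' @examples
#' yatesChisq2x2(rbind(c(18, 48), c(38, 28)))   # statistic ~ 11.2
#' @export
yatesChisq2x2 <- function(tab, alternative = c("auto", "row1_greater",
                                               "row1_less")) {
  alternative <- match.arg(alternative)
  tab <- .check2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("zero margin in the 2x2 table")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(pmax(0, abs(tab - e) - 0.5)^2 / e)
  p2 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  obsdir <- if (tab[1, 1] >= e[1, 1]) "row1_greater" else "row1_less"
  want <- if (alternative == "auto") obsdir else alternative
  p1 <- if (obsdir == want) p2 / 2 else 1 - p2 / 2
  testResult("Yates chi-square (2x2)", stat, p1, p2, df = 1,
             direction = obsdir)
}

#' Yates-corrected goodness of fit of two counts to a fixed ratio
#'
#' @param counts length-2 nonnegative counts with positive total.
#' @param ratio expected ratio, default `c(1, 1)`.
#' @return a `TestResult` (1 df); direction reports which count exceeds its
#'   expectation.
#' @examples
#' chisqRatioGof(c(30, 10))   # statistic 9.025
#' @export
chisqRatioGof <- function(counts, ratio = c(1, 1)) {
  stopifnot(length(counts) == 2L, all(counts >= 0), length(ratio) == 2L,
            all(ratio > 0))
  N <- sum(counts)
  if (N == 0) stopf("zero total count")
  e <- N * ratio / sum(ratio)
  stat <- sum(pmax(0, abs(counts - e) - 0.5)^2 / e)
  p2 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  obsdir <- if (counts[1] >= e[1]) "first_greater" else "first_less"
  testResult("Yates chi-square goodness of fit", stat, p2 / 2, p2, df = 1,
             direction = obsdir)
}

#' One-sided Fisher exact test for a 2x2 table
#'
#' Hypergeometric tail probability of the observed table in the requested
#' direction (with `"auto"`, the direction in which the observed top-left
#' cell deviates from its expectation under fixed margins).
#'
#' @param tab 2x2 count table.
#' @param alternative `"auto"`, `"greater"` or `"less"` (tail for the
#'   top-left cell).
#' @return a `TestResult`; `statistic` is the observed top-left count.
#' @export
fisherExactOneSided <- function(tab, alternative = c("auto", "greater",
                                                     "less")) {
  alternative <- match.arg(alternative)
  tab <- .check2x2(tab)
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  e <- r1 * c1 / max(N, 1)
  obsdir <- if (a >= e) "greater" else "less"
  want <- if (alternative == "auto") obsdir else alternative
  p <- if (want == "greater")
    stats::phyper(a - 1, c1, N - c1, r1, lower.tail = FALSE)
  else
    stats::phyper(a, c1, N - c1, r1)
  p <- min(1, p)
  testResult("Fisher exact (one-sided)", a, p, NA_real_,
             direction = want)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The single-proportion interval recommended by Newcombe: the two roots of
#' the score equation (phat - p)^2 = z^2 p (1 - p) / n.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`; always contains k/n.
#' @export
newcombeWilsonCi <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - half), upper = min(1, ctr + half))
}

#' Holm step-down multiple-testing correction (sequential Bonferroni)
#'
#' Sorts the m p-values ascending and rejects while
#' p_(i) <= alpha / (m - i + 1); adjusted p-values are the running maximum
#' of (m - i + 1) p_(i), capped at 1.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param alpha rejection level (default 0.05).
#' @return list with `adjusted` (same order as input) and `reject` (logical).
#' @export
holmAdjust <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stopf("empty p-value list")
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  o <- order(pvals)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * pvals[o]))
  out <- numeric(m)
  out[o] <- adj
  list(adjusted = out, reject = out <= alpha)
}

#' One-way fixed-effects ANOVA with Tukey HSD post-hoc comparisons
#'
#' Self-contained sums-of-squares decomposition; the F p-value comes from
#' the F distribution and pairwise comparisons use the studentized-range
#' distribution at the within-group degrees of freedom (honest significant
#' differences for possibly unbalanced groups via the Tukey-Kramer
#' standard error).
#'
#' @param values numeric observations.
#' @param groups factor (or coercible) of group membership; alternatively
#'   pass `values` as a list of numeric vectors and omit `groups`.
#' @param level confidence level for the Tukey intervals.
#' @return list with `anova` (data.frame: ss, df, ms, f, p for between /
#'   within rows) and `tukey` (data.frame of pairwise differences with
#'   intervals and adjusted p-values).
#' @examples
#' onewayAnovaTukey(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8)))
#' @export
onewayAnovaTukey <- function(values, groups = NULL, level = 0.95) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  k <- nlevels(groups)
  if (k < 2L) stopf("need at least 2 groups")
  ni <- tabulate(groups)
  if (any(ni < 2L)) stopf("every group needs at least 2 observations")
  N <- length(values)
  gm <- mean(values)
  mi <- tapply(values, groups, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((values - mi[groups])^2)
  dfb <- k - 1L
  dfw <- N - k
  msw <- ssw / dfw
  f <- if (msw > 0) (ssb / dfb) / msw else ifelse(ssb > 0, Inf, 0)
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  anova <- data.frame(source = c("between", "within"),
                      ss = c(ssb, ssw), df = c(dfb, dfw),
                      ms = c(ssb / dfb, msw), f = c(f, NA),
                      p = c(p, NA))
  pairs <- utils::combn(levels(groups), 2)
  tukey <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    d <- mi[[g2]] - mi[[g1]]
    se <- sqrt(msw / 2 * (1 / ni[match(g1, levels(groups))] +
                            1 / ni[match(g2, levels(groups))]))
    q <- if (se > 0) abs(d) / se else ifelse(d == 0, 0, Inf)
    pj <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
    hw <- stats::qtukey(level, k, dfw) * se
    data.frame(group1 = g1, group2 = g2, diff = d,
               lower = d - hw, upper = d + hw, p_adj = pj)
  }))
  list(anova = anova, tukey = tukey)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance
#' from simultaneous random row/column permutations of the second matrix.
#' The identity permutation is included in the reference set, so the
#' permutation p-value is at least 1/(nPerm + 1).  With `exact = TRUE`
#' (feasible up to about 7 taxa) all n! permutations are enumerated
#' instead.
#'
#' @param d1,d2 symmetric matrices with identical labels, zero diagonal.
#' @param nPerm number of random permutations (ignored when `exact`).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all permutations instead of sampling.
#' @return a `TestResult` with `statistic` = the veridical correlation r;
#'   one-sided p is the upper tail (r as large or larger), two-sided uses
#'   |r|.
#' @export
mantelTest <- function(d1, d2, nPerm = 9999, seed = NULL, exact = FALSE) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dimnames(d1), dimnames(d2)) || is.null(rownames(d1)))
    stopf("distance matrices must carry identical labels")
  if (!isSymmetric(unname(d1)) || !isSymmetric(unname(d2)) ||
      any(diag(d1) != 0) || any(diag(d2) != 0))
    stopf("distance matrices must be symmetric with zero diagonal")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  r0 <- stats::cor(d1[lt], d2[lt])
  rOf <- function(perm) {
    dp <- d2[perm, perm]
    stats::cor(d1[lt], dp[lt])
  }
  rs <- if (exact) {
    perms <- .allPermutations(n)
    vapply(perms, rOf, numeric(1))
  } else {
    if (nPerm < 1) stopf("nPerm must be >= 1")
    withSeed(seed, c(r0, vapply(seq_len(nPerm), function(i)
      rOf(sample.int(n)), numeric(1))))
  }
  eps <- 1e-12
  p1 <- mean(rs >= r0 - eps)
  p2 <- mean(abs(rs) >= abs(r0) - eps)
  testResult("Mantel permutation test", r0, p1, p2,
             direction = if (r0 >= 0) "positive" else "negative",
             extra = list(n_perm = length(rs) - !exact))
}

.allPermutations <- function(n) {
  if (n > 8L) stopf("exact enumeration limited to 8 taxa")
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}
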