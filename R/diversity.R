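#' Configuration for dominant-marker diversity estimation
#'
#' @param fis inbreeding coefficient in [0, 1]; the default 1 (full selfing)
#'   makes every individual homozygous, so the probability of the
#'   band-absence phenotype equals the null-allele frequency itself.
#' @param priorMode `"moment_fitted"` (Beta prior fitted by the method of
#'   moments to the among-locus absence fractions) or `"uniform"` (Beta(1,1)).
#' @param threshold polymorphism threshold in (0, 0.5]; a locus is counted
#'   polymorphic when its minor estimated allele frequency reaches it
#'   (default 0.05, the conventional "5% level").
#' @return list of class `DiversityConfig`.
#' @export
diversityConfig <- function(fis = 1,
                            priorMode = c("moment_fitted", "uniform"),
                            threshold = 0.05) {
  priorMode <- match.arg(priorMode)
  stopifnot(fis >= 0, fis <= 1, threshold > 0, threshold <= 0.5)
  structure(list(fis = fis, priorMode = priorMode, threshold = threshold),
            class = "DiversityConfig")
}

#' Method-of-moments Beta prior for null-allele frequencies
#'
#' Fits Beta(a, b) so that its mean and variance reproduce the among-locus
#' mean m and variance v of the observed absence fractions:
#' a = m (m(1-m)/v - 1), b = (1-m) (m(1-m)/v - 1).  Falls back to the
#' uniform Beta(1, 1) when the fit is degenerate (v = 0, v >= m(1-m), or a
#' non-positive parameter).
#'
#' @param absenceFreqs per-locus observed absence fractions (>= 2 values).
#' @return named numeric `c(a, b)`.
#' @export
fitBetaPrior <- function(absenceFreqs) {
  if (length(absenceFreqs) < 2L)
    stopf("need at least 2 loci to fit a prior")
  m <- mean(absenceFreqs)
  v <- stats::var(absenceFreqs)
  uniform <- c(a = 1, b = 1)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m)) return(uniform)
  k <- m * (1 - m) / v - 1
  a <- m * k
  b <- (1 - m) * k
  if (a <= 0 || b <= 0) return(uniform)
  c(a = a, b = b)
}

#' Bayesian null-allele frequency from dominant phenotype counts
#'
#' Posterior-mean estimate of the recessive (band-absence) allele frequency
#' q from the number of accessions lacking the band.  With `fis = 1` every
#' individual is homozygous, the absence phenotype has probability q, and
#' the posterior under a Beta(a, b) prior is Beta(a + nAbsent, b + n -
#' nAbsent), giving the closed form (nAbsent + a) / (n + a + b).  For
#' `fis < 1` the absence phenotype has probability q^2 + fis q(1-q) and the
#' posterior mean is computed by numerical integration.
#'
#' @param nAbsent number of accessions without the band (vectorised).
#' @param n sample size (>= 1).
#' @param prior numeric `c(a, b)` Beta prior parameters.
#' @param fis inbreeding coefficient in [0, 1].
#' @return estimate(s) strictly inside (0, 1).
#' @examples
#' bayesNullFreq(5, 5)             # 6/7
#' bayesNullFreq(4, 10, c(2, 2))   # 6/14
#' @export
bayesNullFreq <- function(nAbsent, n, prior = c(1, 1), fis = 1) {
  stopifnot(n >= 1, all(nAbsent >= 0), all(nAbsent <= n),
            length(prior) == 2L, all(prior > 0))
  a <- prior[[1]]; b <- prior[[2]]
  if (fis == 1)
    return((nAbsent + a) / (n + a + b))
  vapply(nAbsent, function(x) {
    f <- function(q) {
      th <- q^2 + fis * q * (1 - q)
      stats::dbeta(q, a, b) * th^x * (1 - th)^(n - x)
    }
    z <- stats::integrate(function(q) f(q), 0, 1)$value
    stats::integrate(function(q) q * f(q), 0, 1)$value / z
  }, numeric(1))
}

#' Per-taxon dominant-marker diversity profile for one TE family
#'
#' Estimates, within one taxon, the per-locus null-allele frequencies
#' (via [bayesNullFreq()] with a per-taxon prior), Nei's gene diversity
#' H = mean over loci of 2 q(1-q) with its standard error over loci, the
#' proportion of loci polymorphic at the configured threshold, and the
#' band count (loci present in at least one accession of the taxon).
#' Loci absent from every accession of the whole matrix are excluded;
#' loci monomorphic for presence contribute absence fraction 0 to the
#' prior fit.
#'
#' @param m a [MarkerMatrix-class].
#' @param scheme a [TaxonScheme-class].
#' @param taxon taxon label with >= 2 accessions.
#' @param cfg a [diversityConfig()].
#' @return list of class `DiversityEstimate`: `taxon`, `teFamily`,
#'   `nAccessions`, `nBands`, `qhat` (named per locus), `H`, `HSe`,
#'   `polymorphicFraction`, `prior`, and the estimator note that H is
#'   reported as expected heterozygosity even under full inbreeding.
#' @export
neiDiversityProfile <- function(m, scheme, taxon, cfg = diversityConfig()) {
  stopifnot(is(m, "MarkerMatrix"), is(scheme, "TaxonScheme"))
  acc <- accessionsOf(scheme, taxon)
  if (length(acc) < 2L)
    stopf("taxon '%s' has %d accession(s); need >= 2 for diversity estimation",
          taxon, length(acc))
  calls <- markerCalls(m)
  keep <- rowSums(calls) > 0L
  calls <- calls[keep, acc, drop = FALSE]
  n <- length(acc)
  nAbsent <- n - rowSums(calls)
  prior <- switch(cfg$priorMode,
                  uniform = c(a = 1, b = 1),
                  moment_fitted = fitBetaPrior(nAbsent / n))
  qhat <- bayesNullFreq(nAbsent, n, prior, cfg$fis)
  names(qhat) <- rownames(calls)
  Hj <- 2 * qhat * (1 - qhat)
  L <- length(Hj)
  structure(list(
    taxon = taxon, teFamily = teFamily(m), nAccessions = n,
    nBands = sum(rowSums(calls) > 0L),
    qhat = qhat,
    H = mean(Hj),
    HSe = if (L > 1L) stats::sd(Hj) / sqrt(L) else 0,
    polymorphicFraction = mean(pmin(qhat, 1 - qhat) >= cfg$threshold),
    prior = prior,
    note = "H reported as expected heterozygosity 2q(1-q), the dominant-marker convention, irrespective of fis"),
    class = "DiversityEstimate")
}

#' @export
print.DiversityEstimate <- function(x, ...) {
  cat(sprintf(
    "DiversityEstimate %s / %s: %d bands over %d accessions\n  H = %.4f (SE %.4f), polymorphic fraction %.3f\n",
    x$teFamily, x$taxon, x$nBands, x$nAccessions, x$H, x$HSe,
    x$polymorphicFraction))
  invisible(x)
}

#' Diversity table across taxa and TE families
#'
#' Convenience wrapper applying [neiDiversityProfile()] to every declared
#' taxon of every matrix, returning one row per (TE family, taxon).
#'
#' @param matrices list of [MarkerMatrix-class] objects.
#' @param scheme a [TaxonScheme-class].
#' @param cfg a [diversityConfig()].
#' @return data.frame with band counts, polymorphic fractions and H +/- SE.
#' @export
diversityTable <- function(matrices, scheme, cfg = diversityConfig()) {
  rows <- list()
  for (m in matrices) for (tx in taxonNames(scheme)) {
    d <- neiDiversityProfile(m, scheme, tx, cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      te = d$teFamily, taxon = tx, n_accessions = d$nAccessions,
      n_bands = d$nBands, polymorphic_fraction = d$polymorphicFraction,
      H = d$H, H_se = d$HSe)
  }
  do.call(rbind, rows)
}
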