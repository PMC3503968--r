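#' Parameters for the allopolyploid SSAP simulator
#'
#' Defines an explicit model of dominant-marker evolution in an
#' allopolyploid complex: two diploid progenitor taxa carrying shared and
#' taxon-specific insertions, a polyploid subtree in which the first taxon
#' diverges before the remaining two (((B, C), A) with branches
#' `anc` (origin to the first split), `first` (to the first-diverging
#' taxon), `inner` (to the ancestor of the other two), and one terminal
#' branch per remaining taxon), whole-locus band losses with a paternal
#' bias, and gains of brand-new loci (novel insertion junctions are
#' locus-specific, so gains never recreate lost loci).
#'
#' Within-taxon segregation: every locus carried by a taxon receives a
#' presence-allele frequency drawn from `freqBeta`; under full selfing
#' (F_IS = 1) each accession is a homozygous carrier with that probability.
#' Sampling is conditioned on at least one carrier per taxon carrying the
#' locus, since an SSAP band only exists in the data when observed — this
#' keeps taxon-level presence identical to the generating band sets, so in
#' the no-event limit (all loss rates and gain means zero) the polyploids
#' are exactly additive.
#'
#' @param families data.frame with one row per TE family: columns `te`,
#'   `nShared`, `nMaternal`, `nPaternal` (ancestral parental locus counts),
#'   `gainMean` (Poisson mean of gains per branch) and `burst` (multiplier
#'   applied to `gainMean` on the ancestral branch).  The default
#'   reproduces the parental locus structure and qualitative gain/loss
#'   contrasts of the seven surveyed TE families.
#' @param lossRates named per-branch loss probabilities
#'   (`anc`, `first`, `inner`, plus one per non-first polyploid).
#' @param paternalBias probability that a loss among parent-specific bands
#'   hits a band of paternal origin.
#' @param freqBeta length-2 Beta parameters of the presence-allele
#'   frequency distribution.
#' @param accessionsPerTaxon named integer vector (maternal, paternal, then
#'   polyploids).
#' @param maternal,paternal,polys taxon labels; the first polyploid is the
#'   early-diverging one.
#' @param seed integer seed.
#' @return list of class `SimulationParams`.
#' @export
simulationParams <- function(
    families = data.frame(
      te       = c("Au", "TS", "Ns1", "Nt2", "Tnt1", "Tnt2", "TRIM"),
      nShared  = c(15, 2, 10, 8, 3, 5, 11),
      nMaternal = c(35, 13, 38, 15, 22, 39, 25),
      nPaternal = c(37, 15, 18, 35, 31, 19, 30),
      gainMean = c(1, 4, 2.5, 3.5, 2.5, 4, 1),
      burst    = c(2, 3, 1.5, 1, 1, 3, 2)),
    lossRates = c(anc = 0.40, first = 0.10, inner = 0.06,
                  REP = 0.12, ISL = 0.08),
    paternalBias = 0.6,
    freqBeta = c(4, 1),
    accessionsPerTaxon = c(SYL = 4, TRI = 6, NUD = 5, REP = 6, ISL = 4),
    maternal = "SYL", paternal = "TRI",
    polys = c("NUD", "REP", "ISL"),
    seed = 1L) {
  stopifnot(all(c("te", "nShared", "nMaternal", "nPaternal", "gainMean",
                  "burst") %in% names(families)),
            all(families[-1] >= 0), length(polys) == 3L,
            paternalBias >= 0, paternalBias <= 1,
            all(lossRates >= 0 & lossRates <= 1),
            length(freqBeta) == 2L, all(freqBeta > 0))
  branchNames <- c("anc", "first", "inner", polys[2], polys[3])
  if (!all(branchNames %in% names(lossRates)))
    stopf("lossRates must name branches: %s",
          paste(branchNames, collapse = ", "))
  need <- c(maternal, paternal, polys)
  if (!all(need %in% names(accessionsPerTaxon)))
    stopf("accessionsPerTaxon must name every taxon")
  structure(list(families = families, lossRates = lossRates[branchNames],
                 paternalBias = paternalBias, freqBeta = freqBeta,
                 accessionsPerTaxon = accessionsPerTaxon,
                 maternal = maternal, paternal = paternal, polys = polys,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

## zero-truncated binomial carrier counts, vectorised over p
.truncBinom <- function(nAcc, p) {
  k <- stats::rbinom(length(p), nAcc, p)
  while (any(k == 0L))
    k[k == 0L] <- stats::rbinom(sum(k == 0L), nAcc, p[k == 0L])
  k
}

#' Simulate SSAP-like marker matrices with a replayable truth log
#'
#' Runs the model described in [simulationParams()]: builds parental band
#' sets, forms the polyploid ancestor as their union, applies per-branch
#' losses (biased toward paternal-origin bands among parent-specific ones)
#' and gains of brand-new loci along the polyploid subtree, then samples
#' accession-level presence under full selfing.  Identical seeds give
#' identical output.
#'
#' @param params a [simulationParams()] object.
#' @return list of class `SimulationTruth` with `matrices` (named list of
#'   [MarkerMatrix-class]), `scheme` (a [TaxonScheme-class]), `params`, and
#'   `log` — a data.frame per locus: family, locus id, origin class, gain
#'   branch, loss branches, and final per-taxon presence.
#' @export
simulateDataset <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  withSeed(params$seed, .simulateDataset(params))
}

.simulateDataset <- function(params) {
  polys <- params$polys
  taxa <- c(params$maternal, params$paternal, polys)
  nAcc <- params$accessionsPerTaxon[taxa]
  accIds <- unlist(lapply(taxa, function(tx)
    paste0(tolower(tx), seq_len(nAcc[[tx]]))))
  taxonOf <- stats::setNames(rep(taxa, nAcc[taxa]), accIds)
  scheme <- TaxonScheme(taxonOf, params$maternal, params$paternal, polys)

  matrices <- list()
  logs <- list()
  for (i in seq_len(nrow(params$families))) {
    fam <- params$families[i, ]
    nS <- fam$nShared; nM <- fam$nMaternal; nP <- fam$nPaternal
    origin <- rep(c("shared_parental", "maternal_specific",
                    "paternal_specific"), c(nS, nM, nP))
    locus <- sprintf("%s_L%03d", fam$te, seq_along(origin))
    gainBranch <- rep(NA_character_, length(origin))

    ## taxon-level band sets; diploids are static
    sets <- list()
    sets[[params$maternal]] <- which(origin != "paternal_specific")
    sets[[params$paternal]] <- which(origin != "maternal_specific")
    lossLog <- rep("", length(origin))

    ## walk the polyploid subtree; `carry` is the band set entering a branch
    applyBranch <- function(branch, carry) {
      lam <- params$lossRates[[branch]]
      lost <- integer(0)
      if (lam > 0 && length(carry)) {
        st <- origin[carry]
        spec <- carry[st %in% c("maternal_specific", "paternal_specific")]
        rest <- carry[!carry %in% spec]      # shared parental + gained
        lost <- rest[stats::runif(length(rest)) < lam]
        nL <- stats::rbinom(1L, length(spec), lam)
        if (nL > 0L) {
          patPool <- spec[origin[spec] == "paternal_specific"]
          matPool <- spec[origin[spec] == "maternal_specific"]
          wantPat <- sum(stats::runif(nL) < params$paternalBias)
          takeP <- min(wantPat, length(patPool))
          takeM <- min(nL - takeP, length(matPool))
          pick <- c(if (takeP) patPool[sample.int(length(patPool), takeP)],
                    if (takeM) matPool[sample.int(length(matPool), takeM)])
          lost <- c(lost, pick)
        }
      }
      if (length(lost))
        lossLog[lost] <<- ifelse(nzchar(lossLog[lost]),
                                 paste(lossLog[lost], branch, sep = ","),
                                 branch)
      ## gains: brand-new loci, never recreating old ones
      mu <- fam$gainMean * if (branch == "anc") fam$burst else 1
      g <- if (mu > 0) stats::rpois(1L, mu) else 0L
      if (g > 0L) {
        newIdx <- length(origin) + seq_len(g)
        origin <<- c(origin, rep("gained", g))
        locus <<- c(locus, sprintf("%s_G%s_%02d", fam$te, branch, seq_len(g)))
        gainBranch <<- c(gainBranch, rep(branch, g))
        lossLog <<- c(lossLog, rep("", g))
        carry <- c(carry, newIdx)
      }
      setdiff(carry, lost)
    }

    anc0 <- union(sets[[params$maternal]], sets[[params$paternal]])
    atSplit <- applyBranch("anc", anc0)
    sets[[polys[1]]] <- applyBranch("first", atSplit)
    inner <- applyBranch("inner", atSplit)
    sets[[polys[2]]] <- applyBranch(polys[2], inner)
    sets[[polys[3]]] <- applyBranch(polys[3], inner)

    ## observable loci: parental ones (diploids keep them) + surviving gains
    survivors <- origin != "gained" |
      seq_along(origin) %in% unlist(sets[polys])
    keepIdx <- which(survivors)
    remap <- match(seq_along(origin), keepIdx)

    calls <- matrix(0L, length(keepIdx), length(accIds),
                    dimnames = list(locus[keepIdx], accIds))
    for (tx in taxa) {
      members <- intersect(sets[[tx]], keepIdx)
      if (!length(members)) next
      acc <- accessionsOf(scheme, tx)
      p <- stats::rbeta(length(members), params$freqBeta[1],
                        params$freqBeta[2])
      kCar <- .truncBinom(length(acc), p)
      for (j in seq_along(members)) {
        carriers <- acc[sample.int(length(acc), kCar[j])]
        calls[remap[members[j]], carriers] <- 1L
      }
    }
    matrices[[fam$te]] <- MarkerMatrix(calls, teFamily = fam$te)

    presCols <- vapply(taxa, function(tx)
      seq_along(origin) %in% sets[[tx]], logical(length(origin)))
    colnames(presCols) <- taxa
    logs[[fam$te]] <- data.frame(
      te = fam$te, locus = locus, origin = origin,
      gain_branch = gainBranch, loss_branches = lossLog,
      observable = survivors, presCols, row.names = NULL)
  }
  structure(list(matrices = matrices, scheme = scheme, params = params,
                 log = do.call(rbind, logs)),
            class = "SimulationTruth")
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf("SimulationTruth: %d TE families, %d accessions, %d loci logged\n",
              length(x$matrices), length(taxonOf(x$scheme)), nrow(x$log)))
  invisible(x)
}

#' Compare pipeline estimates on simulated data against the truth log
#'
#' Checks three recoverable quantities: (i) the estimated paternal fraction
#' of attributable band losses (pooled over polyploid taxa and families,
#' with its Wilson interval) against the generating `paternalBias`;
#' (ii) that every loss logged on the ancestral branch surfaces in the
#' shared-by-all-polyploids lost category; (iii) that the pipeline's new
#' bands are exactly the observable logged gains.
#'
#' @param truth a [simulateDataset()] result.
#' @param classifications named list of scored [BandClassification-class]
#'   objects, one per family of `truth` (defaults to classifying
#'   `truth$matrices` directly).
#' @param level confidence level for the Wilson interval.
#' @return list of recovery metrics.
#' @export
recoveryReport <- function(truth, classifications = NULL, level = 0.95) {
  stopifnot(inherits(truth, "SimulationTruth"))
  if (is.null(classifications))
    classifications <- lapply(truth$matrices, classifyBands,
                              scheme = truth$scheme)
  if (!setequal(names(classifications), names(truth$matrices)))
    stopf("classifications do not match the simulated families")
  polys <- polyploids(truth$scheme)
  pat <- 0L; mat <- 0L
  newCalled <- character(0); lostAll <- list()
  for (te in names(classifications)) {
    cl <- classifications[[te]]
    lab <- deviationLabels(cl)
    st <- as.character(parentalStatus(cl))
    missingAny <- rowSums(lab == "missing") > 0L
    pat <- pat + sum(missingAny & st == "paternal_specific")
    mat <- mat + sum(missingAny & st == "maternal_specific")
    newCalled <- c(newCalled, locusIds(cl)[rowSums(lab == "new") > 0L])
    lostAll[[te]] <- locusIds(cl)[rowSums(lab == "missing") == length(polys)]
  }
  nAttr <- pat + mat
  betaHat <- if (nAttr > 0) pat / nAttr else NA_real_
  ci <- if (nAttr > 0) newcombeWilsonCi(pat, nAttr, level)
        else c(lower = NA_real_, upper = NA_real_)
  lg <- truth$log
  ancLost <- lg$locus[grepl("(^|,)anc(,|$)", lg$loss_branches) &
                        lg$origin != "gained"]
  inAllCat <- unlist(lostAll, use.names = FALSE)
  gains <- lg$locus[lg$origin == "gained" & lg$observable]
  list(beta_hat = betaHat, beta_ci = ci, beta_true = truth$params$paternalBias,
       beta_covered = nAttr > 0 &&
         truth$params$paternalBias >= ci[["lower"]] &&
         truth$params$paternalBias <= ci[["upper"]],
       n_attributable = nAttr,
       anc_losses = length(ancLost),
       anc_losses_in_all_category = all(ancLost %in% inAllCat),
       gains_logged = length(gains),
       new_called = length(unique(newCalled)),
       new_matches_gains = setequal(gains, unique(newCalled)))
}
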