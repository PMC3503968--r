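#' Classify bands by their distribution in the diploid progenitors
#'
#' Assigns each locus exactly one parental status from the taxon-level
#' presence of the two diploid progenitor taxa: `shared_parental` (present
#' in both), `maternal_specific`, `paternal_specific`, or
#' `absent_in_parents`.  Loci absent from every accession of the matrix are
#' flagged and ignored by all downstream counting.
#'
#' @param m a [MarkerMatrix-class].
#' @param scheme a [TaxonScheme-class].
#' @return a [BandClassification-class] with parental status filled and
#'   polyploid labels still unset.
#' @seealso [scorePolyploidDeviation()], [classifyBands()]
#' @export
classifyParentalBands <- function(m, scheme) {
  pres <- taxonPresence(m, scheme)
  mat <- pres[maternalDiploid(scheme), ]
  pat <- pres[paternalDiploid(scheme), ]
  status <- ifelse(mat & pat, "shared_parental",
            ifelse(mat, "maternal_specific",
            ifelse(pat, "paternal_specific", "absent_in_parents")))
  pp <- polyploids(scheme)
  L <- nrow(m)
  new("BandClassification",
      teFamily = teFamily(m),
      locusIds = rownames(m),
      parentalStatus = factor(status, levels = .parentalLevels),
      polyPresence = matrix(NA, L, length(pp),
                            dimnames = list(rownames(m), pp)),
      labels = matrix(NA_character_, L, length(pp),
                      dimnames = list(rownames(m), pp)),
      flagged = rowSums(markerCalls(m)) == 0L,
      scheme = scheme)
}

#' Score each polyploid taxon against predicted additivity
#'
#' The predicted additive profile of a polyploid is the union of the
#' taxon-level presence of the two diploid progenitors ("summed" parental
#' profiles).  Each locus is then labelled per polyploid taxon:
#' `additive_present` (parental band, present), `missing` (parental band,
#' absent), `new` (non-parental band, present) or `absent_everywhere`
#' (non-parental band, absent in this polyploid).
#'
#' @param classification result of [classifyParentalBands()].
#' @param m the same [MarkerMatrix-class].
#' @param scheme the same [TaxonScheme-class].
#' @return the [BandClassification-class] with presence and labels filled.
#' @export
scorePolyploidDeviation <- function(classification, m, scheme) {
  stopifnot(is(classification, "BandClassification"))
  pres <- taxonPresence(m, scheme)
  pp <- polyploids(scheme)
  for (tx in pp)
    if (!length(accessionsOf(scheme, tx)))
      stopf("polyploid taxon '%s' has no accessions", tx)
  parental <- as.character(classification@parentalStatus) != "absent_in_parents"
  labels <- matrix(NA_character_, length(parental), length(pp),
                   dimnames = list(classification@locusIds, pp))
  poly <- t(pres[pp, , drop = FALSE])
  labels[parental & poly] <- "additive_present"
  labels[parental & !poly] <- "missing"
  labels[!parental & poly] <- "new"
  labels[!parental & !poly] <- "absent_everywhere"
  classification@polyPresence <- poly
  classification@labels <- labels
  validObject(classification)
  classification
}

#' Classify parental bands and score polyploid deviation in one call
#'
#' @inheritParams scorePolyploidDeviation
#' @return a fully filled [BandClassification-class].
#' @export
classifyBands <- function(m, scheme)
  scorePolyploidDeviation(classifyParentalBands(m, scheme), m, scheme)

#' @describeIn classifyParentalBands parental status factor, named by locus.
#' @param x a `BandClassification`.
#' @export
setMethod("parentalStatus", "BandClassification", function(x)
  stats::setNames(x@parentalStatus, x@locusIds))

#' @describeIn scorePolyploidDeviation loci x polyploids label matrix.
#' @param x a `BandClassification`.
#' @export
setMethod("deviationLabels", "BandClassification", function(x) x@labels)

#' @describeIn classifyParentalBands TE family of a classification.
#' @export
setMethod("teFamily", "BandClassification", function(x) x@teFamily)

#' @describeIn classifyParentalBands locus ids of a classification.
#' @export
setMethod("locusIds", "BandClassification", function(x) x@locusIds)

#' @describeIn classifyParentalBands flagged (all-absent) loci.
#' @export
setMethod("flaggedLoci", "BandClassification", function(x)
  x@locusIds[x@flagged])

setMethod("show", "BandClassification", function(object) {
  tab <- table(object@parentalStatus[!object@flagged])
  cat(sprintf("BandClassification '%s': %d loci (%d flagged)\n",
              object@teFamily, length(object@locusIds), sum(object@flagged)))
  cat("  parental status:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!anyNA(object@labels))
    cat("  polyploid labels filled for:",
        paste(colnames(object@labels), collapse = ", "), "\n")
})

.activeLabels <- function(classification) {
  if (anyNA(classification@labels[!classification@flagged, , drop = FALSE]))
    stopf("polyploid labels are not filled; run scorePolyploidDeviation()")
  keep <- !classification@flagged
  list(labels = classification@labels[keep, , drop = FALSE],
       status = as.character(classification@parentalStatus)[keep],
       loci = classification@locusIds[keep])
}

#' Partition non-additive bands into sharing categories
#'
#' Each band that is new (resp. missing) in at least one polyploid taxon is
#' assigned to the unique non-empty subset of polyploid taxa in which it is
#' new (resp. missing); the function returns the count per subset.  With k
#' polyploid taxa there are 2^k - 1 categories, ordered largest subset
#' first (the three-taxon layout of the published tables).
#'
#' @param classification a scored [BandClassification-class].
#' @param block `"new"` or `"lost"`.
#' @return named integer vector of category counts.
#' @export
partitionSharingCategories <- function(classification, block = c("new", "lost")) {
  block <- match.arg(block)
  act <- .activeLabels(classification)
  want <- if (block == "new") "new" else "missing"
  hit <- act$labels == want
  pp <- colnames(act$labels)
  cats <- sharingCategories(pp)
  out <- stats::setNames(integer(length(cats)), names(cats))
  rows <- which(rowSums(hit) > 0L)
  if (length(rows)) {
    key <- apply(hit[rows, , drop = FALSE], 1L, function(z)
      paste(pp[z], collapse = "_"))
    tab <- table(key)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Parental origin of bands lost in one polyploid taxon
#'
#' Among the bands missing from `taxon`, those specific to one diploid
#' progenitor are attributable to that parent; bands shared by both parents
#' are counted separately and excluded from the paternal/maternal ratio
#' because their origin cannot be attributed.
#'
#' @param classification a scored [BandClassification-class].
#' @param taxon a polyploid taxon label.
#' @return list with `paternal_lost`, `maternal_lost`, `shared_lost`,
#'   `fraction_paternal` (NA with `defined = FALSE` when no attributable
#'   losses exist) and the locus ids of the attributable losses.
#' @export
parentalOriginOfLosses <- function(classification, taxon) {
  act <- .activeLabels(classification)
  if (!taxon %in% colnames(act$labels))
    stopf("'%s' is not a polyploid taxon of this classification", taxon)
  lost <- act$labels[, taxon] == "missing"
  pat <- sum(lost & act$status == "paternal_specific")
  mat <- sum(lost & act$status == "maternal_specific")
  shr <- sum(lost & act$status == "shared_parental")
  defined <- (pat + mat) > 0L
  list(taxon = taxon,
       paternal_lost = pat, maternal_lost = mat, shared_lost = shr,
       fraction_paternal = if (defined) pat / (pat + mat) else NA_real_,
       defined = defined,
       attributable_loci = act$loci[lost & act$status %in%
                                      c("paternal_specific", "maternal_specific")])
}

#' Summarise deviation from additivity for one TE family
#'
#' Assembles the full table-shaped summary: parental totals, new and lost
#' blocks (overall, per-taxon and sharing-category counts with the published
#' percentage conventions), per-taxon new/missing ratios, parental origin of
#' losses, and the package's defined deviation proportion
#' (new + missing) / (parental total + new) per polyploid taxon.
#'
#' @param classification a scored [BandClassification-class].
#' @return an [AdditivitySummary-class].
#' @export
deviationSummary <- function(classification) {
  act <- .activeLabels(classification)
  pp <- colnames(act$labels)
  parental <- c(total = sum(act$status != "absent_in_parents"),
                shared_parental = sum(act$status == "shared_parental"),
                maternal_specific = sum(act$status == "maternal_specific"),
                paternal_specific = sum(act$status == "paternal_specific"))

  block <- function(which) {
    want <- if (which == "new") "new" else "missing"
    hit <- act$labels == want
    cats <- partitionSharingCategories(classification, which)
    perTaxon <- stats::setNames(as.numeric(colSums(hit)), pp)
    inAll <- sum(rowSums(hit) > 0L)
    pct <- if (which == "new") {
      list(in_all = 100 * inAll / parental[["total"]],
           per_taxon = 100 * perTaxon / max(inAll, 1L),
           categories = 100 * cats / max(inAll, 1L))
    } else {
      list(in_all = 100 * inAll / parental[["total"]],
           per_taxon = 100 * perTaxon / parental[["total"]],
           categories = 100 * cats / max(inAll, 1L))
    }
    list(in_all = inAll, per_taxon = perTaxon,
         categories = as.numeric(cats) |> stats::setNames(names(cats)),
         pct = pct)
  }
  nb <- block("new")
  lb <- block("lost")

  ratios <- data.frame(
    taxon = pp,
    new = as.numeric(nb$per_taxon[pp]),
    missing = as.numeric(lb$per_taxon[pp]),
    ratio = ifelse(lb$per_taxon[pp] > 0,
                   nb$per_taxon[pp] / lb$per_taxon[pp], NA_real_),
    row.names = NULL)

  origin <- do.call(rbind, lapply(pp, function(tx) {
    o <- parentalOriginOfLosses(classification, tx)
    data.frame(taxon = tx, paternal_lost = o$paternal_lost,
               maternal_lost = o$maternal_lost, shared_lost = o$shared_lost,
               fraction_paternal = o$fraction_paternal)
  }))

  devProp <- stats::setNames(
    (nb$per_taxon[pp] + lb$per_taxon[pp]) /
      (parental[["total"]] + nb$per_taxon[pp]), pp)

  out <- new("AdditivitySummary",
             teFamily = classification@teFamily,
             parental = as.numeric(parental) |> stats::setNames(names(parental)),
             newBlock = nb, lostBlock = lb,
             ratios = ratios, origin = origin,
             deviationProportion = devProp)
  validObject(out)
  out
}

#' @describeIn deviationSummary TE family of a summary.
#' @param x an `AdditivitySummary`.
#' @export
setMethod("teFamily", "AdditivitySummary", function(x) x@teFamily)

setMethod("show", "AdditivitySummary", function(object) {
  cat(sprintf("AdditivitySummary '%s': %d parental bands; %d new, %d lost\n",
              object@teFamily, object@parental[["total"]],
              object@newBlock$in_all, object@lostBlock$in_all))
})

#' Flatten an AdditivitySummary to a one-row data.frame
#'
#' Produces a row in the layout of the published non-additive band tables
#' (counts followed by percentages), for CSV export of several families.
#'
#' @param x an [AdditivitySummary-class].
#' @param block `"new"` or `"lost"`.
#' @return one-row data.frame.
#' @export
summaryRow <- function(x, block = c("new", "lost")) {
  block <- match.arg(block)
  b <- if (block == "new") x@newBlock else x@lostBlock
  counts <- c(in_all = b$in_all,
              stats::setNames(b$per_taxon, paste0("in_", names(b$per_taxon))),
              stats::setNames(b$categories, paste0("cat_", names(b$categories))))
  pcts <- c(pct_in_all = b$pct$in_all,
            stats::setNames(b$pct$per_taxon,
                            paste0("pct_in_", names(b$pct$per_taxon))),
            stats::setNames(b$pct$categories,
                            paste0("pct_cat_", names(b$pct$categories))))
  cbind(data.frame(te = x@teFamily), as.data.frame(as.list(counts)),
        as.data.frame(as.list(round(pcts, 6))))
}
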