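#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Binary presence/absence marker matrix for one TE family
#'
#' `MarkerMatrix` holds the dominantly scored bands of a single
#' transposable-element family: loci (bands) as rows, accessions as columns,
#' with every cell 0 (band absent) or 1 (band present).  The class extends
#' [SummarizedExperiment::SummarizedExperiment] with a single assay named
#' `"calls"`, so the usual `[`, `dim`, `dimnames` machinery applies.
#'
#' Loci that carry no band in any accession are legal (they arise when
#' subsetting) and are flagged by [flaggedLoci()]; downstream scoring ignores
#' them.
#'
#' @slot teFamily single character, the TE family label (e.g. `"Tnt1"`).
#' @seealso [MarkerMatrix()], [readMarkerMatrix()], [taxonPresence()]
#' @exportClass MarkerMatrix
setClass("MarkerMatrix",
         contains = "SummarizedExperiment",
         representation(teFamily = "character"))

setValidity("MarkerMatrix", function(object) {
  msg <- character()
  if (length(object@teFamily) != 1L || is.na(object@teFamily) ||
      !nzchar(object@teFamily))
    msg <- c(msg, "'teFamily' must be a single non-empty string")
  anames <- SummarizedExperiment::assayNames(object)
  if (!identical(anames, "calls")) {
    msg <- c(msg, "exactly one assay named 'calls' is required")
  } else {
    m <- SummarizedExperiment::assay(object, "calls")
    if (anyNA(m) || !all(m %in% c(0L, 1L)))
      msg <- c(msg, "all calls must be 0 or 1 with no missing cells")
  }
  if (nrow(object) < 1L) msg <- c(msg, "at least 1 locus is required")
  if (ncol(object) < 2L) msg <- c(msg, "at least 2 accessions are required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "locus ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "accession ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Accession-to-taxon assignment with progenitor roles
#'
#' Maps each accession to a taxon and records which taxon stands for the
#' maternal diploid progenitor, which for the paternal diploid progenitor,
#' and the ordered set of allopolyploid taxa derived from their hybridisation.
#'
#' @slot taxonOf named character; names are accession ids, values taxon labels.
#' @slot maternalDiploid,paternalDiploid single taxon labels.
#' @slot polyploids ordered character vector of polyploid taxon labels.
#' @seealso [TaxonScheme()], [readTaxonScheme()]
#' @exportClass TaxonScheme
setClass("TaxonScheme",
         representation(taxonOf = "character",
                        maternalDiploid = "character",
                        paternalDiploid = "character",
                        polyploids = "character"))

setValidity("TaxonScheme", function(object) {
  msg <- character()
  if (is.null(names(object@taxonOf)) || anyDuplicated(names(object@taxonOf)))
    msg <- c(msg, "'taxonOf' must be named by unique accession ids")
  if (length(object@maternalDiploid) != 1L || length(object@paternalDiploid) != 1L)
    msg <- c(msg, "exactly one maternal and one paternal diploid taxon")
  if (identical(object@maternalDiploid, object@paternalDiploid))
    msg <- c(msg, "maternal and paternal diploid taxa must differ")
  if (length(object@polyploids) < 1L || anyDuplicated(object@polyploids))
    msg <- c(msg, "at least one polyploid taxon, all distinct")
  if (any(object@polyploids %in% c(object@maternalDiploid, object@paternalDiploid)))
    msg <- c(msg, "polyploid taxa must be disjoint from the diploid progenitors")
  named <- c(object@maternalDiploid, object@paternalDiploid, object@polyploids)
  missing <- setdiff(named, object@taxonOf)
  if (length(missing))
    msg <- c(msg, paste0("taxa without accessions: ",
                         paste(missing, collapse = ", ")))
  stray <- setdiff(object@taxonOf, named)
  if (length(stray))
    msg <- c(msg, paste0("accessions assigned to undeclared taxa: ",
                         paste(stray, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-locus band classification against the diploid progenitors
#'
#' Produced by [classifyParentalBands()] and completed by
#' [scorePolyploidDeviation()].  Each locus receives exactly one parental
#' status (`shared_parental`, `maternal_specific`, `paternal_specific`,
#' `absent_in_parents`) and, once deviation is scored, one label per polyploid
#' taxon (`additive_present`, `missing`, `new`, `absent_everywhere`).
#'
#' @slot teFamily TE family label.
#' @slot locusIds locus ids, in matrix order.
#' @slot parentalStatus factor over the four parental statuses.
#' @slot polyPresence logical matrix, loci x polyploid taxa.
#' @slot labels character matrix, loci x polyploid taxa (NA until scored).
#' @slot flagged logical; locus absent from every accession in the matrix.
#' @slot scheme the [TaxonScheme-class] used.
#' @exportClass BandClassification
setClass("BandClassification",
         representation(teFamily = "character",
                        locusIds = "character",
                        parentalStatus = "factor",
                        polyPresence = "matrix",
                        labels = "matrix",
                        flagged = "logical",
                        scheme = "TaxonScheme"))

.parentalLevels <- c("shared_parental", "maternal_specific",
                     "paternal_specific", "absent_in_parents")
.deviationLabels <- c("additive_present", "missing", "new", "absent_everywhere")

setValidity("BandClassification", function(object) {
  msg <- character()
  L <- length(object@locusIds)
  if (!identical(levels(object@parentalStatus), .parentalLevels))
    msg <- c(msg, "unexpected parental status levels")
  if (length(object@parentalStatus) != L || anyNA(object@parentalStatus))
    msg <- c(msg, "parental status must be total over loci")
  if (length(object@flagged) != L)
    msg <- c(msg, "'flagged' must align with loci")
  pp <- object@scheme@polyploids
  if (!identical(dim(object@labels), c(L, length(pp))))
    msg <- c(msg, "label matrix must be loci x polyploids")
  lab <- object@labels
  if (!all(is.na(lab) | lab %in% .deviationLabels))
    msg <- c(msg, "unexpected deviation labels")
  ok <- !is.na(lab)
  if (any(ok)) {
    st <- as.character(object@parentalStatus)
    newbad <- which(lab == "new" & st != "absent_in_parents")
    misbad <- which(lab == "missing" & st == "absent_in_parents")
    if (length(newbad)) msg <- c(msg, "'new' requires absence in both parents")
    if (length(misbad)) msg <- c(msg, "'missing' requires a parental band")
  }
  if (length(msg)) msg else TRUE
})

#' Additivity-deviation summary for one TE family
#'
#' Counts and percentages in the layout of the published non-additive band
#' tables: parental totals, a new-band block and a lost-band block (overall
#' count, per-polyploid counts, sharing-category counts), new/missing ratios
#' and the parental origin of losses per polyploid taxon.
#'
#' Percentage conventions (matching the published tables): in the new block
#' the overall percentage is relative to the parental total while per-taxon
#' and category percentages are relative to the family's overall new count;
#' in the lost block the overall and per-taxon percentages are relative to
#' the parental total and category percentages to the overall lost count.
#'
#' @slot teFamily TE family label.
#' @slot parental named numeric: `total`, `shared_parental`,
#'   `maternal_specific`, `paternal_specific`.
#' @slot newBlock,lostBlock lists with elements `in_all`, `per_taxon`,
#'   `categories`, `pct` (same shapes, percentage scale).
#' @slot ratios data.frame per polyploid taxon: new, missing, ratio.
#' @slot origin data.frame per polyploid taxon: paternal/maternal/shared
#'   losses, attributable paternal fraction.
#' @slot deviationProportion named numeric per polyploid taxon:
#'   (new + missing) / (parental total + new).
#' @exportClass AdditivitySummary
setClass("AdditivitySummary",
         representation(teFamily = "character",
                        parental = "numeric",
                        newBlock = "list",
                        lostBlock = "list",
                        ratios = "data.frame",
                        origin = "data.frame",
                        deviationProportion = "numeric"))

setValidity("AdditivitySummary", function(object) {
  msg <- character()
  for (bl in list(object@newBlock, object@lostBlock)) {
    if (!all(c("in_all", "per_taxon", "categories") %in% names(bl))) {
      msg <- c(msg, "blocks need in_all, per_taxon, categories")
      next
    }
    if (bl$in_all != sum(bl$categories))
      msg <- c(msg, "in_all must equal the sum of sharing categories")
    for (tx in names(bl$per_taxon)) {
      has <- vapply(strsplit(names(bl$categories), "_", fixed = TRUE),
                    function(s) tx %in% s, logical(1))
      if (bl$per_taxon[[tx]] != sum(bl$categories[has]))
        msg <- c(msg, sprintf("per-taxon count for %s must equal its category sum", tx))
    }
  }
  if (length(object@lostBlock$in_all) &&
      object@lostBlock$in_all > object@parental[["total"]])
    msg <- c(msg, "lost bands cannot exceed the parental total")
  if (length(msg)) msg else TRUE
})

#' Transcribed reference count tables
#'
#' Verbatim transcription of the printed band-count summary tables of the
#' Nicotiana section Repandae SSAP survey (seven TE families, two diploid
#' progenitor taxa, three polyploid taxa), including the printed percentages
#' so recomputations can be compared cell by cell against the original
#' rendering.
#'
#' @slot tableId one of `"table3"`, `"table4"`, `"table5_new"`,
#'   `"table5_lost"`, `"table6"`.
#' @slot data data.frame of the transcribed cells.
#' @exportClass CountFixture
setClass("CountFixture",
         representation(tableId = "character", data = "data.frame"))

setValidity("CountFixture", function(object) {
  known <- c("table3", "table4", "table5_new", "table5_lost", "table6")
  if (!(length(object@tableId) == 1L && object@tableId %in% known))
    return(sprintf("tableId must be one of: %s", paste(known, collapse = ", ")))
  TRUE
})

#' Circular split network
#'
#' A system of weighted splits (bipartitions of the accessions) compatible
#' with one circular ordering, as produced by NeighborNet.  Splits are stored
#' as integer vectors of taxon indices (one side of the bipartition); weights
#' are nonnegative; bootstrap supports, when present, lie in [0, 1].
#'
#' @slot taxa taxon labels (accession ids).
#' @slot cycle integer permutation of `seq_along(taxa)`: the circular order.
#' @slot splits list of integer index vectors (sides of bipartitions).
#' @slot weights numeric split weights.
#' @slot supports numeric bootstrap supports (NA when not estimated).
#' @seealso [neighborNet()], [bootstrapConfidenceNetwork()], [writeSplitsNexus()]
#' @exportClass SplitNetwork
setClass("SplitNetwork",
         representation(taxa = "character",
                        cycle = "integer",
                        splits = "list",
                        weights = "numeric",
                        supports = "numeric"))

setValidity("SplitNetwork", function(object) {
  msg <- character()
  n <- length(object@taxa)
  if (!identical(sort(object@cycle), seq_len(n)))
    msg <- c(msg, "'cycle' must be a permutation of the taxon indices")
  if (length(object@splits) != length(object@weights) ||
      length(object@splits) != length(object@supports))
    msg <- c(msg, "splits, weights and supports must align")
  if (any(object@weights < 0)) msg <- c(msg, "split weights must be >= 0")
  sup <- object@supports
  if (any(!is.na(sup) & (sup < 0 | sup > 1)))
    msg <- c(msg, "supports must lie in [0, 1]")
  pos <- integer(n); pos[object@cycle] <- seq_len(n)
  for (s in object@splits) {
    if (!length(s) || length(s) >= n || anyDuplicated(s) ||
        any(s < 1L | s > n)) {
      msg <- c(msg, "each split must be a proper non-empty taxon subset")
      break
    }
    p <- sort(pos[s])
    contiguous <- all(diff(p) == 1L)
    ## the complement may be the contiguous arc instead
    q <- sort(pos[setdiff(seq_len(n), s)])
    if (!contiguous && !all(diff(q) == 1L)) {
      msg <- c(msg, "split not compatible with the circular ordering")
      break
    }
  }
  if (length(msg)) msg else TRUE
})
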