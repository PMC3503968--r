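#' Construct a MarkerMatrix
#'
#' @param calls matrix of 0/1 calls (numeric, integer or logical), loci as
#'   rows (rownames = locus ids), accessions as columns (colnames =
#'   accession ids).
#' @param teFamily single character label for the TE family.
#' @return a validated [MarkerMatrix-class].
#' @examples
#' m <- MarkerMatrix(matrix(c(1, 0, 1, 1, 0, 0), 3, 2,
#'                          dimnames = list(paste0("L", 1:3), c("a1", "a2"))),
#'                   teFamily = "Tnt1")
#' markerCalls(m)
#' @export
MarkerMatrix <- function(calls, teFamily) {
  if (is.logical(calls)) storage.mode(calls) <- "integer"
  calls <- as.matrix(calls)
  if (is.numeric(calls)) storage.mode(calls) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(calls = calls))
  new("MarkerMatrix", se, teFamily = as.character(teFamily))
}

#' @describeIn MarkerMatrix TE family label.
#' @param x a `MarkerMatrix`.
#' @export
setMethod("teFamily", "MarkerMatrix", function(x) x@teFamily)

#' @describeIn MarkerMatrix locus ids (row names).
#' @export
setMethod("locusIds", "MarkerMatrix", function(x) rownames(x))

#' @describeIn MarkerMatrix accession ids (column names).
#' @export
setMethod("accessionIds", "MarkerMatrix", function(x) colnames(x))

#' @describeIn MarkerMatrix the integer 0/1 call matrix.
#' @export
setMethod("markerCalls", "MarkerMatrix",
          function(x) SummarizedExperiment::assay(x, "calls"))

#' @describeIn MarkerMatrix loci absent from every accession (retained but
#'   ignored by downstream scoring).
#' @export
setMethod("flaggedLoci", "MarkerMatrix",
          function(x) rownames(x)[rowSums(markerCalls(x)) == 0L])

setMethod("show", "MarkerMatrix", function(object) {
  cat(sprintf("MarkerMatrix '%s': %d loci x %d accessions (%d flagged)\n",
              teFamily(object), nrow(object), ncol(object),
              length(flaggedLoci(object))))
})

#' Read a marker matrix from a delimited file
#'
#' Expects the package's tab-separated dialect: a header row naming the
#' accessions (first field is an arbitrary locus-column title), one row per
#' locus with the locus id in the first column and 0/1 calls after it.
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @param teFamily TE family label to attach.
#' @return a validated [MarkerMatrix-class] preserving file row/column order.
#' @seealso [writeMarkerMatrix()]
#' @export
readMarkerMatrix <- function(path, teFamily) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stopf("'%s': empty marker table (need a header and at least one locus)", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  acc <- fields[[1]][-1]
  if (length(acc) < 1L) stopf("'%s': header names no accessions", path)
  body <- fields[-1]
  locus <- vapply(body, `[`, character(1), 1L)
  nc <- lengths(body)
  if (any(nc != length(acc) + 1L))
    stopf("'%s': row '%s' has %d cells, expected %d", path,
          locus[which(nc != length(acc) + 1L)[1]],
          nc[which(nc != length(acc) + 1L)[1]] - 1L, length(acc))
  cells <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(body),
                  byrow = TRUE)
  bad <- which(matrix(!(cells %in% c("0", "1")), nrow(cells)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("'%s': non-binary call '%s' at locus '%s', accession '%s'", path,
          cells[bad[1, 1], bad[1, 2]], locus[bad[1, 1]], acc[bad[1, 2]])
  if (anyDuplicated(locus))
    stopf("'%s': duplicated locus ids (e.g. '%s')", path,
          locus[duplicated(locus)][1])
  if (anyDuplicated(acc))
    stopf("'%s': duplicated accession ids (e.g. '%s')", path,
          acc[duplicated(acc)][1])
  m <- matrix(as.integer(cells), nrow = length(body),
              dimnames = list(locus, acc))
  MarkerMatrix(m, teFamily = teFamily)
}

#' Write a marker matrix in the dialect readMarkerMatrix() accepts
#'
#' @param m a [MarkerMatrix-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeMarkerMatrix <- function(m, path) {
  stopifnot(is(m, "MarkerMatrix"))
  calls <- markerCalls(m)
  header <- paste(c("locus", colnames(calls)), collapse = "\t")
  rows <- vapply(seq_len(nrow(calls)), function(i)
    paste(c(rownames(calls)[i], calls[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Taxon-level band presence
#'
#' A band is present in a taxon when at least one accession of that taxon
#' carries it (no frequency threshold).
#'
#' @param m a [MarkerMatrix-class].
#' @param scheme a [TaxonScheme-class] covering all accessions of `m`.
#' @return logical matrix, taxa x loci.
#' @export
taxonPresence <- function(m, scheme) {
  stopifnot(is(m, "MarkerMatrix"), is(scheme, "TaxonScheme"))
  calls <- markerCalls(m)
  unmapped <- setdiff(colnames(calls), names(taxonOf(scheme)))
  if (length(unmapped))
    stopf("accessions without taxon assignment: %s",
          paste(unmapped, collapse = ", "))
  taxa <- taxonNames(scheme)
  out <- matrix(FALSE, length(taxa), nrow(calls),
                dimnames = list(taxa, rownames(calls)))
  tx <- taxonOf(scheme)[colnames(calls)]
  for (t in taxa) {
    cols <- which(tx == t)
    if (length(cols))
      out[t, ] <- rowSums(calls[, cols, drop = FALSE]) > 0L
  }
  out
}
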