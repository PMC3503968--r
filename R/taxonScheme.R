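#' Construct a TaxonScheme
#'
#' @param taxonOf named character vector: names are accession ids, values
#'   are taxon labels.
#' @param maternalDiploid,paternalDiploid taxon labels of the diploid
#'   progenitor representatives.
#' @param polyploids ordered character vector of allopolyploid taxon labels.
#' @return a validated [TaxonScheme-class].
#' @examples
#' sch <- TaxonScheme(c(s1 = "SYL", s2 = "SYL", t1 = "TRI", t2 = "TRI",
#'                      n1 = "NUD", n2 = "NUD"),
#'                    maternalDiploid = "SYL", paternalDiploid = "TRI",
#'                    polyploids = "NUD")
#' accessionsOf(sch, "NUD")
#' @export
TaxonScheme <- function(taxonOf, maternalDiploid, paternalDiploid, polyploids) {
  new("TaxonScheme", taxonOf = taxonOf,
      maternalDiploid = as.character(maternalDiploid),
      paternalDiploid = as.character(paternalDiploid),
      polyploids = as.character(polyploids))
}

#' @describeIn TaxonScheme accession-to-taxon map.
#' @param x a `TaxonScheme`.
#' @export
setMethod("taxonOf", "TaxonScheme", function(x) x@taxonOf)

#' @describeIn TaxonScheme maternal diploid taxon label.
#' @export
setMethod("maternalDiploid", "TaxonScheme", function(x) x@maternalDiploid)

#' @describeIn TaxonScheme paternal diploid taxon label.
#' @export
setMethod("paternalDiploid", "TaxonScheme", function(x) x@paternalDiploid)

#' @describeIn TaxonScheme ordered polyploid taxon labels.
#' @export
setMethod("polyploids", "TaxonScheme", function(x) x@polyploids)

#' @describeIn TaxonScheme all declared taxa (maternal, paternal, polyploids).
#' @export
setMethod("taxonNames", "TaxonScheme", function(x)
  c(x@maternalDiploid, x@paternalDiploid, x@polyploids))

#' @describeIn TaxonScheme accession ids assigned to `taxon`.
#' @param taxon a taxon label.
#' @export
setMethod("accessionsOf", "TaxonScheme", function(x, taxon)
  names(x@taxonOf)[x@taxonOf == taxon])

setMethod("show", "TaxonScheme", function(object) {
  cat(sprintf(paste0("TaxonScheme: %d accessions in %d taxa\n",
                     "  maternal %s, paternal %s; polyploids: %s\n"),
              length(object@taxonOf), length(taxonNames(object)),
              object@maternalDiploid, object@paternalDiploid,
              paste(object@polyploids, collapse = ", ")))
})

#' Read an accession-to-taxon table
#'
#' Reads a two-column tab-separated file (accession id, taxon label; `#`
#' comments allowed, a header line `accession<TAB>taxon` is skipped if
#' present) and combines it with the progenitor roles supplied as arguments.
#'
#' @param path file path.
#' @inheritParams TaxonScheme
#' @return a validated [TaxonScheme-class].
#' @export
readTaxonScheme <- function(path, maternalDiploid, paternalDiploid, polyploids) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1]][1]), "accession"))
    fields <- fields[-1]
  if (!length(fields)) stopf("'%s': no accession assignments", path)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stopf("'%s': line %d does not have two tab-separated fields", path, bad[1])
  taxonOf <- vapply(fields, `[`, character(1), 2L)
  names(taxonOf) <- vapply(fields, `[`, character(1), 1L)
  TaxonScheme(taxonOf, maternalDiploid, paternalDiploid, polyploids)
}
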