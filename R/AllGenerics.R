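#' @export
setGeneric("teFamily", function(x) standardGeneric("teFamily"))

#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))

#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))

#' @export
setGeneric("markerCalls", function(x) standardGeneric("markerCalls"))

#' @export
setGeneric("flaggedLoci", function(x) standardGeneric("flaggedLoci"))

#' @export
setGeneric("taxonOf", function(x) standardGeneric("taxonOf"))

#' @export
setGeneric("maternalDiploid", function(x) standardGeneric("maternalDiploid"))

#' @export
setGeneric("paternalDiploid", function(x) standardGeneric("paternalDiploid"))

#' @export
setGeneric("polyploids", function(x) standardGeneric("polyploids"))

#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @export
setGeneric("accessionsOf", function(x, taxon) standardGeneric("accessionsOf"))

#' @export
setGeneric("parentalStatus", function(x) standardGeneric("parentalStatus"))

#' @export
setGeneric("deviationLabels", function(x) standardGeneric("deviationLabels"))

#' @export
setGeneric("tableId", function(x) standardGeneric("tableId"))

#' @export
setGeneric("fixtureData", function(x) standardGeneric("fixtureData"))

#' @export
setGeneric("cycleOrder", function(x) standardGeneric("cycleOrder"))

#' @export
setGeneric("splits", function(x) standardGeneric("splits"))

#' @export
setGeneric("splitWeights", function(x) standardGeneric("splitWeights"))

#' @export
setGeneric("splitSupports", function(x) standardGeneric("splitSupports"))
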