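#' @include AllClasses.R
NULL

#' @export
setGeneric("incidence", function(x, ...) standardGeneric("incidence"))

#' @export
setGeneric("plotData", function(x, ...) standardGeneric("plotData"))

#' @export
setGeneric("speciesData", function(x, ...) standardGeneric("speciesData"))

#' @export
setGeneric("designSummary", function(x, ...) standardGeneric("designSummary"))

#' @export
setGeneric("alphaRichness", function(x, ...) standardGeneric("alphaRichness"))

#' @export
setGeneric("gammaRichness",
           function(x, level = c("location", "habitat"), ...)
             standardGeneric("gammaRichness"))

#' @export
setGeneric("endemicProportion",
           function(x, ...) standardGeneric("endemicProportion"))

#' @export
setGeneric("pairwiseBeta", function(x, ...) standardGeneric("pairwiseBeta"))

#' @export
setGeneric("transitionMeans",
           function(x, ...) standardGeneric("transitionMeans"))

#' @export
setGeneric("partitionAll", function(x, ...) standardGeneric("partitionAll"))

#' @export
setGeneric("hillProfiles", function(x, ...) standardGeneric("hillProfiles"))
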