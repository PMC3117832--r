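#' @rdname speciesPanel
#' @export
setGeneric("speciesPanel", function(x) standardGeneric("speciesPanel"))

#' @rdname groupIds
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname members
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname diversity
#' @export
setGeneric("diversity", function(x) standardGeneric("diversity"))

#' @rdname abundance
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname epi
#' @export
setGeneric("epi", function(x) standardGeneric("epi"))

#' @rdname familyMeanDistance
#' @export
setGeneric("meanDistance", function(x) standardGeneric("meanDistance"))

#' @rdname familyMeanDistance
#' @export
setGeneric("pairDistances", function(x) standardGeneric("pairDistances"))

#' @rdname geneIds
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))
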