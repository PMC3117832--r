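#' GeneSet accessors
#'
#' @param x a [GeneSet-class].
#' @return `geneIds()` the identifiers; `setLabel()` the class label.
#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneSet", function(x) x@ids)

#' @rdname geneIds
#' @export
setMethod("setLabel", "GeneSet", function(x) x@label)
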