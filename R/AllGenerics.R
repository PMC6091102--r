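#' @rdname barcodeSeqs
#' @export
setGeneric("barcodeSeqs", function(x) standardGeneric("barcodeSeqs"))

#' @rdname barcodeSeqs
#' @export
setGeneric("recordMeta", function(x) standardGeneric("recordMeta"))

#' @rdname barcodeSeqs
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname datasetSummary
#' @export
setGeneric("datasetSummary", function(x) standardGeneric("datasetSummary"))

#' @rdname k2pDistanceMatrix
#' @export
setGeneric("k2pDistanceMatrix",
           function(x, ...) standardGeneric("k2pDistanceMatrix"))

#' @rdname distances
#' @export
setGeneric("distances", function(x, ...) standardGeneric("distances"))
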