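#' @rdname VariantPanel-class
#' @param x,object An object.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname VariantPanel-class
#' @export
setGeneric("pathoClasses", function(x) standardGeneric("pathoClasses"))

#' @rdname VariantPanel-class
#' @export
setGeneric("panelSpan", function(x) standardGeneric("panelSpan"))

#' @rdname Pedigree-class
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname Pedigree-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname HapFreqModel-class
#' @export
setGeneric("hapFrequencies", function(x) standardGeneric("hapFrequencies"))

#' @rdname HapFreqModel-class
#' @export
setGeneric("marginalAlleleFreqs",
           function(x) standardGeneric("marginalAlleleFreqs"))
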