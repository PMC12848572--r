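## Generics for the package's accessor functions.

#' @rdname DETable
#' @param x an object with a contrast label.
#' @export
setGeneric("contrastId", function(x) standardGeneric("contrastId"))

#' @rdname MergedContrasts-class
#' @param x a [MergedContrasts-class] object.
#' @export
setGeneric("contrastIds", function(x) standardGeneric("contrastIds"))

#' @rdname GeneSet
#' @param x an object holding gene symbols.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneSet
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname PhaseAnnotation
#' @param x a [PhaseAnnotation-class] object.
#' @export
setGeneric("phaseOf", function(x) standardGeneric("phaseOf"))

#' @rdname SynthTruth-class
#' @param x an object carrying a generative attenuation coefficient.
#' @export
setGeneric("betaTrue", function(x) standardGeneric("betaTrue"))
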