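#' @rdname CoexpressionNetwork-class
#' @param x a package object.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname ModuleSet-class
#' @param x a package object.
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleStats", function(x) standardGeneric("moduleStats"))

#' @rdname TargetMap-class
#' @param x a package object.
#' @export
setGeneric("targetsOf", function(x, ...) standardGeneric("targetsOf"))

#' @rdname CoregulationNetwork-class
#' @param x a package object.
#' @export
setGeneric("moduleSummary", function(x) standardGeneric("moduleSummary"))
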