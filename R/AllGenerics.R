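#' @rdname accessors
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @rdname accessors
#' @export
setGeneric("nodeInfo", function(x) standardGeneric("nodeInfo"))

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("trajectoryMatrix", function(x) standardGeneric("trajectoryMatrix"))

#' @rdname accessors
#' @export
setGeneric("trajectoryTimes", function(x) standardGeneric("trajectoryTimes"))

#' @rdname accessors
#' @export
setGeneric("fitDiagnostics", function(x) standardGeneric("fitDiagnostics"))

#' @rdname accessors
#' @export
setGeneric("organs", function(x) standardGeneric("organs"))

#' @rdname accessors
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))

#' @rdname accessors
#' @export
setGeneric("agesWeeks", function(x) standardGeneric("agesWeeks"))

#' @rdname accessors
#' @export
setGeneric("genePanel", function(x) standardGeneric("genePanel"))

#' @rdname accessors
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))
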