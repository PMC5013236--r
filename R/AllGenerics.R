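#' @rdname InteractionNetwork-class
#' @param x,object An \code{InteractionNetwork}.
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))

#' @rdname InteractionNetwork-class
#' @param value Replacement value.
#' @export
setGeneric("networkName<-",
    function(x, value) standardGeneric("networkName<-"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("edgeData", function(x) standardGeneric("edgeData"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname isClean
#' @export
setGeneric("isClean", function(x) standardGeneric("isClean"))

#' @rdname cleanNetwork
#' @export
setGeneric("cleanNetwork", function(x) standardGeneric("cleanNetwork"))

#' @rdname connectedComponents
#' @export
setGeneric("connectedComponents",
    function(x) standardGeneric("connectedComponents"))

#' @rdname mainComponent
#' @export
setGeneric("mainComponent", function(x) standardGeneric("mainComponent"))

#' @rdname topologyReport
#' @export
setGeneric("topologyReport", function(x) standardGeneric("topologyReport"))

#' @rdname identifyHubs
#' @param ... Method arguments.
#' @export
setGeneric("identifyHubs", function(x, ...) standardGeneric("identifyHubs"))

#' @rdname classifyTopology
#' @export
setGeneric("classifyTopology",
    function(x, ...) standardGeneric("classifyTopology"))
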