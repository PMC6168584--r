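#' Accessors for biodelta classes
#'
#' Accessor generics for the package's S4 containers: `measurements()` and
#' `participants()` return the component tables of a
#' \linkS4class{MeasurementTable}; `rangeRules()` returns the rule table of a
#' \linkS4class{RangeRuleSet}; `networkNodes()`, `networkEdges()` and
#' `networkAlpha()` expose the parts of a \linkS4class{CorrelationNetwork};
#' `deltaValues()` returns the biomarkers x participants change matrix of a
#' \linkS4class{DeltaMatrix}; `asIgraph()` converts a network to an
#' \pkg{igraph} graph with `weight = rho` edge attributes.
#'
#' @param x an object of the documented class.
#' @return The extracted component (a data.frame, character vector, numeric
#'   scalar, matrix, or igraph object, respectively).
#' @name accessors
#' @aliases measurements participants rangeRules networkNodes networkEdges
#'   networkAlpha deltaValues asIgraph
NULL

#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname accessors
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))
#' @rdname accessors
#' @export
setGeneric("rangeRules", function(x) standardGeneric("rangeRules"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkAlpha", function(x) standardGeneric("networkAlpha"))
#' @rdname accessors
#' @export
setGeneric("deltaValues", function(x) standardGeneric("deltaValues"))
#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
setMethod("measurements", "MeasurementTable", function(x) x@measurements)
#' @rdname accessors
setMethod("participants", "MeasurementTable", function(x) x@participants)
#' @rdname accessors
setMethod("rangeRules", "RangeRuleSet", function(x) x@rules)
#' @rdname accessors
setMethod("networkNodes", "CorrelationNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "CorrelationNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("networkAlpha", "CorrelationNetwork", function(x) x@alpha)
#' @rdname accessors
setMethod("deltaValues", "DeltaMatrix", function(x)
    SummarizedExperiment::assay(x, "delta"))

#' @rdname accessors
setMethod("asIgraph", "CorrelationNetwork", function(x) {
    e <- x@edges
    g <- igraph::graph_from_data_frame(
        d = if (nrow(e))
                data.frame(from = e$biomarker_a, to = e$biomarker_b,
                           weight = e$rho, n = e$n, p = e$p, q = e$q)
            else
                data.frame(from = character(), to = character(),
                           weight = numeric(), n = integer(),
                           p = numeric(), q = numeric()),
        directed = FALSE,
        vertices = data.frame(name = x@nodes))
    g
})
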