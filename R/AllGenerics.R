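#' @rdname addRelation
#' @export
setGeneric("addRelation", function(graph, child, type, parent)
  standardGeneric("addRelation"))

#' @rdname conceptClosure
#' @export
setGeneric("conceptClosure", function(graph, concept, type = "IS_A")
  standardGeneric("conceptClosure"))

#' @rdname isPermissible
#' @export
setGeneric("isPermissible", function(graph, candidate, roleRoot)
  standardGeneric("isPermissible"))

#' @rdname subsumes
#' @export
setGeneric("subsumes", function(a, b, graph) standardGeneric("subsumes"))

#' @rdname toSCG
#' @export
setGeneric("toSCG", function(expr) standardGeneric("toSCG"))

#' @rdname decomposeTerm
#' @export
setGeneric("decomposeTerm", function(term, eq, graph, grammar = nameGrammar())
  standardGeneric("decomposeTerm"))
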