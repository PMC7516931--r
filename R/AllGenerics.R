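#' @rdname MultilayerGraph-accessors
#' @export
setGeneric("nVars", function(x) standardGeneric("nVars"))

#' @rdname MultilayerGraph-accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname MultilayerGraph-accessors
#' @export
setGeneric("varNames", function(x) standardGeneric("varNames"))

#' @rdname MultilayerGraph-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname MultilayerGraph-accessors
#' @export
setGeneric("edgeSet", function(x) standardGeneric("edgeSet"))

#' @rdname neighborsOf
#' @export
setGeneric("neighborsOf", function(g, v) standardGeneric("neighborsOf"))

#' @rdname isClique
#' @export
setGeneric("isClique", function(g, s) standardGeneric("isClique"))

#' @rdname enumerateCliques
#' @export
setGeneric("enumerateCliques", function(g, ...) standardGeneric("enumerateCliques"))

#' @rdname separates
#' @export
setGeneric("separates", function(g, a, b, c) standardGeneric("separates"))

#' @rdname markovBlanket
#' @export
setGeneric("markovBlanket", function(g, v) standardGeneric("markovBlanket"))

#' @rdname gibbs-measure
#' @export
setGeneric("energy", function(field, config) standardGeneric("energy"))

#' @rdname gibbs-measure
#' @export
setGeneric("partitionFunction", function(field, ...) standardGeneric("partitionFunction"))

#' @rdname gibbs-measure
#' @export
setGeneric("gibbsProbability", function(field, config, ...) standardGeneric("gibbsProbability"))

#' @rdname gibbs-measure
#' @export
setGeneric("toJointTable", function(field, ...) standardGeneric("toJointTable"))

#' @rdname localCharacteristic
#' @export
setGeneric("localCharacteristic", function(field, v, config) standardGeneric("localCharacteristic"))

#' @rdname exactSample
#' @export
setGeneric("exactSample", function(field, n, seed, ...) standardGeneric("exactSample"))

#' @rdname hypermatrix-values
#' @export
setGeneric("hmValues", function(x) standardGeneric("hmValues"))

#' @rdname stValues
#' @export
setGeneric("stValues", function(x) standardGeneric("stValues"))
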