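#' @rdname Volume-class
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' @rdname Volume-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname Volume-class
#' @export
setGeneric("voxelType", function(x) standardGeneric("voxelType"))

#' @rdname Volume-class
#' @export
setGeneric("asArray", function(x, ...) standardGeneric("asArray"))

#' @rdname Volume-class
#' @export
setGeneric("normalizedArray", function(x) standardGeneric("normalizedArray"))

#' @rdname sampleVoxel
#' @export
setGeneric("sampleVoxel",
           function(x, coord, swizzle = NULL) standardGeneric("sampleVoxel"))

#' @rdname convertType
#' @export
setGeneric("convertType",
           function(x, dtype) standardGeneric("convertType"))

#' @rdname FlowGraph-class
#' @export
setGeneric("addNode",
           function(graph, id, kind, params = list()) standardGeneric("addNode"))

#' @rdname connect
#' @export
setGeneric("connect", function(graph, src, dst) standardGeneric("connect"))

#' @rdname setParam
#' @export
setGeneric("setParam",
           function(graph, id, name, value) standardGeneric("setParam"))

#' @rdname executeGraph
#' @export
setGeneric("executeGraph", function(graph, ...) standardGeneric("executeGraph"))

#' @rdname applyPointwise
#' @export
setGeneric("applyPointwise",
           function(kernel, x, ...) standardGeneric("applyPointwise"))
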