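#' @name PodSeedFusion-generics
#' @title Accessor generics
#' @description Small accessor generics used across the package's S4 classes.
#' @param x An object.
#' @return The corresponding slot value.
NULL

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("organ", function(x) standardGeneric("organ"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("objectMask", function(x) standardGeneric("objectMask"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("areaPx", function(x) standardGeneric("areaPx"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("bbox", function(x) standardGeneric("bbox"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("layerName", function(x) standardGeneric("layerName"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("backboneName", function(x) standardGeneric("backboneName"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("featureLayers", function(x) standardGeneric("featureLayers"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("inputSize", function(x) standardGeneric("inputSize"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("numClasses", function(x) standardGeneric("numClasses"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("classOrder", function(x) standardGeneric("classOrder"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname PodSeedFusion-generics
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
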