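#' @include AllClasses.R
NULL

#' @rdname NeuronPointCloud-class
#' @param object,x a \code{NeuronPointCloud}
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname NeuronPointCloud-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname NeuronPointCloud-class
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname NeuronPointCloud-class
#' @export
setGeneric("neuronColors", function(x) standardGeneric("neuronColors"))

#' @rdname NeuronPointCloud-class
#' @export
setGeneric("frameTag", function(x) standardGeneric("frameTag"))

#' @rdname NeuronPointCloud-class
#' @param value replacement value
#' @export
setGeneric("neuronColors<-",
  function(x, value) standardGeneric("neuronColors<-"))

#' Convert an object to a NeuronPointCloud
#'
#' @param x object to convert (e.g. an [Atlas-class]).
#' @param ... further arguments for methods.
#' @return a [NeuronPointCloud-class]
#' @export
setGeneric("asPointCloud", function(x, ...) standardGeneric("asPointCloud"))
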