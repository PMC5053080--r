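#' @rdname BooleanNetwork-class
#' @param x an object.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname BooleanNetwork-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname BooleanNetwork-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname BooleanNetwork-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname Attractor-class
#' @param x an object.
#' @export
setGeneric("avgState", function(x) standardGeneric("avgState"))

#' @rdname Attractor-class
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname Attractor-class
#' @export
setGeneric("stateStrings", function(x) standardGeneric("stateStrings"))

#' @rdname Attractor-class
#' @export
setGeneric("attractorKey", function(x) standardGeneric("attractorKey"))

#' @rdname TrainingSet-class
#' @param x an object.
#' @export
setGeneric("trainingIds", function(x) standardGeneric("trainingIds"))

#' @rdname TrainingSet-class
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname TrainingSet-class
#' @export
setGeneric("perturbations", function(x) standardGeneric("perturbations"))

#' @rdname Fitness-class
#' @param x an object.
#' @export
setGeneric("fitnessKey", function(x) standardGeneric("fitnessKey"))

#' @rdname GARun-class
#' @param x an object.
#' @export
setGeneric("bestFitness", function(x) standardGeneric("bestFitness"))

#' @rdname GARun-class
#' @export
setGeneric("bestNetwork", function(x) standardGeneric("bestNetwork"))

#' @rdname GARun-class
#' @export
setGeneric("gaTrace", function(x) standardGeneric("gaTrace"))
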