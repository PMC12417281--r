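#' Frame times of an object's temporal grid
#' @param x an object with a time grid.
#' @return numeric vector of times in minutes.
#' @export
setGeneric("times", function(x) standardGeneric("times"))

#' Number of frames
#' @param x an object with a time grid.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of pre-contrast baseline frames
#' @param x an object with a time grid.
#' @return integer baseline frame count.
#' @export
setGeneric("nBaseline", function(x) standardGeneric("nBaseline"))

#' Plasma concentration values of an AIF
#' @param x an \linkS4class{AIFCurve}.
#' @return numeric vector, mM.
#' @export
setGeneric("aifValues", function(x) standardGeneric("aifValues"))

#' Ktrans map
#' @param x a \linkS4class{PKMaps} or \linkS4class{PredictionSet}.
#' @return 3D array, min^-1.
#' @export
setGeneric("ktransMap", function(x) standardGeneric("ktransMap"))

#' Ve map
#' @param x a \linkS4class{PKMaps} or \linkS4class{PredictionSet}.
#' @return 3D array.
#' @export
setGeneric("veMap", function(x) standardGeneric("veMap"))

#' Vp map
#' @param x a \linkS4class{PKMaps} or \linkS4class{PredictionSet}.
#' @return 3D array.
#' @export
setGeneric("vpMap", function(x) standardGeneric("vpMap"))

#' Derived efflux-rate map kep = Ktrans/Ve
#'
#' Reported as 0 where Ktrans = 0 (non-enhancing tissue convention).
#' @param x a \linkS4class{PKMaps}.
#' @return 3D array, min^-1.
#' @export
setGeneric("kepMap", function(x) standardGeneric("kepMap"))

#' Voxelwise mean maps of a prediction set
#' @param x a \linkS4class{PredictionSet}.
#' @return a \linkS4class{PKMaps}.
#' @export
setGeneric("meanMaps", function(x) standardGeneric("meanMaps"))

#' Voxelwise standard-deviation uncertainty maps of a prediction set
#' @param x a \linkS4class{PredictionSet}.
#' @return named list (ktrans, ve, vp) of 3D arrays, parameter units.
#' @export
setGeneric("uncertaintyMaps", function(x) standardGeneric("uncertaintyMaps"))

#' Individual sampled maps of a prediction set
#' @param x a \linkS4class{PredictionSet}.
#' @return list of \linkS4class{PKMaps}.
#' @export
setGeneric("sampleMaps", function(x) standardGeneric("sampleMaps"))
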