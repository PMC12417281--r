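#' @describeIn TimeGrid frame times in minutes.
#' @param x object.
#' @aliases times,TimeGrid-method
#' @export
setMethod("times", "TimeGrid", function(x) x@times)

#' @describeIn TimeGrid number of frames.
#' @export
setMethod("nFrames", "TimeGrid", function(x) length(x@times))

#' @describeIn TimeGrid number of baseline frames.
#' @export
setMethod("nBaseline", "TimeGrid", function(x) x@nBaseline)

#' @describeIn AIFCurve frame times of the underlying grid.
#' @param x object.
#' @export
setMethod("times", "AIFCurve", function(x) x@grid@times)

#' @describeIn AIFCurve plasma concentration values (mM).
#' @export
setMethod("aifValues", "AIFCurve", function(x) x@cp)

#' @describeIn AIFCurve number of frames.
#' @export
setMethod("nFrames", "AIFCurve", function(x) length(x@cp))

#' @describeIn DCESeries frame times.
#' @param x object.
#' @export
setMethod("times", "DCESeries", function(x) x@grid@times)

#' @describeIn DCESeries number of frames.
#' @export
setMethod("nFrames", "DCESeries", function(x) length(x@grid@times))

#' @describeIn DCESeries number of baseline frames.
#' @export
setMethod("nBaseline", "DCESeries", function(x) x@grid@nBaseline)

#' @describeIn PKMaps Ktrans map (min^-1).
#' @param x object.
#' @export
setMethod("ktransMap", "PKMaps", function(x) x@ktrans)

#' @describeIn PKMaps Ve map.
#' @export
setMethod("veMap", "PKMaps", function(x) x@ve)

#' @describeIn PKMaps Vp map.
#' @export
setMethod("vpMap", "PKMaps", function(x) x@vp)

#' @describeIn PKMaps kep = Ktrans/Ve, 0 where Ktrans = 0.
#' @export
setMethod("kepMap", "PKMaps", function(x) {
  k <- x@ktrans / x@ve
  k[x@ktrans == 0] <- 0
  k
})

#' @describeIn PredictionSet voxelwise mean maps.
#' @param x object.
#' @export
setMethod("meanMaps", "PredictionSet", function(x) x@meanMaps)

#' @describeIn PredictionSet voxelwise SD uncertainty maps.
#' @export
setMethod("uncertaintyMaps", "PredictionSet", function(x) x@uncertaintyMaps)

#' @describeIn PredictionSet list of sampled maps.
#' @export
setMethod("sampleMaps", "PredictionSet", function(x) x@samples)

#' @describeIn PredictionSet Ktrans of the mean maps.
#' @export
setMethod("ktransMap", "PredictionSet", function(x) x@meanMaps@ktrans)

#' @describeIn PredictionSet Ve of the mean maps.
#' @export
setMethod("veMap", "PredictionSet", function(x) x@meanMaps@ve)

#' @describeIn PredictionSet Vp of the mean maps.
#' @export
setMethod("vpMap", "PredictionSet", function(x) x@meanMaps@vp)

setMethod("show", "TimeGrid", function(object) {
  cat(sprintf("TimeGrid: %d frames, dt = %.4f min (%.1f s), %d baseline frames\n",
              length(object@times), object@dt, object@dt * 60, object@nBaseline))
})

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf("AcquisitionParams: TR = %.4g ms, flip = %.3g deg, r1 = %.3g /s/mM, T10 = %.3g s\n",
              object@trS * 1000, object@flipDeg, object@r1, object@t10S))
})

setMethod("show", "AIFCurve", function(object) {
  cat(sprintf("AIFCurve (%s): %d frames, peak %.2f mM at %.2f min\n",
              object@provenance, length(object@cp), max(object@cp),
              object@grid@times[which.max(object@cp)]))
})

setMethod("show", "PKMaps", function(object) {
  d <- dim(object@ktrans)
  cat(sprintf("PKMaps %dx%dx%d | median (Ktrans, Ve, Vp) over non-zero voxels: ", d[1], d[2], d[3]))
  nz <- object@ktrans > 0 | object@vp > 0
  if (any(nz)) {
    cat(sprintf("(%.4g, %.4g, %.4g)\n", median(object@ktrans[nz]),
                median(object@ve[nz]), median(object@vp[nz])))
  } else cat("(all zero)\n")
})

setMethod("show", "DCESeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("DCESeries '%s': %dx%dx%d voxels x %d frames, dt = %.1f s\n",
              object@subjectId, d[1], d[2], d[3], d[4], object@grid@dt * 60))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d samples, mean uncertainty (Ktrans, Ve, Vp) = (%.4g, %.4g, %.4g)\n",
              length(object@samples),
              mean(object@uncertaintyMaps$ktrans),
              mean(object@uncertaintyMaps$ve),
              mean(object@uncertaintyMaps$vp)))
})

setMethod("show", "ReliabilityReport", function(object) {
  cat("ReliabilityReport\n")
  cat("  similarity:\n"); print(object@similarity)
  cat("  ICC:\n"); print(object@icc)
  cat("  AUROC:\n"); print(object@auroc)
})
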