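#' @import methods
#' @importFrom stats rnorm runif sd qf pf pnorm qnorm approxfun integrate median quantile
NULL

#' Acquisition time grid
#'
#' Uniform temporal sampling of a DCE-MRI series. Times are in minutes
#' throughout the package; \code{nBaseline} counts the pre-contrast frames at
#' the start of the series.
#'
#' @slot times numeric vector of frame times (minutes), strictly increasing,
#'   uniformly spaced.
#' @slot dt frame spacing in minutes.
#' @slot nBaseline number of pre-contrast baseline frames (>= 1).
#' @export
setClass("TimeGrid", representation(
  times = "numeric", dt = "numeric", nBaseline = "integer"
))

setValidity("TimeGrid", function(object) {
  t <- object@times
  if (length(t) < 2L) return("need at least 2 frames")
  d <- diff(t)
  if (any(d <= 0)) return("times must be strictly increasing")
  if (max(abs(d - object@dt)) > 1e-8 * object@dt) return("times must be uniformly spaced with spacing dt")
  if (object@dt <= 0) return("dt must be > 0")
  nb <- object@nBaseline
  if (nb < 1L || nb >= length(t)) return("nBaseline must be >= 1 and < number of frames")
  TRUE
})

#' Construct a TimeGrid
#'
#' @param nFrames number of frames (default 60).
#' @param dt frame spacing in minutes (default 1/12 min = 5 s).
#' @param nBaseline number of pre-contrast frames (default 5).
#' @param t0 time of the first frame in minutes (default 0).
#' @return a \linkS4class{TimeGrid}.
#' @examples
#' g <- timeGrid()
#' nFrames(g)
#' @export
timeGrid <- function(nFrames = 60L, dt = 1 / 12, nBaseline = 5L, t0 = 0) {
  new("TimeGrid", times = t0 + (seq_len(nFrames) - 1L) * dt, dt = dt,
      nBaseline = as.integer(nBaseline))
}

#' SPGR acquisition parameters
#'
#' Spoiled gradient-echo acquisition settings used to convert between contrast
#' concentration and signal intensity. TR and T10 are in seconds, the
#' relaxivity \code{r1} in s^-1 mM^-1; times elsewhere in the package are in
#' minutes (the conversion handles the unit change).
#'
#' @slot trS repetition time, seconds.
#' @slot flipDeg flip angle, degrees, in (0, 90].
#' @slot r1 longitudinal relaxivity of the contrast agent, s^-1 mM^-1.
#' @slot t10S pre-contrast tissue T1, seconds.
#' @slot s0Scale equilibrium signal scale (arbitrary units).
#' @export
setClass("AcquisitionParams", representation(
  trS = "numeric", flipDeg = "numeric", r1 = "numeric",
  t10S = "numeric", s0Scale = "numeric"
))

setValidity("AcquisitionParams", function(object) {
  v <- c(object@trS, object@flipDeg, object@r1, object@t10S, object@s0Scale)
  if (any(!is.finite(v)) || any(v <= 0)) return("all acquisition parameters must be finite and > 0")
  if (object@flipDeg > 90) return("flipDeg must be in (0, 90]")
  TRUE
})

#' Construct AcquisitionParams
#'
#' Defaults describe a 3-T 3D SPGR DCE protocol: TR 2.8 ms, flip 10 degrees,
#' r1 3.3 s^-1 mM^-1, T10 1.5 s.
#'
#' @param trS repetition time in seconds.
#' @param flipDeg flip angle in degrees.
#' @param r1 contrast relaxivity in s^-1 mM^-1.
#' @param t10S pre-contrast T1 in seconds.
#' @param s0Scale equilibrium signal scale.
#' @return an \linkS4class{AcquisitionParams}.
#' @export
acquisitionParams <- function(trS = 0.0028, flipDeg = 10, r1 = 3.3,
                              t10S = 1.5, s0Scale = 1000) {
  new("AcquisitionParams", trS = trS, flipDeg = flipDeg, r1 = r1,
      t10S = t10S, s0Scale = s0Scale)
}

#' Arterial input function curve
#'
#' Plasma contrast concentration Cp(t) (mM) on a \linkS4class{TimeGrid}.
#'
#' @slot cp plasma concentration per frame, mM, non-negative, zero over the
#'   baseline frames.
#' @slot grid the \linkS4class{TimeGrid} the curve lives on.
#' @slot provenance one of "population-model", "extracted", "perturbed".
#' @export
setClass("AIFCurve", representation(
  cp = "numeric", grid = "TimeGrid", provenance = "character"
))

setValidity("AIFCurve", function(object) {
  if (length(object@cp) != length(object@grid@times)) return("cp length must match grid")
  if (any(!is.finite(object@cp))) return("cp must be finite")
  if (any(object@cp < -1e-9)) return("cp must be non-negative")
  nb <- object@grid@nBaseline
  if (any(abs(object@cp[seq_len(nb)]) > 1e-9)) return("cp must be zero over baseline frames")
  if (!object@provenance %in% c("population-model", "extracted", "perturbed"))
    return("unknown provenance")
  TRUE
})

#' Construct an AIFCurve
#' @param cp plasma concentration vector (mM).
#' @param grid a \linkS4class{TimeGrid}.
#' @param provenance curve origin label.
#' @return an \linkS4class{AIFCurve}.
#' @export
aifCurve <- function(cp, grid, provenance = "population-model") {
  new("AIFCurve", cp = as.numeric(cp), grid = grid, provenance = provenance)
}

#' Voxelwise pharmacokinetic parameter maps
#'
#' The extended-Tofts parameter triplet per voxel: Ktrans (volume transfer
#' constant, min^-1), Ve (extravascular extracellular fraction) and Vp (plasma
#' fraction). Maps are 3D arrays with identical dimensions; the efflux rate
#' kep = Ktrans/Ve is derived on demand (\code{\link{kepMap}}), reported 0
#' where Ktrans = 0 by convention.
#'
#' @slot ktrans 3D array, min^-1, >= 0.
#' @slot ve 3D array, dimensionless in [0, 1].
#' @slot vp 3D array, dimensionless in [0, 1]; ve + vp <= 1 voxelwise.
#' @export
setClass("PKMaps", representation(ktrans = "array", ve = "array", vp = "array"))

setValidity("PKMaps", function(object) {
  dk <- dim(object@ktrans)
  if (length(dk) != 3L) return("maps must be 3D arrays")
  if (!identical(dk, dim(object@ve)) || !identical(dk, dim(object@vp)))
    return("ktrans, ve, vp must have identical dimensions")
  tol <- 1e-8
  if (any(object@ktrans < -tol)) return("ktrans must be >= 0")
  if (any(object@ve < -tol) || any(object@ve > 1 + tol)) return("ve must be in [0, 1]")
  if (any(object@vp < -tol) || any(object@vp > 1 + tol)) return("vp must be in [0, 1]")
  if (any(object@ve + object@vp > 1 + 1e-6)) return("ve + vp must be <= 1 voxelwise")
  if (any(object@ktrans > tol & object@ve <= tol))
    return("ve must be > 0 wherever ktrans > 0")
  TRUE
})

#' Construct PKMaps
#' @param ktrans,ve,vp 3D arrays (a matrix is promoted to a single-slice array).
#' @return a \linkS4class{PKMaps}.
#' @export
pkMaps <- function(ktrans, ve, vp) {
  as3d <- function(a) {
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    a
  }
  new("PKMaps", ktrans = as3d(ktrans), ve = as3d(ve), vp = as3d(vp))
}

#' 4D DCE-MRI signal series
#'
#' Raw signal intensities on an (x, y, z, t) grid together with the temporal
#' grid and acquisition parameters needed to interpret them.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot grid \linkS4class{TimeGrid}; its length equals dim(data)[4].
#' @slot acq \linkS4class{AcquisitionParams}.
#' @slot subjectId subject identifier.
#' @export
setClass("DCESeries", representation(
  data = "array", grid = "TimeGrid", acq = "AcquisitionParams",
  subjectId = "character"
))

setValidity("DCESeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (x, y, z, t)")
  if (d[4] != length(object@grid@times)) return("4th dimension must match the time grid")
  TRUE
})

#' Construct a DCESeries
#' @param data 4D array (x, y, z, t).
#' @param grid a \linkS4class{TimeGrid}.
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param subjectId subject identifier.
#' @return a \linkS4class{DCESeries}.
#' @export
dceSeries <- function(data, grid, acq = acquisitionParams(), subjectId = "subject") {
  new("DCESeries", data = data, grid = grid, acq = acq, subjectId = subjectId)
}

#' Sampled predictions from the probabilistic network
#'
#' Holds N sampled PK map triplets drawn from the prior latent distribution of
#' the probabilistic U-Net, together with the voxelwise mean maps and the
#' voxelwise standard-deviation uncertainty maps (in parameter units).
#'
#' @slot samples list of \linkS4class{PKMaps}, one per latent draw.
#' @slot meanMaps voxelwise mean over samples.
#' @slot uncertaintyMaps named list (ktrans, ve, vp) of voxelwise standard
#'   deviation arrays.
#' @slot seeds integer seeds used for the draws.
#' @export
setClass("PredictionSet", representation(
  samples = "list", meanMaps = "PKMaps", uncertaintyMaps = "list",
  seeds = "integer"
))

setValidity("PredictionSet", function(object) {
  n <- length(object@samples)
  if (n < 2L) return("need >= 2 samples for uncertainty")
  if (!all(vapply(object@samples, is, TRUE, "PKMaps"))) return("samples must be PKMaps")
  if (!identical(sort(names(object@uncertaintyMaps)), c("ktrans", "ve", "vp")))
    return("uncertaintyMaps must be named ktrans, ve, vp")
  if (any(vapply(object@uncertaintyMaps, function(a) any(a < 0), TRUE)))
    return("uncertainty must be >= 0")
  if (length(object@seeds) != n) return("one seed per sample")
  TRUE
})

#' Reliability and diagnostic evaluation report
#'
#' Assembled output of the validation battery: map similarity (SSIM, NRMSE),
#' agreement across repeated measurements (ICC, Bland-Altman) for the
#' conventional (two AIF raters) and synthetic (N prediction samples)
#' pathways, and diagnostic AUROCs with DeLong confidence intervals and
#' paired comparisons.
#'
#' @slot similarity data.frame of SSIM/NRMSE per parameter and region.
#' @slot icc data.frame of ICC estimates with 95\% CI per parameter/pathway.
#' @slot blandAltman data.frame of mean difference and limits of agreement.
#' @slot auroc data.frame of AUROC with 95\% CI per parameter/task/pathway.
#' @slot pairedTests data.frame of paired DeLong comparisons.
#' @slot info list of run metadata (subject counts, exclusions).
#' @export
setClass("ReliabilityReport", representation(
  similarity = "data.frame", icc = "data.frame", blandAltman = "data.frame",
  auroc = "data.frame", pairedTests = "data.frame", info = "list"
))
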