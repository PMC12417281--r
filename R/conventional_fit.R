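# Conventional pathway: semi-automatic AIF extraction (with seeded
# rater-variability emulation) and voxelwise bounded nonlinear least-squares
# fitting of the extended Tofts model.

.defaultBounds <- function() {
  list(lower = c(ktrans = 0, ve = 1e-4, vp = 0),
       upper = c(ktrans = 5, ve = 1, vp = 1))
}

.defaultInits <- function() {
  list(c(ktrans = 0.02, ve = 0.10, vp = 0.01),
       c(ktrans = 0.10, ve = 0.30, vp = 0.03),
       c(ktrans = 0.50, ve = 0.50, vp = 0.10))
}

#' Semi-automatic AIF extraction from vessel candidate voxels
#'
#' Emulates semi-automatic arterial input function selection: candidate voxels
#' (a vessel mask) are converted to concentration, ranked by peak height with
#' earlier bolus arrival breaking ties, and the top-k curves are averaged and
#' scaled from whole-blood to plasma concentration by 1/(1 - hct). With
#' \code{perturbation = "jitter"} a seeded perturbation re-ranks the
#' candidates (multiplicative noise on the ranking score), applies a small
#' multiplicative scale error (within \code{scaleJitter}) and a bolus delay of
#' -1, 0 or +1 frame — emulating the variability between two independent
#' human AIF selections.
#'
#' @param dce a \linkS4class{DCESeries}.
#' @param candidateMask logical 3D array marking vessel candidate voxels.
#' @param perturbation "none" or "jitter".
#' @param seed integer seed for the jitter (required for "jitter").
#' @param topK number of top-ranked voxels averaged (default 5).
#' @param hct haematocrit for the blood-to-plasma conversion.
#' @param scaleJitter half-width of the uniform multiplicative scale error.
#' @param enhancementFloor minimum acceptable candidate peak (mM); an error is
#'   raised if no candidate reaches it.
#' @param raterId label stored with the selection.
#' @return a list of class "AIFSelection": \code{voxelIndices} (matrix of
#'   (x,y,z) rows actually used), \code{aif} (an \linkS4class{AIFCurve} with
#'   provenance "extracted" or "perturbed"), \code{raterId}.
#' @export
extractAIF <- function(dce, candidateMask, perturbation = c("none", "jitter"),
                       seed = NULL, topK = 5L, hct = 0.42, scaleJitter = 0.1,
                       enhancementFloor = 0.5, raterId = "rater") {
  perturbation <- match.arg(perturbation)
  stopifnot(is(dce, "DCESeries"))
  idx <- which(candidateMask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("candidate mask is empty")
  d <- dim(dce@data)
  flat <- matrix(aperm(dce@data, c(4, 1, 2, 3)), nrow = d[4])  # [T x vox]
  lin <- (idx[, 3] - 1L) * d[1] * d[2] + (idx[, 2] - 1L) * d[1] + idx[, 1]
  curves <- t(flat[, lin, drop = FALSE])                        # [cand x T]
  conv <- signalToConcentration(curves, dce@acq, nBaseline(dce))
  ct <- conv$ct
  peak <- apply(ct, 1L, max)
  if (max(peak) < enhancementFloor)
    stop("no candidate voxel exceeds the enhancement floor")
  arrival <- apply(ct, 1L, function(v) which(v > 0.1 * max(v))[1])

  scale <- 1; delay <- 0L; rankScore <- peak
  if (perturbation == "jitter") {
    if (is.null(seed)) stop("jitter perturbation requires a seed")
    jit <- withSeed(seed, list(rank = runif(nrow(ct), 0.85, 1.15),
                               scale = runif(1, -scaleJitter, scaleJitter),
                               delay = sample(c(-1L, 0L, 1L), 1L)))
    rankScore <- peak * jit$rank
    scale <- 1 + jit$scale
    delay <- jit$delay
  }
  ord <- order(-rankScore, arrival)
  keep <- ord[seq_len(min(topK, length(ord)))]
  cp <- colMeans(ct[keep, , drop = FALSE]) / (1 - hct) * scale
  if (delay != 0L) {
    n <- length(cp)
    cp <- if (delay > 0L) c(rep(0, delay), cp[seq_len(n - delay)])
          else c(cp[(1L - delay):n], rep(cp[n], -delay))
  }
  cp[seq_len(nBaseline(dce))] <- 0
  cp[cp < 0] <- 0
  structure(list(
    voxelIndices = idx[keep, , drop = FALSE],
    aif = aifCurve(cp, dce@grid,
                   provenance = if (perturbation == "none") "extracted" else "perturbed"),
    raterId = raterId
  ), class = "AIFSelection")
}

# Residuals of the extended Tofts model for one voxel; penalty keeps ve+vp <= 1.
.toftsResiduals <- function(theta, ct, cp, dt, valid, penalty = 50) {
  kep <- if (theta[1] > 0) theta[1] / max(theta[2], 1e-6) else 0
  I <- drop(.leakageIntegral(cp, dt, kep))
  model <- theta[1] * I + theta[3] * cp
  c((model - ct)[valid], penalty * max(0, theta[2] + theta[3] - 1))
}

#' Fit the extended Tofts model to one concentration curve
#'
#' Bounded Levenberg-Marquardt least squares (via \code{minpack.lm::nls.lm})
#' minimising the residual sum of squares between the measured curve and
#' \code{\link{toftsForward}}, with a penalty enforcing ve + vp <= 1. A small
#' deterministic multistart (3 initial points by default) guards against the
#' shallow vp/ktrans trade-off; the solution with the lowest RSS wins, ties
#' broken by the smaller ktrans. Frames that are NaN are dropped; if fewer
#' than \code{minValidFrac} of frames remain the voxel is skipped and
#' zero-filled with a QC flag.
#'
#' @param ct measured tissue concentration per frame, mM (NaN allowed).
#' @param aif an \linkS4class{AIFCurve} on the same grid.
#' @param bounds list with named vectors \code{lower}, \code{upper} over
#'   (ktrans, ve, vp); defaults ktrans in [0, 5] min^-1, ve in [1e-4, 1],
#'   vp in [0, 1].
#' @param inits list of named starting triplets (default: 3 spread starts).
#' @param minValidFrac minimum fraction of non-NaN frames required.
#' @return list (class "FitResult"): \code{params} (named vector ktrans, ve,
#'   vp, kep), \code{rss}, \code{converged}, \code{nIter}, \code{boundsHit}
#'   (logical per parameter), \code{skipped}.
#' @export
fitVoxel <- function(ct, aif, bounds = .defaultBounds(), inits = .defaultInits(),
                     minValidFrac = 0.75) {
  stopifnot(is(aif, "AIFCurve"))
  if (!any(is.finite(aif@cp))) stop("non-finite AIF")
  if (length(ct) != nFrames(aif)) stop("curve and AIF must share the grid")
  valid <- is.finite(ct)
  if (!any(valid)) stop("all-NaN input curve")
  mkres <- function(par, rss, conv, nit, skipped = FALSE) {
    s <- par[["ve"]] + par[["vp"]]
    if (s > 1) {   # the soft penalty tolerates tiny excursions; project back
      par[["ve"]] <- par[["ve"]] / s * (1 - 1e-9)
      par[["vp"]] <- par[["vp"]] / s * (1 - 1e-9)
    }
    bh <- c(ktrans = FALSE, ve = FALSE, vp = FALSE)
    for (nm in names(bh))
      bh[nm] <- par[nm] <= bounds$lower[nm] + 1e-8 || par[nm] >= bounds$upper[nm] - 1e-8
    kep <- if (par[["ktrans"]] > 0) par[["ktrans"]] / par[["ve"]] else 0
    structure(list(params = c(par, kep = kep), rss = rss, converged = conv,
                   nIter = nit, boundsHit = bh, skipped = skipped),
              class = "FitResult")
  }
  if (mean(valid) < minValidFrac)
    return(mkres(c(ktrans = 0, ve = bounds$lower[["ve"]], vp = 0), NA_real_,
                 FALSE, 0L, skipped = TRUE))
  ctv <- ct; ctv[!valid] <- 0
  if (all(abs(ctv) < 1e-12))   # unidentifiable: flat zero curve
    return(mkres(c(ktrans = 0, ve = bounds$lower[["ve"]], vp = 0), 0, TRUE, 0L))
  cp <- aif@cp; dt <- aif@grid@dt
  best <- NULL
  for (init in inits) {
    th0 <- pmin(pmax(init[c("ktrans", "ve", "vp")], bounds$lower), bounds$upper)
    fit <- minpack.lm::nls.lm(
      par = th0, lower = bounds$lower, upper = bounds$upper,
      fn = .toftsResiduals, ct = ctv, cp = cp, dt = dt, valid = valid,
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12, ptol = 1e-12))
    th <- fit$par
    r <- .toftsResiduals(th, ctv, cp, dt, valid)
    rss <- sum(r[seq_len(sum(valid))]^2)
    cand <- list(par = th, rss = rss, conv = fit$info %in% 1:4, nit = fit$niter)
    if (is.null(best) || rss < best$rss - 1e-14 ||
        (abs(rss - best$rss) <= 1e-14 && th[["ktrans"]] < best$par[["ktrans"]]))
      best <- cand
  }
  mkres(unlist(best$par), best$rss, best$conv, best$nit)
}

#' Voxelwise extended Tofts fitting over a volume
#'
#' Converts the signal series to concentration (baseline-referenced SPGR
#' inversion), then applies \code{\link{fitVoxel}} to every voxel inside the
#' mask. Voxels outside the mask are zero. Each voxel is fitted independently,
#' so results do not depend on processing order.
#'
#' @param dce a \linkS4class{DCESeries}.
#' @param aif an \linkS4class{AIFCurve} on the same grid.
#' @param mask logical 3D array of voxels to fit.
#' @param ... passed on to \code{\link{fitVoxel}}.
#' @return list: \code{maps} (\linkS4class{PKMaps}), \code{rss} (3D array, NA
#'   outside mask), \code{converged} and \code{skipped} (logical 3D arrays),
#'   \code{clamped} (3D array, fraction of frames clamped in the signal
#'   inversion).
#' @export
fitVolume <- function(dce, aif, mask, ...) {
  stopifnot(is(dce, "DCESeries"))
  if (nFrames(dce) != nFrames(aif)) stop("grid mismatch between dce and aif")
  d <- dim(dce@data)
  if (!identical(dim(mask), d[1:3])) stop("mask must match volume dimensions")
  z <- array(0, d[1:3])
  out <- list(maps = pkMaps(z, z, z), rss = array(NA_real_, d[1:3]),
              converged = array(FALSE, d[1:3]), skipped = array(FALSE, d[1:3]),
              clamped = array(0, d[1:3]))
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  flat <- matrix(dce@data, nrow = prod(d[1:3]))          # [vox x T]
  conv <- signalToConcentration(flat[idx, , drop = FALSE], dce@acq, nBaseline(dce))
  kt <- ve <- vp <- rss <- numeric(length(idx))
  cvg <- skp <- logical(length(idx))
  for (i in seq_along(idx)) {
    f <- fitVoxel(conv$ct[i, ], aif, ...)
    kt[i] <- f$params[["ktrans"]]; ve[i] <- f$params[["ve"]]
    vp[i] <- f$params[["vp"]]; rss[i] <- f$rss
    cvg[i] <- f$converged; skp[i] <- f$skipped
  }
  out$maps@ktrans[idx] <- kt; out$maps@ve[idx] <- ve; out$maps@vp[idx] <- vp
  out$rss[idx] <- rss; out$converged[idx] <- cvg; out$skipped[idx] <- skp
  out$clamped[idx] <- rowMeans(conv$clamped)
  validObject(out$maps)
  out
}

#' Best RSS on a bounded parameter grid
#'
#' Exhaustive evaluation of the extended Tofts RSS on an n x n x n grid over
#' (ktrans, ve, vp) within bounds — an independent check that the nonlinear
#' fit attains at least grid-level optimality.
#'
#' @param ct measured concentration curve, mM.
#' @param aif an \linkS4class{AIFCurve}.
#' @param n grid points per parameter (default 20).
#' @param bounds as in \code{\link{fitVoxel}}.
#' @return list: \code{rss} (best grid RSS), \code{params} (named triplet).
#' @export
toftsGridSearch <- function(ct, aif, n = 20L, bounds = .defaultBounds()) {
  gk <- seq(bounds$lower[["ktrans"]], bounds$upper[["ktrans"]], length.out = n)
  ge <- seq(bounds$lower[["ve"]], bounds$upper[["ve"]], length.out = n)
  gv <- seq(bounds$lower[["vp"]], bounds$upper[["vp"]], length.out = n)
  cp <- aif@cp; dt <- aif@grid@dt
  ke <- as.vector(outer(gk, ge, function(k, e) ifelse(k > 0, k / e, 0)))
  I <- .leakageIntegral(cp, dt, ke)                  # [(n*n) x T]
  kt <- as.vector(outer(gk, ge, function(k, e) k))
  leak <- I * kt                                     # ktrans * integral
  best <- list(rss = Inf, params = NULL)
  for (v in gv) {
    resid <- sweep(leak, 2L, ct - v * cp, "-")
    rss <- rowSums(resid^2)
    j <- which.min(rss)
    if (rss[j] < best$rss) {
      best$rss <- rss[j]
      best$params <- c(ktrans = kt[j], ve = ge[(j - 1) %/% n + 1], vp = v)
    }
  }
  best
}
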