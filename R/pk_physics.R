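# Extended Tofts physics. Units everywhere: time in minutes, ktrans/kep in
# min^-1, concentration in mM; TR and T1 in seconds (converted inside the
# signal equations). Getting s vs min wrong is the classic DCE bug — every
# function states its units.

#' Construct a validated PK parameter triplet
#'
#' @param ktrans volume transfer constant, min^-1, >= 0.
#' @param ve extravascular extracellular volume fraction in (0, 1]; may be 0
#'   only when ktrans = 0 (non-enhancing tissue).
#' @param vp plasma volume fraction in [0, 1]; ve + vp <= 1.
#' @return named numeric vector c(ktrans, ve, vp, kep); kep = ktrans/ve, 0 by
#'   convention when ktrans = 0.
#' @examples
#' pkParams(0.1, 0.2, 0.02)
#' @export
pkParams <- function(ktrans, ve, vp) {
  if (!is.finite(ktrans) || ktrans < 0) stop("ktrans must be finite and >= 0")
  if (!is.finite(ve) || ve < 0 || ve > 1) stop("ve must be in [0, 1]")
  if (ktrans > 0 && ve == 0) stop("ve = 0 with ktrans > 0: kep undefined")
  if (!is.finite(vp) || vp < 0 || vp > 1) stop("vp must be in [0, 1]")
  if (ve + vp > 1 + 1e-12) stop("ve + vp must be <= 1")
  kep <- if (ktrans == 0) 0 else ktrans / ve
  c(ktrans = ktrans, ve = ve, vp = vp, kep = kep)
}

# Interval weights for the exponential-kernel convolution with piecewise-linear
# Cp: over one interval of width dt, with kernel exp(-a (dt - s)),
#   J0 = int_0^dt e^{-a(dt-s)} ds,  J1 = int_0^dt (s/dt) e^{-a(dt-s)} ds.
# Series expansion below x = a*dt = 1e-4 avoids catastrophic cancellation.
.expWeights <- function(a, dt) {
  x <- a * dt
  E <- exp(-x)
  small <- x < 1e-4
  J0 <- ifelse(small, dt * (1 - x / 2 + x^2 / 6), -expm1(-x) / a)
  J1num <- -expm1(-x) - x * E            # = 1 - E(1 + x)
  J1 <- ifelse(small, dt * (0.5 - x / 3 + x^2 / 8), J0 - J1num / (a^2 * dt))
  list(E = E, J0 = J0, J1 = J1)
}

# Vectorised over kep: tissue leakage integral
#   I(t_i) = int_0^{t_i} Cp(tau) exp(-kep (t_i - tau)) dtau
# with Cp piecewise linear between frames; exact per-interval exponential
# handling (log-trapezoid), so the scheme is exact for the interpolated Cp
# and O(dt^2) against a continuous Cp.
.leakageIntegral <- function(cp, dt, kep) {
  m <- length(kep)
  Tn <- length(cp)
  w <- .expWeights(pmax(kep, 0), dt)
  I <- matrix(0, m, Tn)
  for (i in 2:Tn) {
    I[, i] <- I[, i - 1] * w$E + cp[i - 1] * (w$J0 - w$J1) + cp[i] * w$J1
  }
  I
}

#' Extended Tofts forward model
#'
#' Computes the tissue concentration curve
#' \deqn{C_t(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(\tau)
#'   e^{-k_{ep}(t-\tau)} d\tau}
#' on the AIF's time grid, treating Cp as piecewise linear between frames and
#' integrating the exponential kernel exactly over each interval.
#'
#' @param params a triplet from \code{\link{pkParams}} (or any numeric vector
#'   with named elements ktrans, ve, vp).
#' @param aif an \linkS4class{AIFCurve} on a uniform grid.
#' @return numeric tissue concentration per frame, mM.
#' @examples
#' aif <- populationAIF(timeGrid())
#' ct <- toftsForward(pkParams(0.1, 0.2, 0.02), aif)
#' @export
toftsForward <- function(params, aif) {
  stopifnot(is(aif, "AIFCurve"))
  p <- pkParams(params[["ktrans"]], params[["ve"]], params[["vp"]])
  drop(toftsForwardBatch(p[["ktrans"]], p[["ve"]], p[["vp"]], aif))
}

#' Vectorised extended Tofts forward model
#'
#' Evaluates the forward model for many parameter triplets against one AIF in
#' a single pass; used by the phantom renderer and the grid-search utilities.
#'
#' @param ktrans,ve,vp numeric vectors of equal length (recycled scalars
#'   allowed), same meaning/units as \code{\link{pkParams}}.
#' @param aif an \linkS4class{AIFCurve}.
#' @return matrix [length(ktrans) x nFrames] of tissue concentrations, mM.
#' @export
toftsForwardBatch <- function(ktrans, ve, vp, aif) {
  n <- max(length(ktrans), length(ve), length(vp))
  ktrans <- rep_len(ktrans, n); ve <- rep_len(ve, n); vp <- rep_len(vp, n)
  if (any(ktrans > 0 & ve <= 0)) stop("ve = 0 with ktrans > 0: kep undefined")
  kep <- ifelse(ktrans > 0, ktrans / pmax(ve, 1e-300), 0)
  cp <- aif@cp
  I <- .leakageIntegral(cp, aif@grid@dt, kep)
  ktrans * I + outer(vp, cp)
}

.defaultAIFModels <- function() {
  path <- system.file("extdata", "aif_models.yaml", package = "PKSynth")
  yaml::read_yaml(path)
}

#' Population arterial input function
#'
#' Evaluates a population AIF model on a time grid, shifted to a bolus-arrival
#' time \code{onset}. Two functional forms are provided: a mixed
#' gaussian-plus-sigmoid form (two Gaussian bolus passes plus an
#' exponentially decaying sigmoid washout, the Parker population shape;
#' default coefficients shipped in \code{extdata/aif_models.yaml}) and a
#' simpler biexponential washout with a fast bolus ramp. Whole-blood forms
#' are converted to plasma concentration via the haematocrit.
#'
#' @param grid a \linkS4class{TimeGrid}.
#' @param model "parker-mixed" or "biexponential".
#' @param coef named list of model coefficients; defaults come from the
#'   shipped YAML config (see \code{aif_models.yaml} for names and units).
#' @param onset bolus arrival time in minutes; must be at or after the last
#'   baseline frame. Default: half a frame after the last baseline frame.
#' @param hct haematocrit used for the blood-to-plasma conversion of the
#'   gaussian-sigmoid form (its coefficients describe whole blood).
#' @return an \linkS4class{AIFCurve} with provenance "population-model".
#' @examples
#' aif <- populationAIF(timeGrid())
#' max(aifValues(aif))
#' @export
populationAIF <- function(grid, model = c("parker-mixed", "biexponential"),
                          coef = NULL, onset = NULL, hct = 0.42) {
  model <- match.arg(model)
  cfg <- .defaultAIFModels()[[model]]
  if (is.null(coef)) coef <- cfg$coefficients
  need <- names(.defaultAIFModels()[[model]]$coefficients)
  if (!setequal(names(coef), need))
    stop(sprintf("coefficients for '%s' must be exactly: %s", model,
                 paste(need, collapse = ", ")))
  nb <- grid@nBaseline
  if (is.null(onset)) onset <- grid@times[nb] + grid@dt / 2
  if (onset < grid@times[nb] - 1e-12)
    stop("onset must be at or after the last baseline frame")
  tp <- pmax(grid@times - onset, 0)
  cp <- .aifClosedForm(model, coef, hct)(tp)
  cp[grid@times < onset] <- 0
  aifCurve(cp, grid, provenance = "population-model")
}

# Closed-form Cp(t') as a function of time since bolus arrival (minutes).
.aifClosedForm <- function(model, coef, hct) {
  cf <- lapply(coef, as.numeric)
  if (model == "parker-mixed") {
    with(cf, function(tp) {
      g1 <- A1 / (sigma1 * sqrt(2 * pi)) * exp(-(tp - T1)^2 / (2 * sigma1^2))
      g2 <- A2 / (sigma2 * sqrt(2 * pi)) * exp(-(tp - T2)^2 / (2 * sigma2^2))
      sig <- alpha * exp(-beta * tp) / (1 + exp(-s * (tp - tau)))
      (g1 + g2 + sig) / (1 - hct) * (tp > 0)
    })
  } else {
    with(cf, function(tp) {
      (A1 * exp(-m1 * tp) + A2 * exp(-m2 * tp)) * (1 - exp(-m0 * tp)) * (tp > 0)
    })
  }
}

# SPGR steady-state signal for given R1 (s^-1): S = s0 sin(a) (1-E1)/(1-E1 cos(a))
.spgr <- function(R1, acq) {
  a <- acq@flipDeg * pi / 180
  E1 <- exp(-acq@trS * R1)
  acq@s0Scale * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

#' Convert tissue concentration to SPGR signal intensity
#'
#' Applies the spoiled gradient-echo steady-state equation with
#' R1(t) = 1/T10 + r1 * Ct(t). Signal is strictly increasing in Ct for flip
#' angles in (0, 90] and equals the pre-contrast baseline where Ct = 0.
#'
#' @param ct concentration (mM): vector, matrix or array; shape preserved.
#' @param acq an \linkS4class{AcquisitionParams}.
#' @return signal intensities, same shape as \code{ct}.
#' @export
concentrationToSignal <- function(ct, acq) {
  if (any(ct < -1e-9, na.rm = TRUE)) stop("ct must be >= 0")
  out <- .spgr(1 / acq@t10S + acq@r1 * ct, acq)
  attributes(out) <- attributes(ct)
  out
}

#' Convert SPGR signal to tissue concentration
#'
#' Inverts \code{\link{concentrationToSignal}}. The per-voxel equilibrium
#' signal is estimated from the mean of the pre-contrast baseline frames, so
#' the baseline concentration has mean zero by construction (before
#' clamping). Signals implying non-physical R1 (noise pushing intensity below
#' the invertibility floor) are clamped to concentration 0 and flagged.
#'
#' @param si signal: vector (one voxel's curve) or matrix [voxels x frames].
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param nBaseline number of pre-contrast frames used to estimate the
#'   baseline signal (>= 1).
#' @return list with \code{ct} (same shape as \code{si}, mM) and
#'   \code{clamped} (logical, same shape; TRUE where clamping occurred).
#' @export
signalToConcentration <- function(si, acq, nBaseline) {
  vec <- is.null(dim(si))
  S <- if (vec) matrix(si, nrow = 1L) else si
  nBaseline <- as.integer(nBaseline)
  if (nBaseline < 1L || nBaseline >= ncol(S)) stop("need >= 1 baseline frame (< nFrames)")
  a <- acq@flipDeg * pi / 180
  sb <- rowMeans(S[, seq_len(nBaseline), drop = FALSE])
  if (any(sb <= 0)) stop("baseline mean signal must be > 0")
  E10 <- exp(-acq@trS / acq@t10S)
  s0 <- sb * (1 - E10 * cos(a)) / (sin(a) * (1 - E10))
  x <- S / (s0 * sin(a))
  E1raw <- (1 - x) / (1 - x * cos(a))
  E1 <- pmin(pmax(E1raw, 1e-12), 1 - 1e-12)
  R1 <- -log(E1) / acq@trS
  ct <- (R1 - 1 / acq@t10S) / acq@r1
  # re-zero on the baseline, then clamp negatives (non-invertible noise)
  ct <- ct - rowMeans(ct[, seq_len(nBaseline), drop = FALSE])
  clamped <- (ct < 0) | (E1raw >= 1 - 1e-12) | (E1raw <= 1e-12)
  ct[ct < 0] <- 0
  if (vec) list(ct = drop(ct), clamped = drop(clamped))
  else list(ct = ct, clamped = clamped)
}
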