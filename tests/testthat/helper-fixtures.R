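# Shared small fixtures, built in code.

fixGrid <- function(nFrames = 60L, dt = 1 / 12, nBaseline = 5L)
  timeGrid(nFrames, dt, nBaseline)

fixAIF <- function(grid = fixGrid()) populationAIF(grid)

fixAcq <- function() acquisitionParams()

# an AIF that steps from 0 to `level` right after the single baseline frame
stepAIF <- function(nFrames = 60L, dt = 0.1, level = 1) {
  g <- timeGrid(nFrames, dt, nBaseline = 1L)
  cp <- c(0, rep(level, nFrames - 1L))
  aifCurve(cp, g, provenance = "population-model")
}

# adaptive-quadrature evaluation of the extended Tofts integral treating the
# sampled Cp as piecewise linear (the same curve the discrete scheme sees);
# integrated interval-by-interval so the quadrature never straddles a kink
quadTofts <- function(params, aif) {
  tt <- times(aif)
  cpf <- approxfun(tt, aifValues(aif), rule = 2)
  kep <- if (params[["ktrans"]] > 0) params[["ktrans"]] / params[["ve"]] else 0
  sapply(seq_along(tt), function(i) {
    ti <- tt[i]
    I <- 0
    if (i > 1L) {
      for (j in 2:i) {
        I <- I + integrate(function(u) cpf(u) * exp(-kep * (ti - u)),
                           tt[j - 1L], tt[j], rel.tol = 1e-10,
                           abs.tol = 1e-13)$value
      }
    }
    params[["vp"]] * cpf(ti) + params[["ktrans"]] * I
  })
}

# deterministic 16x16 test images for the SSIM oracle comparison
ssimFixture <- function() {
  i <- 1:16
  a <- outer(i, i, function(x, y) sin(x * 0.7) + cos(y * 1.3))
  b <- 0.9 * a + 0.1 * outer(i, i, function(x, y) sin(x * 1.9) * cos(y * 0.5))
  list(a = a, b = b)
}

tinyModelConfig <- function()
  modelConfig(nFrames = 12L, tcnChannels = 4L, tcnDilations = c(1L, 2L),
              unetChannels = 4L, latentDim = 3L)

# small model sized for the default 60-frame series
tinyModelConfig60 <- function()
  modelConfig(tcnChannels = 4L, unetChannels = 4L, latentDim = 3L)

tinyRenderedCohort <- function(n = 6L, seed = 5L, noiseSd = 0,
                               shape = c(16L, 16L, 1L))
  generateCohort(n, seed = seed, shape = shape, noiseSd = noiseSd)
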