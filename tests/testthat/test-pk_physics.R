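test_that("population AIF respects causality and degenerate coefficients", {
  g <- fixGrid()
  for (m in c("parker-mixed", "biexponential")) {
    aif <- populationAIF(g, model = m)
    expect_s4_class(aif, "AIFCurve")
    expect_identical(aifValues(aif)[seq_len(nBaseline(g))], rep(0, nBaseline(g)))
    onset <- times(aif)[nBaseline(g)] + g@dt / 2
    expect_true(all(aifValues(aif)[times(aif) < onset] == 0))
    expect_gt(max(aifValues(aif)), 0)
  }
  z <- populationAIF(g, model = "biexponential",
                     coef = list(A1 = 0, A2 = 0, m1 = 0.144, m2 = 0.0111, m0 = 25))
  expect_true(all(aifValues(z) == 0))
  expect_error(populationAIF(g, model = "nonesuch"))
  expect_error(populationAIF(g, model = "biexponential", coef = list(A1 = 1)),
               "coefficients")
})

test_that("AIF evaluated on a fine grid resolves the closed-form peak", {
  # coarse grid fine enough to sample the first-pass peak to < 1%
  g <- timeGrid(nFrames = 200L, dt = 0.01, nBaseline = 5L)
  onset <- g@times[nBaseline(g)] + g@dt / 2
  coarse <- populationAIF(g, onset = onset)
  gf <- timeGrid(nFrames = 20000L, dt = 1e-4, nBaseline = 401L)
  fine <- populationAIF(gf, onset = onset)
  expect_lt(abs(max(aifValues(coarse)) - max(aifValues(fine))) /
              max(aifValues(fine)), 0.01)
  expect_lt(abs(times(coarse)[which.max(aifValues(coarse))] -
                  times(fine)[which.max(aifValues(fine))]), 0.011)
})

test_that("extended Tofts forward model handles limiting cases exactly", {
  aif <- fixAIF()
  expect_equal(toftsForward(pkParams(0, 0, 0), aif), rep(0, nFrames(aif)))
  # pure-plasma limit: Ct = vp * Cp exactly
  expect_equal(toftsForward(pkParams(0, 0.3, 0.05), aif),
               0.05 * aifValues(aif), tolerance = 1e-12)
  # zero inflow before bolus arrival
  ct <- toftsForward(pkParams(0.2, 0.3, 0.05), aif)
  nb <- nBaseline(aif@grid)
  expect_identical(ct[seq_len(nb)], rep(0, nb))
  expect_error(toftsForwardBatch(0.1, 0, 0.05, aif), "kep undefined")
})

test_that("step-response matches the closed form after grid refinement", {
  # Cp = unit step; Ct(t) = vp + ktrans (1 - exp(-kep t)) / kep
  p <- pkParams(0.1, 0.2, 0.02)
  aif <- stepAIF(nFrames = 3000L, dt = 0.002)
  ct <- toftsForward(p, aif)
  tt <- times(aif) - times(aif)[2]   # time since step onset
  keep <- which(times(aif) >= 1)     # away from the single ramp interval
  closed <- p[["vp"]] + p[["ktrans"]] * (1 - exp(-p[["kep"]] * tt[keep])) / p[["kep"]]
  expect_lt(max(abs(ct[keep] - closed) / closed), 0.005)
})

test_that("discrete convolution agrees with adaptive quadrature", {
  aif <- fixAIF()
  set.seed(101)
  for (r in 1:5) {
    p <- pkParams(runif(1, 0.01, 1), runif(1, 0.05, 0.6), runif(1, 0.001, 0.2))
    expect_lt(max(abs(toftsForward(p, aif) - quadTofts(p, aif))), 1e-6)
  }
})

test_that("forward model obeys superposition, vp-linearity and ktrans monotonicity", {
  aif <- fixAIF()
  set.seed(7)
  for (r in 1:10) {
    k <- runif(1, 0.05, 0.5); ve <- runif(1, 0.05, 0.4); vp <- runif(1, 0, 0.3)
    full <- toftsForward(pkParams(k, ve, vp), aif)
    leak <- toftsForward(pkParams(k, ve, 0), aif)
    plasma <- toftsForward(pkParams(0, ve, vp), aif)
    expect_equal(full, leak + plasma, tolerance = 1e-12)
    expect_equal(plasma, vp * aifValues(aif), tolerance = 1e-12)
    # at fixed kep the leakage term is linear in ktrans, hence monotone
    k2 <- k * 1.5 + 0.01
    more <- toftsForward(pkParams(k2, ve * k2 / max(k, 1e-9), vp), aif)
    expect_true(all(more - full >= -1e-12))
  }
})

test_that("halving dt shows second-order convergence of the convolution", {
  p <- pkParams(0.3, 0.25, 0.03)
  errAt <- function(dt) {
    n <- round(4 / dt)
    g <- timeGrid(nFrames = n, dt = dt, nBaseline = max(2L, round(0.4 / dt)))
    onset <- 0.45
    aif <- populationAIF(g, onset = onset)
    ct <- toftsForward(p, aif)
    gf <- timeGrid(nFrames = n * 16L, dt = dt / 16,
                   nBaseline = max(2L, round(0.4 / (dt / 16))))
    ctf <- toftsForward(p, populationAIF(gf, onset = onset))
    max(abs(ct - ctf[seq(1, length(ctf), by = 16L)]))
  }
  e1 <- errAt(0.08); e2 <- errAt(0.04)
  expect_gt(e1 / e2, 3)   # O(dt^2): halving dt cuts the error ~4x
})

test_that("SPGR conversion is monotone, baseline-anchored and exactly invertible", {
  acq <- fixAcq()
  expect_equal(concentrationToSignal(rep(0, 10), acq),
               rep(concentrationToSignal(0, acq), 10))
  expect_gt(concentrationToSignal(1.0, acq), concentrationToSignal(0.5, acq))
  ct <- toftsForward(pkParams(0.2, 0.3, 0.05), fixAIF())
  si <- concentrationToSignal(ct, acq)
  back <- signalToConcentration(si, acq, nBaseline = 5L)
  expect_lt(max(abs(back$ct - ct) / max(ct)), 1e-9)
  expect_false(any(back$clamped))
  # constant baseline input maps to zero concentration
  flat <- signalToConcentration(rep(concentrationToSignal(0, acq), 20), acq, 5L)
  expect_equal(flat$ct, rep(0, 20))
  # signal pushed below the invertibility floor is clamped and flagged
  dip <- si; dip[30] <- si[1] * 0.5
  clamped <- signalToConcentration(dip, acq, 5L)
  expect_equal(clamped$ct[30], 0)
  expect_true(clamped$clamped[30])
  expect_error(signalToConcentration(rep(0, 10), acq, 2L), "baseline mean")
})

test_that("parameter and grid validation reject non-physical inputs", {
  expect_error(pkParams(-0.1, 0.2, 0.02))
  expect_error(pkParams(0.1, 0, 0.02), "kep undefined")
  expect_error(pkParams(0.1, 0.7, 0.4), "<= 1")
  expect_silent(pkParams(0, 0, 0))   # non-enhancing tissue is legal
  expect_equal(pkParams(0, 0, 0)[["kep"]], 0)
  expect_error(timeGrid(10, dt = -0.1), "increasing")
  expect_error(acquisitionParams(trS = -1))
  expect_error(aifCurve(rep(1, 60), fixGrid()), "baseline")
})
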