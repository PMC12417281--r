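test_that("fitVoxel recovers noiseless parameters and respects conventions", {
  aif <- fixAIF()
  truth <- pkParams(0.1, 0.2, 0.02)
  ct <- toftsForward(truth, aif)
  f <- fitVoxel(ct, aif)
  expect_true(f$converged)
  for (p in c("ktrans", "ve", "vp"))
    expect_lt(abs(f$params[[p]] - truth[[p]]) / truth[[p]], 1e-3)
  # degenerate flat-zero curve: ktrans = vp = 0, ve pinned at its lower bound
  f0 <- fitVoxel(rep(0, nFrames(aif)), aif)
  expect_equal(f0$params[["ktrans"]], 0)
  expect_equal(f0$params[["vp"]], 0)
  expect_true(f0$boundsHit[["ve"]])
  expect_equal(f0$rss, 0)
  expect_error(fitVoxel(rep(NaN, nFrames(aif)), aif), "all-NaN")
})

test_that("fitVoxel attains at least grid-level optimality on noisy curves", {
  aif <- fixAIF()
  set.seed(21)
  for (r in 1:5) {
    truth <- pkParams(runif(1, 0.02, 0.5), runif(1, 0.1, 0.5), runif(1, 0.005, 0.1))
    ct <- toftsForward(truth, aif) + rnorm(nFrames(aif), 0, 0.02)
    f <- fitVoxel(ct, aif)
    g <- toftsGridSearch(ct, aif, n = 12L)
    expect_lte(f$rss, g$rss + 1e-10)
  }
})

test_that("fitVoxel skips voxels with too few valid frames", {
  aif <- fixAIF()
  ct <- toftsForward(pkParams(0.1, 0.2, 0.02), aif)
  ct[1:20] <- NaN    # 40/60 valid < 75%
  f <- fitVoxel(ct, aif)
  expect_true(f$skipped)
  expect_false(f$converged)
  # with >= 75% valid frames the fit proceeds on the remaining ones
  ct2 <- toftsForward(pkParams(0.1, 0.2, 0.02), aif)
  ct2[c(10, 20, 30)] <- NaN
  f2 <- fitVoxel(ct2, aif)
  expect_false(f2$skipped)
  expect_lt(abs(f2$params[["ktrans"]] - 0.1) / 0.1, 1e-3)
})

test_that("fitVolume reproduces phantom truth and handles empty masks", {
  ph <- buildPhantom(phantomSpec(shape = c(16L, 16L, 1L), tumorRadii = c(3.5, 3),
                                 seed = 3))
  aif <- fixAIF()
  dce <- renderDCE(ph$gt, aif, noiseSd = 0)
  sub <- ph$masks$enhancing_tumor
  fv <- fitVolume(dce, aif, sub)
  idx <- which(sub)
  for (p in c("ktrans", "ve", "vp")) {
    rel <- abs(slot(fv$maps, p)[idx] - slot(ph$gt, p)[idx]) /
      pmax(slot(ph$gt, p)[idx], 1e-6)
    expect_lt(max(rel), 1e-3)
  }
  expect_true(all(slot(fv$maps, "ktrans")[!sub] == 0))
  empty <- fitVolume(dce, aif, array(FALSE, dim(ph$gt@ktrans)))
  expect_true(all(empty$maps@ktrans == 0))
  expect_true(all(is.na(empty$rss)))
  expect_error(fitVolume(dce, populationAIF(timeGrid(30L)), sub), "mismatch")
})

test_that("AIF extraction matches single-voxel truth and jitter is seeded", {
  ph <- buildPhantom(phantomSpec(seed = 4))
  aif <- fixAIF()
  dce <- renderDCE(ph$gt, aif, noiseSd = 0)
  # single-voxel mask: extracted curve equals that voxel's (plasma-scaled) curve
  one <- array(FALSE, dim(ph$gt@ktrans))
  one[which(ph$masks$vessel)[1]] <- TRUE
  sel <- extractAIF(dce, one, "none")
  expect_equal(nrow(sel$voxelIndices), 1L)
  expect_lt(max(abs(aifValues(sel$aif) - aifValues(aif))), 1e-8)
  # determinism: same jitter seed twice gives identical selections
  s1 <- extractAIF(dce, ph$masks$vessel, "jitter", seed = 33L)
  s2 <- extractAIF(dce, ph$masks$vessel, "jitter", seed = 33L)
  expect_identical(aifValues(s1$aif), aifValues(s2$aif))
  expect_identical(s1$voxelIndices, s2$voxelIndices)
  expect_identical(s1$aif@provenance, "perturbed")
  # different seeds perturb the curve
  s3 <- extractAIF(dce, ph$masks$vessel, "jitter", seed = 34L)
  expect_gt(max(abs(aifValues(s1$aif) - aifValues(s3$aif))), 0)
  expect_error(extractAIF(dce, array(FALSE, dim(ph$gt@ktrans)), "none"), "empty")
  # enhancement floor: flat tissue voxels only
  flat <- array(FALSE, dim(ph$gt@ktrans)); flat[1, 1, 1] <- TRUE
  expect_error(extractAIF(dce, flat, "none"), "enhancement floor")
})

test_that("distinct AIF raters reduce downstream agreement below unity", {
  ph <- buildPhantom(phantomSpec(seed = 9))
  aif <- fixAIF()
  dce <- renderDCE(ph$gt, aif, noiseSd = 0.5, seed = 2)
  roi <- which(ph$masks$enhancing_tumor)[1:12]
  sub <- array(FALSE, dim(ph$gt@ktrans)); sub[roi] <- TRUE
  sA <- extractAIF(dce, ph$masks$vessel, "jitter", seed = 1L)
  sB <- extractAIF(dce, ph$masks$vessel, "jitter", seed = 2L)
  fA <- fitVolume(dce, sA$aif, sub)$maps
  fB <- fitVolume(dce, sB$aif, sub)$maps
  # the two raters disagree strictly somewhere (the variability channel)
  expect_gt(max(abs(fA@ktrans[roi] - fB@ktrans[roi])), 0)
})
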