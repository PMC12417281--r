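test_that("phantom geometry and determinism behave as specified", {
  sp <- phantomSpec(seed = 12L)
  a <- buildPhantom(sp); b <- buildPhantom(sp)
  expect_identical(a$gt@ktrans, b$gt@ktrans)
  expect_identical(a$classMap, b$classMap)
  expect_true(all(a$masks$enhancing_tumor <= a$masks$whole_tumor))
  expect_true(all(a$masks$whole_tumor <= a$masks$brain))
  expect_true(any(a$masks$vessel))
  # voxelwise PK invariants hold after truncation
  expect_true(all(a$gt@ve + a$gt@vp <= 1 + 1e-9))
  expect_true(all(a$gt@ktrans >= 0))
  # zero tumour radius: no tumour classes, empty enhancing mask
  z <- buildPhantom(phantomSpec(tumorRadii = c(0, 0), seed = 1L))
  expect_false(any(z$masks$enhancing_tumor))
  expect_false(any(z$masks$whole_tumor))
  expect_true(all(z$classMap %in% c(0L, 1L, 5L)))
  expect_error(phantomSpec(shape = c(8L, 8L, 1L)))
  expect_error(phantomSpec(tumorRadii = c(20, 20)), "larger")
})

test_that("class samples match their configured distributions", {
  # big phantom so each class exceeds 500 voxels; means within 3 SE
  sp <- phantomSpec(shape = c(96L, 96L, 1L), tumorRadii = c(22, 20), seed = 8L)
  ph <- buildPhantom(sp)
  cls <- phantomClasses()
  for (cl in list(c(1L, "normal"), c(3L, "tumor_rim"))) {
    idx <- which(ph$classMap == as.integer(cl[[1]]))
    expect_gt(length(idx), 500L)
    for (p in c("ktrans", "ve", "vp")) {
      mu <- cls[[cl[[2]]]]$center[[p]]; s <- cls[[cl[[2]]]]$sdlog[[p]]
      m <- exp(log(mu) + s^2 / 2)             # log-normal mean
      sdv <- m * sqrt(exp(s^2) - 1)
      got <- mean(slot(ph$gt, p)[idx])
      expect_lt(abs(got - m), 3 * sdv / sqrt(length(idx)))
    }
  }
})

test_that("rendering honours noise, frame count and invertibility", {
  ph <- buildPhantom(phantomSpec(seed = 2L))
  aif <- fixAIF()
  dce <- renderDCE(ph$gt, aif, noiseSd = 0)
  expect_equal(dim(dce@data)[4], 60L)
  # zero-PK phantom renders a flat baseline everywhere
  d <- dim(ph$gt@ktrans)
  zero <- pkMaps(array(0, d), array(0, d), array(0, d))
  flat <- renderDCE(zero, aif, noiseSd = 0)
  expect_equal(max(flat@data) - min(flat@data), 0)
  # determinism of the noise given a seed
  n1 <- renderDCE(ph$gt, aif, noiseSd = 1, seed = 3L)
  n2 <- renderDCE(ph$gt, aif, noiseSd = 1, seed = 3L)
  expect_identical(n1@data, n2@data)
  expect_error(renderDCE(ph$gt, aif, noiseSd = -1), "noiseSd")
})

test_that("fit error grows with the noise level", {
  ph <- buildPhantom(phantomSpec(seed = 6L))
  aif <- fixAIF()
  roi <- which(ph$masks$enhancing_tumor)[1:15]
  sub <- array(FALSE, dim(ph$gt@ktrans)); sub[roi] <- TRUE
  err <- sapply(c(0, 1, 3), function(ns) {
    e <- 0
    for (s in 1:3) {
      dce <- renderDCE(ph$gt, aif, noiseSd = ns, seed = s)
      f <- fitVolume(dce, aif, sub)$maps
      e <- e + mean(abs(f@ktrans[roi] - ph$gt@ktrans[roi]))
    }
    e / 3
  })
  expect_true(all(diff(err) >= 0))
})

test_that("cohorts are reproducible and splits respect the fractions", {
  a <- generateCohort(12, seed = 3L, render = FALSE)
  b <- generateCohort(12, seed = 3L, render = FALSE)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$subjects[[5]]$gt@ktrans, b$subjects[[5]]$gt@ktrans)
  expect_setequal(unique(a$manifest$split), c("train", "valid", "test"))
  expect_equal(sum(a$manifest$split == "train"), round(0.50 * 12))
  expect_error(generateCohort(2, seed = 1L), ">= 3")
  expect_error(generateCohort(10, split = c(train = 0.5, valid = 0.2, test = 0.2)),
               "sum to 1")
})

test_that("null-effect cohorts carry no label signal; shifts follow the binormal law", {
  nullEff <- cohortEffect(gradeRatio = c(ktrans = 1, ve = 1, vp = 1),
                          idhRatio = c(ktrans = 1, ve = 1, vp = 1),
                          subjectSd = c(ktrans = 0.4, ve = 0.2, vp = 0.4))
  co <- generateCohort(200, seed = 17L, effect = nullEff, render = FALSE)
  sc <- vapply(co$subjects, function(s)
    subjectScore(s$gt, s$masks$enhancing_tumor)[["ktrans"]], 0)
  r <- rocAUC(sc, co$manifest$label_grade, positive = "high")
  expect_gt(r$ciUpper, 0.5)
  expect_lt(r$ciLower, 0.5)
  # log-mean shift delta with subject sd sigma: AUROC ~ Phi(delta/(sigma sqrt(2)))
  delta <- 0.8; sigma <- 0.5
  eff <- cohortEffect(gradeRatio = c(ktrans = exp(delta), ve = 1, vp = 1),
                      idhRatio = c(ktrans = 1, ve = 1, vp = 1),
                      subjectSd = c(ktrans = sigma, ve = 0.2, vp = 0.3))
  co2 <- generateCohort(300, seed = 23L, effect = eff, render = FALSE)
  sc2 <- vapply(co2$subjects, function(s)
    subjectScore(s$gt, s$masks$enhancing_tumor)[["ktrans"]], 0)
  lab <- co2$manifest$label_grade
  a <- rocAUC(sc2, lab, positive = "high")$auc
  expected <- pnorm(delta / (sigma * sqrt(2)))
  n1 <- sum(lab == "high"); n0 <- sum(lab == "low")
  se <- sqrt(expected * (1 - expected) / min(n1, n0))   # conservative MC error
  expect_lt(abs(a - expected), 3 * se)
  # permuting labels destroys the signal
  set.seed(1); perm <- sample(lab)
  expect_lt(rocAUC(sc2, perm, positive = "high")$auc, a)
})
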