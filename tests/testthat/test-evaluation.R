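test_that("SSIM satisfies identity, anticorrelation and a reference value", {
  fx <- ssimFixture()
  expect_equal(ssimMap(fx$a, fx$a, dataRange = 2), 1)
  # anticorrelated fluctuations around a shared local mean: the covariance
  # term turns negative while the luminance term stays near 1
  i <- 1:16
  base <- outer(i, i, function(x, y) sin(x * 0.9) * cos(y * 0.9))
  expect_lt(ssimMap(5 - base, 5 + base, dataRange = 2), 0)
  # reference-implementation oracle (scikit-image, same window settings),
  # frozen from the deterministic fixture
  got <- ssimMap(fx$b, fx$a, dataRange = 2, winSize = 11L, sigma = 1.5)
  expect_equal(got, 0.9874968018004413, tolerance = 1e-9)
  expect_error(ssimMap(fx$a, fx$a, dataRange = 0), "dataRange")
})

test_that("NRMSE matches its closed forms and a brute-force recomputation", {
  set.seed(31)
  b <- array(runif(16 * 16, 0, 2), c(16L, 16L, 1L))
  expect_equal(nrmse(b, b), 0)
  rng <- max(b) - min(b)
  expect_equal(nrmse(b + 0.07 * rng, b), 7, tolerance = 1e-10)
  a <- b + array(rnorm(length(b), 0, 0.1), dim(b))
  mask <- array(runif(length(b)) > 0.4, dim(b))
  brute <- 100 * sqrt(mean((a[mask] - b[mask])^2)) / (max(b[mask]) - min(b[mask]))
  expect_equal(nrmse(a, b, mask), brute, tolerance = 1e-12)
  expect_error(nrmse(b, array(1, dim(b))), "range")
})

test_that("ICC(A,1) matches the ANOVA mean squares and handles edge cases", {
  # worked 6x2 matrix: compare against mean squares from base-R aov
  m <- cbind(c(9, 2, 5, 8, 6, 7), c(10, 4, 6, 9, 7, 8))
  got <- icc(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:6, 2)), rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  names(ms) <- c("subj", "rater", "resid")
  hand <- (ms[["subj"]] - ms[["resid"]]) /
    (ms[["subj"]] + (2 - 1) * ms[["resid"]] +
       2 / 6 * (ms[["rater"]] - ms[["resid"]]))
  expect_equal(got$icc, hand, tolerance = 1e-12)
  # independent reference value (pingouin ICC2 on the same matrix)
  expect_equal(got$icc, 0.8767123, tolerance = 1e-6)
  expect_lt(abs(got$lower - (-0.03)), 0.02)
  expect_lt(abs(got$upper - 0.99), 0.02)
  # identical columns: perfect agreement
  p <- icc(cbind(1:6, 1:6))
  expect_equal(p$icc, 1)
  # independent noise columns at n = 200: CI covers 0
  set.seed(41)
  nullM <- cbind(rnorm(200), rnorm(200))
  z <- icc(nullM)
  expect_gt(z$upper, 0); expect_lt(z$lower, 0)
  # zero between-subject variance is flagged undefined
  expect_true(icc(matrix(5, 4, 2))$undefined)
  expect_error(icc(m[, 1, drop = FALSE]), "raters")
  expect_error(icc(m[1:2, ]), "subjects")
})

test_that("ICC is invariant under a shared affine rescaling of all cells", {
  set.seed(4)
  m <- matrix(rnorm(30, 10, 2), 15, 2) + rnorm(15)
  expect_equal(icc(3.2 * m + 7)$icc, icc(m)$icc, tolerance = 1e-10)
})

test_that("Bland-Altman agreement matches hand arithmetic", {
  x <- c(1, 2, 3, 4)
  expect_equal(unlist(blandAltman(x, x)[1:3]), c(meanDiff = 0, loaLower = 0, loaUpper = 0))
  # differences {-1, +1}: mean 0, LoA = +-1.96 sqrt(2)
  ba <- blandAltman(c(0, 2), c(1, 1))
  expect_equal(ba$meanDiff, 0)
  expect_equal(ba$loaUpper, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loaLower, -1.96 * sqrt(2), tolerance = 1e-12)
  # translation equivariance: shifting y by c shifts all outputs by -c
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  b0 <- blandAltman(a, b); b1 <- blandAltman(a, b + 0.7)
  expect_equal(unlist(b1[1:3]), unlist(b0[1:3]) - 0.7, tolerance = 1e-12)
  expect_error(blandAltman(1, 2), "n >= 2")
})

test_that("AUROC equals the pairwise Mann-Whitney statistic with half ties", {
  bruteAUC <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(rocAUC(c(1, 2, 3, 10, 11), c(F, F, F, T, T), positive = "TRUE")$auc, 1)
  set.seed(13)
  for (r in 1:20) {
    n <- sample(4:12, 1)
    y <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    s <- sample(1:6, n, replace = TRUE)   # heavy ties
    expect_equal(rocAUC(s, y, positive = "TRUE")$auc, bruteAUC(s, y),
                 tolerance = 1e-12)
    # label flip symmetry
    expect_equal(rocAUC(s, !y, positive = "TRUE")$auc, 1 - bruteAUC(s, y),
                 tolerance = 1e-12)
  }
  expect_error(rocAUC(1:4, rep(TRUE, 4)), "two classes")
})

test_that("DeLong variance tracks a jackknife estimate and the paired test is sane", {
  set.seed(77)
  n <- 100
  y <- rep(c(TRUE, FALSE), each = n / 2)
  s <- rnorm(n) + y * 1.2
  v <- rocAUC(s, y, positive = "TRUE")$var
  # leave-one-out jackknife variance of the AUC
  aucOf <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  jk <- vapply(seq_len(n), function(i) aucOf(s[-i], y[-i]), 0)
  vjk <- (n - 1) / n * sum((jk - mean(jk))^2)
  expect_lt(abs(v - vjk) / vjk, 0.10)
  s2 <- s + rnorm(n, 0, 0.5)
  t12 <- delongPairedTest(s, s2, y, positive = "TRUE")
  t21 <- delongPairedTest(s2, s, y, positive = "TRUE")
  expect_equal(t12$diff, -t21$diff, tolerance = 1e-12)
  expect_equal(t12$p, t21$p, tolerance = 1e-12)
  same <- delongPairedTest(s, s, y, positive = "TRUE")
  expect_equal(same$diff, 0); expect_equal(same$p, 1)
})

test_that("subject scores are masked means", {
  d <- c(4L, 4L, 1L)
  u <- pkMaps(array(0.3, d), array(0.4, d), array(0.05, d))
  mask <- array(TRUE, d)
  expect_equal(subjectScore(u, mask),
               c(ktrans = 0.3, ve = 0.4, vp = 0.05))
  two <- array(FALSE, d); two[1:2] <- TRUE
  m <- pkMaps(array(seq(0.1, 1.6, by = 0.1), d) * 0 + array(0.1, d),
              array(0.4, d), array(0.05, d))
  m@ktrans[1] <- 0.1; m@ktrans[2] <- 0.3
  expect_equal(subjectScore(m, two)[["ktrans"]], 0.2)
  set.seed(8)
  r <- pkMaps(array(runif(16), d), array(runif(16, 0, 0.5), d),
              array(runif(16, 0, 0.3), d))
  mk <- array(runif(16) > 0.5, d)
  expect_equal(subjectScore(r, mk)[["ve"]], mean(r@ve[mk]))
  expect_error(subjectScore(r, array(FALSE, d)), "empty")
})

test_that("cohort evaluation assembles a consistent report", {
  co <- tinyRenderedCohort(12, seed = 61L, noiseSd = 0.5)
  testIds <- co$manifest$id[co$manifest$split == "test"]
  # synthetic pathway with identical samples and conventional pathway with
  # duplicated raters: both ICCs must be exactly 1
  conv <- list(); preds <- list()
  for (id in testIds) {
    s <- co$subjects[[match(id, co$manifest$id)]]
    fv <- fitVolume(s$dce, co$aif, s$masks$enhancing_tumor)$maps
    conv[[id]] <- list(fv, fv)
    noisy <- fv
    noisy@ktrans <- fv@ktrans * 1.01 + 0.001
    samples <- list(noisy, noisy, noisy, noisy)
    d <- dim(fv@ktrans)
    zeroU <- list(ktrans = array(0, d), ve = array(0, d), vp = array(0, d))
    preds[[id]] <- new("PredictionSet", samples = samples, meanMaps = noisy,
                       uncertaintyMaps = zeroU, seeds = 1:4)
  }
  rep_ <- evaluateCohort(co, conv, preds)
  expect_s4_class(rep_, "ReliabilityReport")
  expect_true(all(rep_@icc$icc == 1))
  expect_true(all(rep_@blandAltman$meanDiff == 0))
  expect_equal(rep_@info$n + length(rep_@info$excluded), length(testIds))
  expect_setequal(unique(rep_@auroc$task), c("grade", "idh"))
  expect_true(all(rep_@similarity$ssim_total <= 1))
  expect_error(evaluateCohort(co, conv[-1], preds), "missing pathway")
})
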