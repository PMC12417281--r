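test_that("TCN output is purely voxel-local and deterministic", {
  cfg <- tinyModelConfig()
  model <- initModel(cfg, seed = 2L)
  set.seed(5)
  X <- matrix(rnorm(40 * cfg$nFrames), 40, cfg$nFrames)
  F1 <- tcnForward(X, model)
  expect_identical(dim(F1), c(40L, 3L))
  expect_true(all(is.finite(F1)))
  expect_identical(F1, tcnForward(X, model))
  # changing one voxel's curve changes only that voxel's features
  X2 <- X; X2[17, ] <- X2[17, ] + 1
  F2 <- tcnForward(X2, model)
  expect_identical(F1[-17, ], F2[-17, ])
  expect_false(all(F1[17, ] == F2[17, ]))
  # spatial permutation equivariance
  perm <- sample(40)
  expect_equal(tcnForward(X[perm, ], model), F1[perm, ], tolerance = 1e-12)
  # constant-in-time input stays finite and deterministic
  Xc <- matrix(1, 8, cfg$nFrames)
  expect_true(all(is.finite(tcnForward(Xc, model))))
  expect_error(tcnForward(X[, 1:5], model), "frame count")
})

test_that("the configured dilation stack covers the full 60-frame series", {
  cfg <- modelConfig()
  expect_identical(tcnReceptiveField(cfg),
                   (cfg$kernel - 1L) * sum(cfg$tcnDilations) + 1L)
  expect_gte(tcnReceptiveField(cfg), cfg$nFrames)
})

test_that("latent encoders are deterministic with floored positive sigma", {
  cfg <- tinyModelConfig()
  model <- initModel(cfg, seed = 3L)
  set.seed(8)
  F <- array(rnorm(8 * 8 * 3), c(8L, 8L, 3L))
  p1 <- priorEncode(F, model); p2 <- priorEncode(F, model)
  expect_identical(p1$mu, p2$mu); expect_identical(p1$sigma, p2$sigma)
  expect_true(all(p1$sigma >= cfg$sigmaFloor))
  # zero-weight network: mu = 0, sigma = softplus(0)
  z <- model
  z$params$prior <- rapply(z$params$prior, function(x) x * 0, how = "replace")
  pz <- priorEncode(F, z)
  expect_equal(pz$mu, rep(0, cfg$latentDim))
  expect_equal(pz$sigma, rep(log(2), cfg$latentDim), tolerance = 1e-12)
  expect_error(priorEncode(F * NA, model), "non-finite")
})

test_that("KL divergence matches the diagonal-Gaussian closed form", {
  q <- structure(list(mu = c(0.3, -0.2), sigma = c(0.8, 1.4)),
                 class = "LatentDistribution")
  p <- structure(list(mu = c(0.0, 0.5), sigma = c(1.0, 0.9)),
                 class = "LatentDistribution")
  hand <- sum(log(p$sigma / q$sigma) +
                (q$sigma^2 + (q$mu - p$mu)^2) / (2 * p$sigma^2) - 0.5)
  expect_equal(klDivergence(q, p), hand, tolerance = 1e-12)
  expect_equal(klDivergence(p, p), 0)
  expect_gte(klDivergence(q, p), 0)
  # posterior conditioned on maps yields a finite non-negative KL
  cfg <- tinyModelConfig()
  model <- initModel(cfg, seed = 4L)
  set.seed(2)
  F <- array(rnorm(8 * 8 * 3), c(8L, 8L, 3L))
  G <- matrix(abs(rnorm(64 * 3)), 64, 3)
  kl <- klDivergence(posteriorEncode(F, G, model), priorEncode(F, model))
  expect_true(is.finite(kl) && kl >= 0)
})

test_that("decoder is deterministic, non-negative and latent-sensitive", {
  cfg <- tinyModelConfig()
  model <- initModel(cfg, seed = 5L)
  set.seed(3)
  # the refinement head is zero-initialised; give it weight as training would
  model$params$decoder$out$W[] <- rnorm(length(model$params$decoder$out$W), 0, 0.3)
  F <- array(rnorm(8 * 8 * 3), c(8L, 8L, 3L))
  z1 <- rnorm(cfg$latentDim); z2 <- rnorm(cfg$latentDim)
  m1 <- decodePK(F, z1, model)
  expect_identical(ktransMap(m1), ktransMap(decodePK(F, z1, model)))
  expect_true(all(ktransMap(m1) >= 0) && all(veMap(m1) >= 0) && all(vpMap(m1) >= 0))
  m2 <- decodePK(F, z2, model)
  expect_gt(max(abs(ktransMap(m1) - ktransMap(m2))), 0)
  expect_error(decodePK(F, rnorm(cfg$latentDim + 1L), model), "dimension")
})

test_that("prediction sets are seeded, self-consistent and collapsible", {
  cfg <- modelConfig(tcnChannels = 4L, tcnDilations = c(1L, 2L, 4L, 8L, 16L),
                     unetChannels = 4L, latentDim = 3L)
  model <- initModel(cfg, seed = 6L)
  co <- tinyRenderedCohort(3, seed = 30L, noiseSd = 0.5)
  dce <- co$subjects[[1]]$dce
  ps <- predictPK(dce, model, nSamples = 4L, seed = 9L)
  expect_length(sampleMaps(ps), 4L)
  ps2 <- predictPK(dce, model, nSamples = 4L, seed = 9L)
  expect_identical(ktransMap(ps), ktransMap(ps2))
  # mean and SD maps are bit-exact recomputations from the stored samples
  kt <- sapply(sampleMaps(ps), function(s) as.vector(ktransMap(s)))
  expect_identical(as.vector(ktransMap(meanMaps(ps))), rowMeans(kt))
  expect_equal(as.vector(uncertaintyMaps(ps)$ktrans), apply(kt, 1, sd),
               tolerance = 1e-15)
  # mean maps lie within the samples' voxelwise convex hull
  expect_true(all(ktransMap(meanMaps(ps)) <= apply(kt, 1, max) + 1e-12))
  expect_true(all(ktransMap(meanMaps(ps)) >= apply(kt, 1, min) - 1e-12))
  # collapsed latent: all samples identical, uncertainty exactly zero
  pc <- predictPK(dce, model, nSamples = 4L, seed = 9L, collapse = TRUE)
  expect_identical(ktransMap(sampleMaps(pc)[[1]]), ktransMap(sampleMaps(pc)[[4]]))
  expect_true(all(uncertaintyMaps(pc)$ktrans == 0))
  expect_error(predictPK(dce, model, nSamples = 0L), "nSamples")
})

test_that("analytic gradients of the joint objective match finite differences", {
  ns <- asNamespace("PKSynth")
  cfg <- tinyModelConfig()
  model <- initModel(cfg, seed = 3L)
  set.seed(42)  # tiny perturbation breaks structural ReLU ties at exactly 0
  model$params <- ns$.nnMap(model$params, function(x) x + rnorm(length(x), 0, 0.01))
  set.seed(9)
  H <- 8L; W <- 8L; V <- H * W; Tn <- cfg$nFrames
  X <- matrix(rnorm(V * Tn, 0, 0.5), V, Tn)
  Gn <- matrix(abs(rnorm(V * 3, 0.5, 0.3)), V, 3)
  eps <- rnorm(cfg$latentDim)
  lossOf <- function(p) ns$.jointStep(X, Gn, H, W, p, cfg, 0.7, eps)$total
  st <- ns$.jointStep(X, Gn, H, W, model$params, cfg, 0.7, eps)
  h <- 1e-6
  probes <- list(
    list(function(p, d) { p$tcn$blocks[[1]]$conv1$W[[1]][1, 2] <- p$tcn$blocks[[1]]$conv1$W[[1]][1, 2] + d; p },
         st$gTcn$blocks[[1]]$conv1$W[[1]][1, 2]),
    list(function(p, d) { p$tcn$blocks[[2]]$conv2$b[3] <- p$tcn$blocks[[2]]$conv2$b[3] + d; p },
         st$gTcn$blocks[[2]]$conv2$b[3]),
    list(function(p, d) { p$tcn$head1$W[5, 2] <- p$tcn$head1$W[5, 2] + d; p },
         st$gTcn$head1$W[5, 2]),
    list(function(p, d) { p$prior$d$W[2, 4] <- p$prior$d$W[2, 4] + d; p },
         st$gPrior$d$W[2, 4]),
    list(function(p, d) { p$posterior$c2$W[[2]][2, 2] <- p$posterior$c2$W[[2]][2, 2] + d; p },
         st$gPost$c2$W[[2]][2, 2]),
    list(function(p, d) { p$decoder$d2$W[[9]][5, 1] <- p$decoder$d2$W[[9]][5, 1] + d; p },
         st$gDec$d2$W[[9]][5, 1]),
    list(function(p, d) { p$decoder$z1$W[6, 2] <- p$decoder$z1$W[6, 2] + d; p },
         st$gDec$z1$W[6, 2]),
    list(function(p, d) { p$decoder$out$b[2] <- p$decoder$out$b[2] + d; p },
         st$gDec$out$b[2]))
  for (pr in probes) {
    num <- (lossOf(pr[[1]](model$params, h)) - lossOf(pr[[1]](model$params, -h))) / (2 * h)
    expect_lt(abs(pr[[2]] - num) / max(abs(num), 1e-8), 1e-4)
  }
})
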