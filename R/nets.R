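# The two-stage spatiotemporal model: a per-voxel temporal convolutional
# network (stage 1) condenses each voxel's signal-time curve into three
# temporal feature maps, and a probabilistic U-Net (stage 2) integrates
# spatial context and a Gaussian latent space to emit PK maps and, through
# repeated latent draws, uncertainty maps.

#' Model configuration for the two-stage network
#'
#' All architecture sizes are configuration, not constants. The default TCN
#' (kernel 3, dilations 1,2,4,8,16, non-causal) has receptive field
#' (kernel - 1) * 2 * sum(dilations) / 2 + 1 = 63 frames, covering the
#' 60-frame series with few parameters.
#'
#' @param nFrames number of input frames (default 60).
#' @param tcnChannels channel width of the TCN residual blocks.
#' @param tcnDilations dilation per residual block.
#' @param kernel temporal kernel size (odd).
#' @param unetChannels base channel width of the probabilistic U-Net.
#' @param latentDim dimension of the Gaussian latent space.
#' @param sigmaFloor lower bound for latent standard deviations.
#' @param paramScales per-parameter normalisation scales (ktrans, ve, vp);
#'   maps are divided by these before the loss so Ve's larger magnitude does
#'   not dominate.
#' @return list of class "ModelConfig".
#' @export
modelConfig <- function(nFrames = 60L, tcnChannels = 8L,
                        tcnDilations = c(1L, 2L, 4L, 8L, 16L), kernel = 3L,
                        unetChannels = 8L, latentDim = 6L, sigmaFloor = 1e-4,
                        paramScales = c(ktrans = 0.1, ve = 0.3, vp = 0.05)) {
  rf <- (kernel - 1L) * sum(tcnDilations) + 1L
  structure(list(nFrames = as.integer(nFrames), tcnChannels = as.integer(tcnChannels),
                 tcnDilations = as.integer(tcnDilations), kernel = as.integer(kernel),
                 unetChannels = as.integer(unetChannels), latentDim = as.integer(latentDim),
                 sigmaFloor = sigmaFloor, paramScales = paramScales,
                 receptiveField = rf), class = "ModelConfig")
}

#' Receptive field of the configured TCN
#' @param config a \code{\link{modelConfig}}.
#' @return number of frames seen by one output sample.
#' @export
tcnReceptiveField <- function(config) config$receptiveField

#' Initialise model weights
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed integer seed for the weight draws.
#' @return list of class "PKModel": \code{params} (nested weight lists for
#'   tcn, abl head, prior, posterior, decoder) and \code{config}.
#' @export
initModel <- function(config = modelConfig(), seed = 1L) {
  C <- config$tcnChannels; U <- config$unetChannels; L <- config$latentDim
  k <- config$kernel
  params <- withSeed(seed, {
    tcnBlocks <- list()
    cin <- 1L
    for (i in seq_along(config$tcnDilations)) {
      tcnBlocks[[i]] <- list(conv1 = .initConv(cin, C, k), conv2 = .initConv(C, C, k),
                             proj = if (cin != C) .initDense(cin, C) else NULL)
      tcnBlocks[[i]] <- tcnBlocks[[i]][!vapply(tcnBlocks[[i]], is.null, TRUE)]
      cin <- C
    }
    # zero-init output layer: prior and posterior both start at N(0, softplus(0)),
    # so KL starts at 0 and the latents only separate as far as the data warrants
    encoder <- function(cin) list(
      c1 = .initConv(cin, U, 9L), c2 = .initConv(U, U, 9L),
      d = .initDense(U, 2L * L, gain = 0))
    list(
      tcn = list(blocks = tcnBlocks, head1 = .initDense(4L * C, 3L * C),
                 head2 = .initDense(3L * C, 3L)),
      abl = .initDense(3L, 3L),
      prior = encoder(3L),
      posterior = encoder(6L),
      decoder = list(
        e1a = .initConv(3L, U, 9L), e1b = .initConv(U, U, 9L),
        e2a = .initConv(U, 2L * U, 9L), e2b = .initConv(2L * U, 2L * U, 9L),
        bb = .initConv(2L * U, 2L * U, 9L),
        d2 = .initConv(4L * U, 2L * U, 9L),
        d1 = .initConv(3L * U, U, 9L),
        z1 = .initDense(U + L, U),
        out = .initDense(U, 3L, gain = 0))  # zero-init: refinement starts at 0
    )
  })
  structure(list(params = params, config = config), class = "PKModel")
}

#' Normalise a DCE series for the network
#'
#' Per-subject normalisation: the signal is divided by the mean pre-contrast
#' baseline signal over the brain (or whole volume) and shifted by -1, so
#' pre-contrast tissue sits near 0 and enhancement is a relative change.
#' Removes scanner scale while preserving enhancement dynamics.
#'
#' @param dce a \linkS4class{DCESeries}.
#' @param z slice index (the network's spatial unit is a 2D slice).
#' @param mask optional logical 3D array restricting the baseline average.
#' @return matrix [H*W, nFrames] of normalised intensities.
#' @export
normalizeDCE <- function(dce, z = 1L, mask = NULL) {
  d <- dim(dce@data)
  sl <- matrix(dce@data[, , z, ], d[1] * d[2], d[4])
  base <- dce@data[, , , seq_len(nBaseline(dce)), drop = FALSE]
  if (!is.null(mask)) {
    mb <- mean(apply(base, 4, function(v) mean(v[mask])))
  } else mb <- mean(base)
  sl / mb - 1
}

# ---- TCN --------------------------------------------------------------------

.tcnFwd <- function(X, params, config, V, Tn) {
  # X is [V, T]; column-major vectorisation puts element (v, t) at row (t-1)V+v
  Xr <- matrix(as.vector(X), V * Tn, 1L)
  caches <- list(); H <- Xr
  for (i in seq_along(params$blocks)) {
    bp <- params$blocks[[i]]; dil <- config$tcnDilations[i]
    c1 <- .conv1dF(H, bp$conv1, dil, V, Tn)
    H1 <- .relu(c1$Y)
    c2 <- .conv1dF(H1, bp$conv2, dil, V, Tn)
    if (!is.null(bp$proj)) { pr <- .denseF(H, bp$proj); P <- pr$Y } else { pr <- NULL; P <- H }
    S <- c2$Y + P
    caches[[i]] <- list(c1 = c1, A1 = c1$Y, c2 = c2, pr = pr, S = S, Xin = H)
    H <- .relu(S)
  }
  # temporal pooling: fold rows (t-1)V+v to [V, T, C]; concatenate the mean,
  # the max (peak/arrival information a pure average washes out), and the
  # early- and late-window means (first/last third — the wash-in/wash-out
  # contrast that identifies kep), then a small MLP head emits the 3 features
  C <- ncol(H)
  A <- aperm(array(H, c(V, Tn, C)), c(2L, 1L, 3L))     # [T, V, C]
  M <- colMeans(A); dim(M) <- c(V, C)
  AM <- array(A, c(Tn, V * C))
  amax <- max.col(t(AM), ties.method = "first")        # argmax over T per (v,c)
  Mx <- matrix(AM[amax + (seq_len(V * C) - 1L) * Tn], V, C)
  nw <- max(1L, Tn %/% 3L)
  Me <- colMeans(A[seq_len(nw), , , drop = FALSE]); dim(Me) <- c(V, C)
  Ml <- colMeans(A[(Tn - nw + 1L):Tn, , , drop = FALSE]); dim(Ml) <- c(V, C)
  P <- cbind(M, Mx, Me, Ml)
  h1 <- .denseF(P, params$head1)
  hr <- .relu(h1$Y)
  hd <- .denseF(hr, params$head2)
  list(F = hd$Y, caches = caches, P = P, amax = amax, nw = nw, h1 = h1,
       hd = hd, Hlast = H)
}

.tcnBwd <- function(dF, params, config, fw, V, Tn) {
  g <- list(blocks = vector("list", length(params$blocks)))
  h2b <- .denseB(dF, params$head2, fw$hd)
  dH1 <- h2b$dX * (fw$h1$Y > 0)
  h1b <- .denseB(dH1, params$head1, fw$h1)
  g$head1 <- h1b$g; g$head2 <- h2b$g
  C <- ncol(h1b$dX) %/% 4L
  dM <- h1b$dX[, seq_len(C), drop = FALSE]     # [V, C] mean branch
  dMx <- h1b$dX[, C + seq_len(C), drop = FALSE]
  dMe <- h1b$dX[, 2L * C + seq_len(C), drop = FALSE]
  dMl <- h1b$dX[, 3L * C + seq_len(C), drop = FALSE]
  dH <- dM[rep(seq_len(V), Tn), , drop = FALSE] / Tn
  # max branch: route gradient to the argmax frame of each (v, c)
  dA <- array(0, c(Tn, V * C))
  dA[fw$amax + (seq_len(V * C) - 1L) * Tn] <- as.vector(dMx)
  # window means: spread over their frames
  nw <- fw$nw
  dAe <- array(0, c(Tn, V, C)); dAl <- array(0, c(Tn, V, C))
  dAe[seq_len(nw), , ] <- rep(as.vector(dMe) / nw, each = nw)
  dAl[(Tn - nw + 1L):Tn, , ] <- rep(as.vector(dMl) / nw, each = nw)
  dA <- array(dA, c(Tn, V, C)) + dAe + dAl
  dH <- dH + matrix(aperm(dA, c(2L, 1L, 3L)), V * Tn, C)
  for (i in rev(seq_along(params$blocks))) {
    bp <- params$blocks[[i]]; ca <- fw$caches[[i]]; dil <- config$tcnDilations[i]
    dS <- dH * (ca$S > 0)
    b2 <- .conv1dB(dS, bp$conv2, ca$c2, V, Tn)
    dA1 <- b2$dX * (ca$A1 > 0)
    b1 <- .conv1dB(dA1, bp$conv1, ca$c1, V, Tn)
    gb <- list(conv1 = b1$g, conv2 = b2$g)
    dX <- b1$dX
    if (!is.null(bp$proj)) {
      pb <- .denseB(dS, bp$proj, ca$pr)
      gb$proj <- pb$g
      dX <- dX + pb$dX
    } else dX <- dX + dS
    g$blocks[[i]] <- gb
    dH <- dX
  }
  g
}

#' Stage-1 temporal feature maps
#'
#' Runs the temporal convolutional network on each voxel's time curve,
#' producing three feature maps (one per PK parameter) with the input's
#' in-plane geometry. The operation is purely per-voxel: the output at a
#' voxel depends only on that voxel's curve.
#'
#' @param x a \linkS4class{DCESeries} (slice \code{z} is used) or a
#'   pre-normalised matrix [V, nFrames] from \code{\link{normalizeDCE}}.
#' @param model a "PKModel" from \code{\link{initModel}} or a trained
#'   checkpoint.
#' @param z slice index when \code{x} is a series.
#' @return if given a series: array [H, W, 3]; if given a matrix: matrix
#'   [V, 3].
#' @export
tcnForward <- function(x, model, z = 1L) {
  cfg <- model$config
  if (is(x, "DCESeries")) {
    d <- dim(x@data)
    if (d[4] != cfg$nFrames) stop("frame count does not match the trained configuration")
    X <- normalizeDCE(x, z)
    fw <- .tcnFwd(X, model$params$tcn, cfg, nrow(X), ncol(X))
    array(fw$F, c(d[1], d[2], 3L))
  } else {
    if (ncol(x) != cfg$nFrames) stop("frame count does not match the trained configuration")
    .tcnFwd(x, model$params$tcn, cfg, nrow(x), ncol(x))$F
  }
}

# Ablation head: per-voxel 1x1 regression from features to normalised PK maps.
.ablFwd <- function(F, params) {
  hd <- .denseF(F, params$abl)
  list(Y = .softplus(hd$Y), hd = hd)
}

# ---- latent encoders ---------------------------------------------------------

.encFwd <- function(X, p, H, W, cfg) {
  c1 <- .conv2dF(X, p$c1, H, W); h1 <- .relu(c1$Y)
  p1 <- .pool2F(h1, H, W)
  c2 <- .conv2dF(p1, p$c2, H %/% 2L, W %/% 2L); h2 <- .relu(c2$Y)
  p2 <- .pool2F(h2, H %/% 2L, W %/% 2L)
  gmean <- colMeans(p2)
  d <- .denseF(matrix(gmean, 1L), p$d)
  L <- cfg$latentDim
  raw <- drop(d$Y)
  mu <- raw[seq_len(L)]; sraw <- raw[L + seq_len(L)]
  sigma <- pmax(.softplus(sraw), cfg$sigmaFloor)
  list(mu = mu, sigma = sigma, sraw = sraw, c1 = c1, p1 = p1, c2 = c2,
       p2 = p2, gmean = gmean, d = d, H = H, W = W)
}

.encBwd <- function(dmu, dsigma, p, fw, cfg) {
  L <- cfg$latentDim
  act <- .softplus(fw$sraw) > cfg$sigmaFloor
  dsraw <- dsigma * .sigmoid(fw$sraw) * act
  dOut <- matrix(c(dmu, dsraw), 1L)
  db <- .denseB(dOut, p$d, fw$d)
  n2 <- nrow(fw$p2)
  dP2 <- matrix(rep(drop(db$dX) / n2, each = n2), n2)
  dH2 <- .pool2B(dP2, fw$H %/% 2L, fw$W %/% 2L)
  dC2 <- dH2 * (fw$c2$Y > 0)
  b2 <- .conv2dB(dC2, p$c2, fw$c2, fw$H %/% 2L, fw$W %/% 2L)
  dH1 <- .pool2B(b2$dX, fw$H, fw$W)
  dC1 <- dH1 * (fw$c1$Y > 0)
  b1 <- .conv2dB(dC1, p$c1, fw$c1, fw$H, fw$W)
  list(dX = b1$dX, g = list(c1 = b1$g, c2 = b2$g, d = db$g))
}

#' Prior latent distribution from temporal features
#'
#' Deterministic map from the three temporal feature maps to the mean and
#' (floored) standard deviation of the diagonal-Gaussian prior latent.
#'
#' @param features array [H, W, 3] or matrix [H*W, 3] of temporal features.
#' @param model a "PKModel".
#' @return list of class "LatentDistribution" with \code{mu}, \code{sigma}.
#' @export
priorEncode <- function(features, model) {
  X <- .asFeatureMatrix(features)
  if (!all(is.finite(X$m))) stop("non-finite activations in features")
  fw <- .encFwd(X$m, model$params$prior, X$H, X$W, model$config)
  structure(list(mu = fw$mu, sigma = fw$sigma), class = "LatentDistribution")
}

#' Posterior latent distribution from features and ground-truth maps
#'
#' Training-time encoder conditioned on the normalised ground-truth PK maps
#' in addition to the temporal features.
#'
#' @param features array [H, W, 3] or matrix [H*W, 3].
#' @param gt a \linkS4class{PKMaps} (single slice) or matrix [H*W, 3] of
#'   normalised maps.
#' @param model a "PKModel".
#' @return a "LatentDistribution".
#' @export
posteriorEncode <- function(features, gt, model) {
  X <- .asFeatureMatrix(features)
  G <- .normalizeMaps(gt, model$config)
  if (!all(is.finite(X$m)) || !all(is.finite(G))) stop("non-finite activations")
  fw <- .encFwd(cbind(X$m, G), model$params$posterior, X$H, X$W, model$config)
  structure(list(mu = fw$mu, sigma = fw$sigma), class = "LatentDistribution")
}

.asFeatureMatrix <- function(features) {
  if (is.array(features) && length(dim(features)) == 3L) {
    d <- dim(features)
    list(m = matrix(features, d[1] * d[2], d[3]), H = d[1], W = d[2])
  } else {
    H <- as.integer(sqrt(nrow(features)))
    if (H * H != nrow(features))
      stop("pass an [H, W, 3] array for non-square geometries")
    list(m = features, H = H, W = as.integer(nrow(features) / H))
  }
}

.normalizeMaps <- function(gt, cfg, z = 1L) {
  if (is(gt, "PKMaps")) {
    cbind(as.vector(gt@ktrans[, , z]) / cfg$paramScales[["ktrans"]],
          as.vector(gt@ve[, , z]) / cfg$paramScales[["ve"]],
          as.vector(gt@vp[, , z]) / cfg$paramScales[["vp"]])
  } else gt
}

#' KL divergence between two diagonal-Gaussian latent distributions
#'
#' \deqn{KL(q\|p) = \sum_i \log(\sigma_{p,i}/\sigma_{q,i}) +
#'   (\sigma_{q,i}^2 + (\mu_{q,i}-\mu_{p,i})^2)/(2\sigma_{p,i}^2) - 1/2}
#'
#' @param q,p "LatentDistribution" objects (q = posterior, p = prior).
#' @return non-negative scalar.
#' @export
klDivergence <- function(q, p) {
  sum(log(p$sigma / q$sigma) +
        (q$sigma^2 + (q$mu - p$mu)^2) / (2 * p$sigma^2) - 0.5)
}

.klGrads <- function(q, p) {
  dmuq <- (q$mu - p$mu) / p$sigma^2
  list(dmuq = dmuq, dmup = -dmuq,
       dsq = -1 / q$sigma + q$sigma / p$sigma^2,
       dsp = 1 / p$sigma - (q$sigma^2 + (q$mu - p$mu)^2) / p$sigma^3)
}

# ---- decoder (U-Net over features, z broadcast at the final 1x1 block) ------

# base: per-voxel logits from the stage-1 regression head; the U-Net output
# is a spatial refinement added to them before the softplus, so an untrained
# decoder already reproduces the stage-1 estimate
.decFwd <- function(F, z, p, H, W, base = 0) {
  e1a <- .conv2dF(F, p$e1a, H, W); h1a <- .relu(e1a$Y)
  e1b <- .conv2dF(h1a, p$e1b, H, W); h1b <- .relu(e1b$Y)
  p1 <- .pool2F(h1b, H, W)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  e2a <- .conv2dF(p1, p$e2a, H2, W2); h2a <- .relu(e2a$Y)
  e2b <- .conv2dF(h2a, p$e2b, H2, W2); h2b <- .relu(e2b$Y)
  p2 <- .pool2F(h2b, H2, W2)
  H4 <- H2 %/% 2L; W4 <- W2 %/% 2L
  bb <- .conv2dF(p2, p$bb, H4, W4); hb <- .relu(bb$Y)
  u2 <- .up2F(hb, H4, W4)
  c2in <- cbind(u2, h2b)
  d2 <- .conv2dF(c2in, p$d2, H2, W2); hd2 <- .relu(d2$Y)
  u1 <- .up2F(hd2, H2, W2)
  c1in <- cbind(u1, h1b)
  d1 <- .conv2dF(c1in, p$d1, H, W); hd1 <- .relu(d1$Y)
  zb <- matrix(z, H * W, length(z), byrow = TRUE)
  z1 <- .denseF(cbind(hd1, zb), p$z1); hz <- .relu(z1$Y)
  out <- .denseF(hz, p$out)
  preact <- out$Y + base
  Y <- .softplus(preact)
  list(Y = Y, preact = preact, e1a = e1a, e1b = e1b, e2a = e2a, e2b = e2b,
       bb = bb, d2 = d2, d1 = d1, z1 = z1, out = out, h1b = h1b, h2b = h2b,
       H = H, W = W, zlen = length(z))
}

.decBwd <- function(dY, p, fw) {
  H <- fw$H; W <- fw$W; H2 <- H %/% 2L; W2 <- W %/% 2L
  H4 <- H2 %/% 2L; W4 <- W2 %/% 2L
  dOut <- dY * .sigmoid(fw$preact)
  ob <- .denseB(dOut, p$out, fw$out)
  dHz <- ob$dX * (fw$z1$Y > 0)
  zb <- .denseB(dHz, p$z1, fw$z1)
  U <- nrow(p$out$W)                       # decoder channel width
  dHd1 <- zb$dX[, seq_len(U), drop = FALSE]
  dz <- colSums(zb$dX[, U + seq_len(fw$zlen), drop = FALSE])
  dD1 <- dHd1 * (fw$d1$Y > 0)
  b1 <- .conv2dB(dD1, p$d1, fw$d1, H, W)
  C1 <- ncol(fw$h1b)
  dU1 <- b1$dX[, seq_len(ncol(b1$dX) - C1), drop = FALSE]
  dH1b <- b1$dX[, ncol(b1$dX) - C1 + seq_len(C1), drop = FALSE]
  dHd2 <- .up2B(dU1, H2, W2)
  dD2 <- dHd2 * (fw$d2$Y > 0)
  b2 <- .conv2dB(dD2, p$d2, fw$d2, H2, W2)
  C2 <- ncol(fw$h2b)
  dU2 <- b2$dX[, seq_len(ncol(b2$dX) - C2), drop = FALSE]
  dH2b <- b2$dX[, ncol(b2$dX) - C2 + seq_len(C2), drop = FALSE]
  dHb <- .up2B(dU2, H4, W4)
  dBB <- dHb * (fw$bb$Y > 0)
  bbB <- .conv2dB(dBB, p$bb, fw$bb, H4, W4)
  dH2bTot <- dH2b + .pool2B(bbB$dX, H2, W2)
  dE2b <- dH2bTot * (fw$e2b$Y > 0)
  e2bB <- .conv2dB(dE2b, p$e2b, fw$e2b, H2, W2)
  dE2a <- e2bB$dX * (fw$e2a$Y > 0)
  e2aB <- .conv2dB(dE2a, p$e2a, fw$e2a, H2, W2)
  dH1bTot <- dH1b + .pool2B(e2aB$dX, H, W)
  dE1b <- dH1bTot * (fw$e1b$Y > 0)
  e1bB <- .conv2dB(dE1b, p$e1b, fw$e1b, H, W)
  dE1a <- e1bB$dX * (fw$e1a$Y > 0)
  e1aB <- .conv2dB(dE1a, p$e1a, fw$e1a, H, W)
  list(dF = e1aB$dX, dz = dz, dBase = dOut,
       g = list(e1a = e1aB$g, e1b = e1bB$g, e2a = e2aB$g, e2b = e2bB$g,
                bb = bbB$g, d2 = b2$g, d1 = b1$g, z1 = zb$g, out = ob$g))
}

#' Decode PK maps from temporal features and a latent sample
#'
#' Runs the U-Net decoder over the feature maps with the latent vector
#' broadcast-concatenated before the final 1x1 convolutions. The decoder
#' output is a spatial refinement added to the stage-1 regression head's
#' per-voxel logits before the final softplus, so outputs are non-negative
#' by construction and de-normalised to parameter units.
#'
#' @param features array [H, W, 3] of temporal features.
#' @param z latent vector of length \code{latentDim}.
#' @param model a "PKModel".
#' @return a \linkS4class{PKMaps} (single slice).
#' @export
decodePK <- function(features, z, model) {
  cfg <- model$config
  X <- .asFeatureMatrix(features)
  if (length(z) != cfg$latentDim) stop("z dimension does not match configuration")
  if (X$H %% 4L != 0L || X$W %% 4L != 0L) stop("in-plane size must be divisible by 4")
  base <- .denseF(X$m, model$params$abl)$Y
  fw <- .decFwd(X$m, z, model$params$decoder, X$H, X$W, base = base)
  .toPKMaps(fw$Y, cfg$paramScales, X$H, X$W)
}

# de-normalise network outputs and project onto the physical simplex
# (ve + vp <= 1) before constructing validated maps
.toPKMaps <- function(Y, sc, H, W) {
  kt <- Y[, 1] * sc[["ktrans"]]
  # softplus can underflow to exactly 0; keep ve strictly positive so
  # kep = ktrans/ve stays defined wherever ktrans > 0
  ve <- pmin(pmax(Y[, 2] * sc[["ve"]], 1e-6), 1)
  vp <- pmin(Y[, 3] * sc[["vp"]], 1)
  s <- ve + vp
  over <- s > 1
  if (any(over)) {
    f <- (1 - 1e-9) / s[over]
    ve[over] <- ve[over] * f; vp[over] <- vp[over] * f
  }
  pkMaps(array(kt, c(H, W, 1L)), array(ve, c(H, W, 1L)), array(vp, c(H, W, 1L)))
}

#' Sample PK map predictions with uncertainty
#'
#' Draws \code{nSamples} latent vectors from the prior (one derived seed per
#' sample), decodes each into a PK map triplet, and summarises them with
#' voxelwise mean maps and voxelwise standard-deviation uncertainty maps in
#' parameter units.
#'
#' @param dce a \linkS4class{DCESeries}.
#' @param model a trained "PKModel".
#' @param nSamples number of latent draws (>= 2; default 4).
#' @param seed master seed; per-sample seeds are derived from it.
#' @param z slice index.
#' @param collapse if TRUE the latent is collapsed to the prior mean for all
#'   samples (deterministic U-Net pass; uncertainty is exactly zero).
#' @return a \linkS4class{PredictionSet}.
#' @export
predictPK <- function(dce, model, nSamples = 4L, seed = 1L, z = 1L,
                      collapse = FALSE) {
  if (nSamples < 1L) stop("nSamples must be >= 1")
  if (nSamples < 2L) stop("need >= 2 samples to form uncertainty maps")
  feats <- tcnForward(dce, model, z = z)
  prior <- priorEncode(feats, model)
  seeds <- vapply(seq_len(nSamples), function(s) deriveSeed(seed, s), 0L)
  samples <- lapply(seq_len(nSamples), function(s) {
    zv <- if (collapse) prior$mu else
      withSeed(seeds[s], prior$mu + prior$sigma * rnorm(length(prior$mu)))
    decodePK(feats, zv, model)
  })
  d <- dim(samples[[1]]@ktrans)
  stack <- function(get) vapply(samples, get, array(0, d))
  mstat <- function(a, f) array(apply(a, 1:3, f), d)
  kt <- stack(function(s) s@ktrans); ve <- stack(function(s) s@ve)
  vp <- stack(function(s) s@vp)
  meanM <- pkMaps(mstat(kt, mean), mstat(ve, mean), mstat(vp, mean))
  unc <- list(ktrans = mstat(kt, sd), ve = mstat(ve, sd), vp = mstat(vp, sd))
  new("PredictionSet", samples = samples, meanMaps = meanM,
      uncertaintyMaps = unc, seeds = seeds)
}

#' Stage-1-only PK maps (ablation comparator)
#'
#' Applies the per-voxel 1x1 regression head to the temporal feature maps:
#' PK maps with no spatial mixing, the "temporal-only" model of the ablation
#' comparison.
#'
#' @param dce a \linkS4class{DCESeries}.
#' @param model a trained "PKModel" (mode "tcn_only" or "full").
#' @param z slice index.
#' @return a \linkS4class{PKMaps}.
#' @export
predictTCNOnly <- function(dce, model, z = 1L) {
  feats <- tcnForward(dce, model, z = z)
  X <- .asFeatureMatrix(feats)
  Y <- .ablFwd(X$m, model$params)$Y
  .toPKMaps(Y, model$config$paramScales, X$H, X$W)
}
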