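# Training: ELBO-style loss (reconstruction + beta * KL), two-phase loop
# (stage-1 pretraining of the TCN on subsampled voxel curves, then joint
# end-to-end training of the full two-stage model), deterministic seeding,
# checkpointing, and manifest-driven split handling.

#' Training configuration
#'
#' @param mode "full" (TCN + probabilistic U-Net) or "tcn_only" (stage-1
#'   ablation model). In full mode the TCN is pretrained for
#'   \code{stage1Epochs} epochs and the whole model is then trained jointly
#'   for \code{epochs} epochs; tcn_only trains stage 1 for
#'   \code{stage1Epochs + epochs} epochs so both modes receive a comparable
#'   budget.
#' @param epochs joint-phase epochs (>= 1).
#' @param stage1Epochs stage-1 pretraining epochs.
#' @param batchVoxels voxel curves sampled per subject per stage-1 step.
#' @param lr Adam learning rate for the joint phase.
#' @param stage1Lr Adam learning rate for stage-1 (per-voxel regression
#'   tolerates a larger step).
#' @param beta KL weight in the ELBO; reached after a linear warm-up over
#'   \code{klWarmupFrac} of the joint epochs.
#' @param klWarmupFrac fraction of joint epochs over which beta ramps up.
#' @param reconLoss "mse" (L2 on normalised maps) or "l1".
#' @param seed training seed (weights, shuffling, subsampling, latent draws).
#' @param patience early-stopping patience on the validation loss (epochs);
#'   Inf disables early stopping.
#' @param freezeStage1 if TRUE the TCN weights are frozen during the joint
#'   phase.
#' @param augment if TRUE (default), second-phase steps apply a random
#'   dihedral symmetry (rotations/flips) to each slice — the spatial stage
#'   sees few slices, and augmentation is its main overfitting control.
#' @return list of class "TrainConfig".
#' @export
trainConfig <- function(mode = c("full", "tcn_only"), epochs = 30L,
                        stage1Epochs = 40L, batchVoxels = 256L, lr = 1e-3,
                        stage1Lr = 3e-3, beta = 1, klWarmupFrac = 0.2,
                        reconLoss = c("mse", "l1"), seed = 1L, patience = Inf,
                        freezeStage1 = FALSE, augment = TRUE) {
  mode <- match.arg(mode); reconLoss <- match.arg(reconLoss)
  if (beta < 0) stop("beta must be >= 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(mode = mode, epochs = as.integer(epochs),
                 stage1Epochs = as.integer(stage1Epochs),
                 batchVoxels = as.integer(batchVoxels), lr = lr,
                 stage1Lr = stage1Lr, beta = beta,
                 klWarmupFrac = klWarmupFrac, reconLoss = reconLoss,
                 seed = as.integer(seed), patience = patience,
                 freezeStage1 = freezeStage1, augment = augment),
            class = "TrainConfig")
}

#' Training loss: reconstruction plus weighted KL
#'
#' \code{total = recon + beta * KL(posterior || prior)} with the
#' reconstruction term a mean squared (or mean absolute) error between
#' predicted and target maps. With \code{scales} given, maps are divided by
#' the per-parameter scales first (the form used during training).
#'
#' @param pred,gt \linkS4class{PKMaps} or numeric arrays/matrices of equal
#'   shape.
#' @param prior,posterior "LatentDistribution" objects (NULL for a pure
#'   reconstruction loss, e.g. stage-1 training).
#' @param beta KL weight (>= 0).
#' @param scales optional named per-parameter scales (ktrans, ve, vp).
#' @param reconLoss "mse" or "l1".
#' @return list: \code{total}, \code{recon}, \code{kl}.
#' @export
pkLoss <- function(pred, gt, prior = NULL, posterior = NULL, beta = 1,
                   scales = NULL, reconLoss = "mse") {
  asMat <- function(x) {
    if (is(x, "PKMaps")) {
      m <- cbind(as.vector(x@ktrans), as.vector(x@ve), as.vector(x@vp))
      if (!is.null(scales)) m <- sweep(m, 2L, scales[c("ktrans", "ve", "vp")], "/")
      m
    } else as.matrix(x)
  }
  a <- asMat(pred); b <- asMat(gt)
  if (!identical(dim(a), dim(b))) stop("pred and gt shapes do not match")
  recon <- if (reconLoss == "mse") mean((a - b)^2) else mean(abs(a - b))
  kl <- if (is.null(prior) || is.null(posterior)) 0
        else klDivergence(posterior, prior)
  list(total = recon + beta * kl, recon = recon, kl = kl)
}

.zeroLike <- function(params) .nnMap(params, function(x) x * 0)

# row-index permutations of an H x W slice under the 8 dihedral symmetries
.dihedralIndex <- function(H, W, k) {
  A <- matrix(seq_len(H * W), H, W)
  if (k >= 4L) { A <- A[H:1, , drop = FALSE]; k <- k - 4L }
  for (r in seq_len(k)) A <- t(A[nrow(A):1, , drop = FALSE])
  as.vector(A)
}

# one stage-1 step on a voxel subsample; returns grads (tcn + abl) and loss
.stage1Step <- function(X, Gn, idx, params, cfg) {
  Xs <- X[idx, , drop = FALSE]; Gs <- Gn[idx, , drop = FALSE]
  V <- length(idx); Tn <- ncol(X)
  fw <- .tcnFwd(Xs, params$tcn, cfg, V, Tn)
  hd <- .denseF(fw$F, params$abl)
  Y <- .softplus(hd$Y)
  diff <- Y - Gs
  loss <- mean(diff^2)
  dY <- 2 * diff / length(diff)
  dA <- dY * .sigmoid(hd$Y)
  ab <- .denseB(dA, params$abl, hd)
  gT <- .tcnBwd(ab$dX, params$tcn, cfg, fw, V, Tn)
  list(loss = loss, gTcn = gT, gAbl = ab$g)
}

# one joint step on a full slice; returns grads for all components and loss.
# With frozen stage-1 the caller passes precomputed features via Ffix and the
# TCN is neither run nor differentiated (the big saving of the frozen recipe).
.jointStep <- function(X, Gn, H, W, params, cfg, betaEff, eps, Ffix = NULL) {
  V <- nrow(Gn); Tn <- cfg$nFrames
  if (is.null(Ffix)) {
    fwT <- .tcnFwd(X, params$tcn, cfg, V, Tn)
    F <- fwT$F
  } else F <- Ffix
  ab <- .denseF(F, params$abl)            # stage-1 logits, refined by the U-Net
  fq <- .encFwd(cbind(F, Gn), params$posterior, H, W, cfg)
  fp <- .encFwd(F, params$prior, H, W, cfg)
  z <- fq$mu + fq$sigma * eps
  fd <- .decFwd(F, z, params$decoder, H, W, base = ab$Y)
  diff <- fd$Y - Gn
  recon <- mean(diff^2)
  q <- list(mu = fq$mu, sigma = fq$sigma); p <- list(mu = fp$mu, sigma = fp$sigma)
  kl <- klDivergence(q, p)
  dY <- 2 * diff / length(diff)
  db <- .decBwd(dY, params$decoder, fd)
  klg <- .klGrads(q, p)
  dmuq <- db$dz + betaEff * klg$dmuq
  dsq <- db$dz * eps + betaEff * klg$dsq
  qb <- .encBwd(dmuq, dsq, params$posterior, fq, cfg)
  pb <- .encBwd(betaEff * klg$dmup, betaEff * klg$dsp, params$prior, fp, cfg)
  abB <- .denseB(db$dBase, params$abl, ab)
  gT <- NULL
  if (is.null(Ffix)) {
    dF <- db$dF + pb$dX + qb$dX[, 1:3, drop = FALSE] + abB$dX
    gT <- .tcnBwd(dF, params$tcn, cfg, fwT, V, Tn)
  }
  list(recon = recon, kl = kl, total = recon + betaEff * kl,
       gTcn = gT, gAbl = abB$g, gPrior = pb$g, gPost = qb$g, gDec = db$g)
}

.prepSubject <- function(subj, cfg, target = NULL) {
  d <- dim(subj$dce@data)
  gt <- if (is.null(target)) subj$gt else target
  list(X = normalizeDCE(subj$dce), Gn = .normalizeMaps(gt, cfg),
       H = d[1], W = d[2])
}

#' Train the two-stage model on a synthetic cohort
#'
#' Honours the cohort manifest's train/valid splits, logs per-epoch losses,
#' retains the weights with the best validation loss, and is deterministic
#' for a fixed configuration and seed (single-threaded). Aborts with
#' diagnostics if the loss turns non-finite.
#'
#' @param cohort a cohort from \code{\link{generateCohort}} (subjects must
#'   be rendered).
#' @param config a \code{\link{trainConfig}}.
#' @param mconfig a \code{\link{modelConfig}}.
#' @param targets optional named list (by subject id) of \linkS4class{PKMaps}
#'   to use as the training target instead of the simulator ground truth
#'   (e.g. conventional-fit maps, mirroring training toward
#'   commercial-software fits).
#' @return list of class "PKCheckpoint": \code{model} ("PKModel"),
#'   \code{trainConfig}, \code{log} (data.frame epoch/phase/train/valid),
#'   \code{bestEpoch}, \code{hash}.
#' @export
train <- function(cohort, config = trainConfig(), mconfig = modelConfig(),
                  targets = NULL) {
  man <- cohort$manifest
  trIdx <- which(man$split == "train"); vaIdx <- which(man$split == "valid")
  if (!length(trIdx)) stop("manifest has no train split")
  if (!length(vaIdx)) stop("manifest has no valid split")
  getTarget <- function(i) if (is.null(targets)) NULL else targets[[man$id[i]]]
  prep <- lapply(seq_len(nrow(man)), function(i)
    .prepSubject(cohort$subjects[[i]], mconfig, getTarget(i)))
  model <- initModel(mconfig, seed = deriveSeed(config$seed, 11L))
  params <- model$params
  adam <- .adamInit(params)
  log <- data.frame()
  best <- list(loss = Inf, params = params, epoch = 0L)
  sinceBest <- 0L
  # fixed voxel subsets for cheap stage-1 validation
  vaSub <- lapply(vaIdx, function(i) withSeed(deriveSeed(config$seed, 1000L + i),
    sample.int(nrow(prep[[i]]$X), min(512L, nrow(prep[[i]]$X)))))

  s1Epochs <- config$stage1Epochs +
    if (config$mode == "tcn_only") config$epochs else 0L
  epochCounter <- 0L
  # step decay: full rate for the first 60% of a phase, then 0.3x, then 0.1x
  lrDecay <- function(e, total) if (e <= 0.6 * total) 1 else if (e <= 0.85 * total) 0.3 else 0.1
  runEpoch <- function(phase, e) {
    epochCounter <<- epochCounter + 1L
    eseed <- deriveSeed(config$seed, 2000L + epochCounter)
    ord <- withSeed(eseed, sample(trIdx))
    trLoss <- 0
    for (j in seq_along(ord)) {
      i <- ord[j]; pr <- prep[[i]]
      sseed <- deriveSeed(eseed, j)
      if (phase == "stage1") {
        idx <- withSeed(sseed, sample.int(nrow(pr$X), min(config$batchVoxels, nrow(pr$X))))
        st <- .stage1Step(pr$X, pr$Gn, idx, params, mconfig)
        g <- .zeroLike(params)
        g$tcn <- st$gTcn; g$abl <- st$gAbl
        stepLoss <- st$loss
      } else {
        betaEff <- config$beta *
          min(1, e / max(1, ceiling(config$klWarmupFrac * config$epochs)))
        draw <- withSeed(sseed, list(
          eps = rnorm(mconfig$latentDim),
          k = if (config$augment) sample(0:7, 1L) else 0L))
        k <- if (pr$H == pr$W) draw$k else (draw$k %/% 4L) * 4L  # flips only
        idx <- if (k == 0L) NULL else .dihedralIndex(pr$H, pr$W, k)
        Gn <- if (is.null(idx)) pr$Gn else pr$Gn[idx, , drop = FALSE]
        Ff <- featCache[[i]]
        if (!is.null(idx) && !is.null(Ff)) Ff <- Ff[idx, , drop = FALSE]
        X <- if (is.null(idx)) pr$X else pr$X[idx, , drop = FALSE]
        st <- .jointStep(X, Gn, pr$H, pr$W, params, mconfig, betaEff,
                         draw$eps, Ffix = Ff)
        g <- .zeroLike(params)
        g$tcn <- if (config$freezeStage1) .zeroLike(params$tcn) else st$gTcn
        if (!config$freezeStage1) g$abl <- st$gAbl
        g$prior <- st$gPrior; g$posterior <- st$gPost; g$decoder <- st$gDec
        if (is.null(st$gTcn)) st$gTcn <- .zeroLike(params$tcn)
        stepLoss <- st$total
      }
      if (!is.finite(stepLoss))
        stop(sprintf("non-finite loss at %s epoch %d, subject %s", phase, e, man$id[i]))
      trLoss <- trLoss + stepLoss
      baseLr <- if (phase == "stage1") config$stage1Lr else config$lr
      total <- if (phase == "stage1") s1Epochs else config$epochs
      up <- .adamStep(params, g, adam, lr = baseLr * lrDecay(e, total))
      params <<- up$params; adam <<- up$state
    }
    trLoss / length(ord)
  }
  validLoss <- function(phase) {
    tot <- 0
    for (k in seq_along(vaIdx)) {
      i <- vaIdx[k]; pr <- prep[[i]]
      if (phase == "stage1") {
        idx <- vaSub[[k]]
        fw <- .tcnFwd(pr$X[idx, , drop = FALSE], params$tcn, mconfig,
                      length(idx), ncol(pr$X))
        Y <- .softplus(.denseF(fw$F, params$abl)$Y)
        tot <- tot + mean((Y - pr$Gn[idx, , drop = FALSE])^2)
      } else {
        F <- featCache[[i]] %||%
          .tcnFwd(pr$X, params$tcn, mconfig, nrow(pr$X), ncol(pr$X))$F
        base <- .denseF(F, params$abl)$Y
        fp <- .encFwd(F, params$prior, pr$H, pr$W, mconfig)
        fd <- .decFwd(F, fp$mu, params$decoder, pr$H, pr$W, base = base)
        tot <- tot + mean((fd$Y - pr$Gn)^2)
      }
    }
    tot / length(vaIdx)
  }

  for (e in seq_len(s1Epochs)) {
    tr <- runEpoch("stage1", e)
    va <- validLoss("stage1")
    log <- rbind(log, data.frame(epoch = epochCounter, phase = "stage1",
                                 trainLoss = tr, validLoss = va))
    if (config$mode == "tcn_only") {
      if (va < best$loss) { best <- list(loss = va, params = params, epoch = epochCounter); sinceBest <- 0L }
      else sinceBest <- sinceBest + 1L
      if (sinceBest > config$patience) break
    }
  }
  featCache <- vector("list", nrow(man))
  if (config$mode == "full") {
    if (config$freezeStage1) {
      # frozen TCN: temporal features are fixed, compute once per subject
      for (i in c(trIdx, vaIdx)) {
        pr <- prep[[i]]
        featCache[[i]] <- .tcnFwd(pr$X, params$tcn, mconfig, nrow(pr$X),
                                  ncol(pr$X))$F
      }
    }
    best <- list(loss = Inf, params = params, epoch = epochCounter)
    sinceBest <- 0L
    for (e in seq_len(config$epochs)) {
      tr <- runEpoch("joint", e)
      va <- validLoss("joint")
      log <- rbind(log, data.frame(epoch = epochCounter, phase = "joint",
                                   trainLoss = tr, validLoss = va))
      if (va < best$loss) { best <- list(loss = va, params = params, epoch = epochCounter); sinceBest <- 0L }
      else sinceBest <- sinceBest + 1L
      if (sinceBest > config$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, trainConfig = config, log = log,
                 bestEpoch = best$epoch, hash = .cfgHash(list(mconfig, config))),
            class = "PKCheckpoint")
}

# cheap deterministic checksum of a configuration (no external digest dep)
.cfgHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  bytes <- bytes[-seq_len(14L)]  # drop header (R version stamp)
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97L + 1L)) %% 4294967291)
}

#' Save / load a training checkpoint
#'
#' The checkpoint embeds a configuration hash; loading verifies it and a
#' round-trip reproduces identical predictions.
#'
#' @param ckpt a "PKCheckpoint" from \code{\link{train}}.
#' @param path file path (.rds).
#' @return \code{loadCheckpoint} returns the checkpoint.
#' @export
saveCheckpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "PKCheckpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "PKCheckpoint")) stop("not a PKSynth checkpoint")
  if (!identical(ckpt$hash, .cfgHash(list(ckpt$model$config, ckpt$trainConfig))))
    stop("checkpoint configuration hash mismatch")
  ckpt
}
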