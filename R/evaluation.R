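# Validation battery: map similarity (SSIM, NRMSE), repeated-measurement
# agreement (ICC(A,1), Bland-Altman limits of agreement), and diagnostic
# performance (AUROC with DeLong CI and paired DeLong tests).

.gaussianWindow <- function(winSize, sigma) {
  half <- (winSize - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'valid' 2D correlation with a window: output is (H-win+1) x (W-win+1)
.filterValid <- function(X, w) {
  win <- nrow(w)
  Ho <- nrow(X) - win + 1L; Wo <- ncol(X) - win + 1L
  acc <- matrix(0, Ho, Wo)
  for (i in seq_len(win)) for (j in seq_len(win)) {
    if (w[i, j] != 0)
      acc <- acc + w[i, j] * X[i:(i + Ho - 1L), j:(j + Wo - 1L)]
  }
  acc
}

.ssimSlice <- function(a, b, dataRange, winSize, sigma) {
  w <- .gaussianWindow(winSize, sigma)
  mux <- .filterValid(a, w); muy <- .filterValid(b, w)
  sxx <- .filterValid(a * a, w) - mux^2
  syy <- .filterValid(b * b, w) - muy^2
  sxy <- .filterValid(a * b, w) - mux * muy
  C1 <- (0.01 * dataRange)^2; C2 <- (0.03 * dataRange)^2
  ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (sxx + syy + C2))
}

#' Structural similarity between two parameter maps
#'
#' Standard SSIM (luminance/contrast/structure product) with a Gaussian
#' window, computed slicewise in 2D on the window-valid interior and averaged
#' over the mask. Defaults follow the common reference setting: 11-wide
#' window, sigma 1.5, C1 = (0.01 R)^2, C2 = (0.03 R)^2.
#'
#' @param a test map (3D array or matrix).
#' @param b reference map, same shape.
#' @param mask optional logical mask; NULL averages over the whole interior.
#' @param dataRange dynamic range R of the reference data (> 0).
#' @param winSize odd window width.
#' @param sigma Gaussian window sigma.
#' @return scalar mean SSIM (<= 1).
#' @export
ssimMap <- function(a, b, mask = NULL, dataRange, winSize = 11L, sigma = 1.5) {
  if (dataRange <= 0) stop("dataRange must be > 0")
  if (is.matrix(a)) { a <- array(a, c(dim(a), 1L)); b <- array(b, c(dim(b), 1L)) }
  if (!identical(dim(a), dim(b))) stop("maps must be aligned")
  if (!is.null(mask) && is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  pad <- (winSize - 1L) %/% 2L
  d <- dim(a)
  if (d[1] < winSize || d[2] < winSize) stop("maps smaller than the window")
  vals <- c(); wts <- c()
  core1 <- (pad + 1L):(d[1] - pad); core2 <- (pad + 1L):(d[2] - pad)
  for (z in seq_len(d[3])) {
    s <- .ssimSlice(a[, , z], b[, , z], dataRange, winSize, sigma)
    m <- if (is.null(mask)) matrix(TRUE, nrow(s), ncol(s))
         else mask[core1, core2, z]
    if (any(m)) { vals <- c(vals, mean(s[m])); wts <- c(wts, sum(m)) }
  }
  if (!length(vals)) stop("mask is empty on the window-valid interior")
  sum(vals * wts) / sum(wts)
}

#' Normalised root-mean-square error (percent)
#'
#' RMSE over the mask divided by the reference range over the mask, times
#' 100.
#'
#' @param a test map.
#' @param b reference map.
#' @param mask logical mask (NULL = everywhere).
#' @return scalar percent NRMSE.
#' @export
nrmse <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("maps must be aligned")
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  if (!any(mask)) stop("mask is empty")
  av <- a[mask]; bv <- b[mask]
  rng <- max(bv) - min(bv)
  if (rng <= 0) stop("reference range over the mask is zero")
  100 * sqrt(mean((av - bv)^2)) / rng
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the ANOVA mean squares, with the F-based 95\% confidence interval
#' (McGraw & Wong convention, as implemented in standard ICC software).
#'
#' @param mat numeric matrix, subjects in rows (>= 3), raters/measurements in
#'   columns (>= 2), no missing cells.
#' @param alpha 1 - confidence level (default 0.05).
#' @return list: \code{icc}, \code{lower}, \code{upper}, \code{msr},
#'   \code{msc}, \code{mse}, \code{undefined} (TRUE when the between-subject
#'   variance is zero and the coefficient is undefined).
#' @export
icc <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need >= 2 raters")
  if (n < 3L) stop("need >= 3 subjects")
  if (any(!is.finite(mat))) stop("missing cells are not supported")
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ssb <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssb - ssc
  msr <- ssb / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300 || (msr < 1e-300 && mse < 1e-300 && msc < 1e-300))
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                msr = msr, msc = msc, mse = mse, undefined = TRUE))
  est <- (msr - mse) / denom
  if (mse < 1e-300 && msc < 1e-300) {  # perfect agreement: CI collapses
    return(list(icc = est, lower = est, upper = est, msr = msr, msc = msc,
                mse = mse, undefined = FALSE))
  }
  aa <- (k * est) / (n * (1 - est))
  bb <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - FL * mse) /
    (FL * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (FU * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * FU * msr)
  list(icc = est, lower = lower, upper = upper, msr = msr, msc = msc,
       mse = mse, undefined = FALSE)
}

#' Bland-Altman agreement between two measurement series
#'
#' Mean difference and limits of agreement, defined as the mean difference
#' +/- 1.96 times the standard deviation of the differences.
#'
#' @param x,y paired measurements (equal length >= 2).
#' @return list: \code{meanDiff}, \code{loaLower}, \code{loaUpper},
#'   \code{sdDiff}.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2L) stop("need n >= 2")
  d <- x - y
  md <- mean(d); s <- sd(d)
  list(meanDiff = md, loaLower = md - 1.96 * s, loaUpper = md + 1.96 * s,
       sdDiff = s)
}

.asBinary <- function(labels, positive = NULL) {
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- u[2L]
  factor(as.character(labels), levels = c(setdiff(u, positive), positive))
}

#' AUROC with DeLong confidence interval
#'
#' Area under the ROC curve for a continuous score against binary labels,
#' with ties counted 1/2 (Mann-Whitney convention), plus the DeLong 95\%
#' confidence interval and variance. Computed with the pROC package with a
#' fixed direction (higher score predicts the positive class), so values
#' below 0.5 are reported as such.
#'
#' @param scores numeric vector.
#' @param labels two-class vector.
#' @param positive label treated as positive (default: last alphabetically).
#' @return list: \code{auc}, \code{ciLower}, \code{ciUpper}, \code{var},
#'   \code{n}.
#' @export
rocAUC <- function(scores, labels, positive = NULL) {
  y <- .asBinary(labels, positive)
  r <- pROC::roc(response = y, predictor = scores, levels = levels(y),
                 direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), ciLower = ci[1], ciUpper = ci[3],
       var = as.numeric(v), n = length(scores))
}

#' Paired DeLong test between two AUROCs
#'
#' DeLong covariance-based z-test on the difference between the AUROCs of
#' two scores measured on the same subjects; two-sided p. Identical scores
#' give difference 0 and p = 1 by convention (the test statistic is
#' degenerate there).
#'
#' @param scoresA,scoresB numeric score vectors on the same subjects.
#' @param labels two-class vector.
#' @param positive label treated as positive.
#' @return list: \code{aucA}, \code{aucB}, \code{diff}, \code{z}, \code{p}.
#' @export
delongPairedTest <- function(scoresA, scoresB, labels, positive = NULL) {
  if (length(scoresA) != length(scoresB)) stop("scores must be paired")
  y <- .asBinary(labels, positive)
  rA <- pROC::roc(response = y, predictor = scoresA, levels = levels(y),
                  direction = "<", quiet = TRUE)
  rB <- pROC::roc(response = y, predictor = scoresB, levels = levels(y),
                  direction = "<", quiet = TRUE)
  aucA <- as.numeric(pROC::auc(rA)); aucB <- as.numeric(pROC::auc(rB))
  if (isTRUE(all.equal(scoresA, scoresB)))
    return(list(aucA = aucA, aucB = aucB, diff = 0, z = 0, p = 1))
  # rank-identical scores give a degenerate (zero-variance) difference; report
  # no evidence of a difference rather than failing
  tst <- tryCatch(
    suppressWarnings(pROC::roc.test(rA, rB, method = "delong", paired = TRUE)),
    error = function(e) NULL)
  z <- if (is.null(tst)) NaN else as.numeric(tst$statistic)
  p <- if (is.null(tst)) NaN else as.numeric(tst$p.value)
  if (!is.finite(z)) { z <- 0; p <- 1 }
  list(aucA = aucA, aucB = aucB, diff = aucA - aucB, z = z, p = p)
}

#' Per-subject PK summary within a region of interest
#'
#' Arithmetic mean of each parameter map within the (non-empty) mask — the
#' per-patient summary used for the diagnostic tasks.
#'
#' @param maps a \linkS4class{PKMaps}.
#' @param mask logical 3D array (e.g. the enhancing-tumour ROI).
#' @return named numeric (ktrans, ve, vp).
#' @export
subjectScore <- function(maps, mask) {
  if (!any(mask)) stop("empty mask")
  c(ktrans = mean(maps@ktrans[mask]), ve = mean(maps@ve[mask]),
    vp = mean(maps@vp[mask]))
}

.robustMax <- function(x, p = 0.995) as.numeric(quantile(x, p))

#' Assemble the full reliability and diagnostic report for a cohort
#'
#' For the chosen subset (default: the test split) this computes, per PK
#' parameter: SSIM and NRMSE of the synthetic mean maps (and optionally the
#' stage-1-only ablation maps) against the ground-truth maps over the brain
#' and over the enhancing tumour; ICC(A,1) of enhancing-ROI means across the
#' two conventional AIF raters and across the prediction samples;
#' Bland-Altman agreement between two repeated measurements of each pathway;
#' and AUROC (with DeLong CI) of the ROI means for the WHO-grade and IDH
#' tasks for both pathways, with paired DeLong comparisons. The SSIM data
#' range is the robust (99.5th percentile) ground-truth maximum per
#' parameter over the evaluated subjects.
#'
#' @param cohort a cohort from \code{\link{generateCohort}}.
#' @param conventional named list (subject id) of lists of
#'   \linkS4class{PKMaps}, one per AIF rater (>= 2 raters).
#' @param predictions named list (subject id) of
#'   \linkS4class{PredictionSet}s.
#' @param ablation optional named list (subject id) of \linkS4class{PKMaps}
#'   from the stage-1-only model.
#' @param subset manifest split to evaluate ("test") or "all".
#' @return a \linkS4class{ReliabilityReport}.
#' @export
evaluateCohort <- function(cohort, conventional, predictions, ablation = NULL,
                           subset = "test") {
  man <- cohort$manifest
  keep <- if (identical(subset, "all")) seq_len(nrow(man))
          else which(man$split == subset)
  ids <- man$id[keep]
  missing <- setdiff(ids, intersect(names(conventional), names(predictions)))
  if (length(missing))
    stop("missing pathway outputs for: ", paste(missing, collapse = ", "))
  excluded <- character()
  rows <- list()
  for (id in ids) {
    i <- match(id, man$id)
    if (!any(cohort$subjects[[i]]$masks$enhancing_tumor)) {
      excluded <- c(excluded, id); next
    }
    rows[[id]] <- i
  }
  idx <- unlist(rows)
  subj <- cohort$subjects[idx]
  params <- c("ktrans", "ve", "vp")
  getMap <- function(maps, p) slot(maps, p)

  # ---- similarity -----------------------------------------------------------
  ranges <- vapply(params, function(p)
    .robustMax(unlist(lapply(subj, function(s) getMap(s$gt, p)[s$masks$brain]))), 0)
  simRows <- list()
  pathways <- c(synthetic = TRUE)
  for (p in params) {
    for (pw in c("synthetic", if (!is.null(ablation)) "tcn_only")) {
      sv <- tv <- nv <- ntv <- numeric(0)
      for (s in subj) {
        pred <- if (pw == "synthetic") meanMaps(predictions[[s$id]])
                else ablation[[s$id]]
        gt <- s$gt
        sv <- c(sv, ssimMap(getMap(pred, p), getMap(gt, p), s$masks$brain,
                            dataRange = ranges[p]))
        tv <- c(tv, ssimMap(getMap(pred, p), getMap(gt, p),
                            s$masks$enhancing_tumor, dataRange = ranges[p]))
        nv <- c(nv, nrmse(getMap(pred, p), getMap(gt, p), s$masks$brain))
        ntv <- c(ntv, nrmse(getMap(pred, p), getMap(gt, p),
                            s$masks$enhancing_tumor))
      }
      simRows[[paste(p, pw)]] <- data.frame(
        parameter = p, pathway = pw,
        ssim_total = mean(sv), ssim_tumor = mean(tv),
        nrmse_total = mean(nv), nrmse_tumor = mean(ntv))
    }
  }
  similarity <- do.call(rbind, c(simRows, list(make.row.names = FALSE)))

  # ---- ROI score matrices ---------------------------------------------------
  nRater <- length(conventional[[subj[[1]]$id]])
  nSamp <- length(sampleMaps(predictions[[subj[[1]]$id]]))
  convScores <- lapply(params, function(p)
    t(vapply(subj, function(s) vapply(seq_len(nRater), function(r)
      subjectScore(conventional[[s$id]][[r]], s$masks$enhancing_tumor)[[p]], 0),
      numeric(nRater))))
  synScores <- lapply(params, function(p)
    t(vapply(subj, function(s) vapply(seq_len(nSamp), function(k)
      subjectScore(sampleMaps(predictions[[s$id]])[[k]], s$masks$enhancing_tumor)[[p]], 0),
      numeric(nSamp))))
  names(convScores) <- names(synScores) <- params

  iccRows <- list(); baRows <- list()
  for (p in params) {
    ic <- icc(convScores[[p]]); is_ <- icc(synScores[[p]])
    iccRows[[p]] <- data.frame(
      parameter = p,
      pathway = c("conventional", "synthetic"),
      icc = c(ic$icc, is_$icc), lower = c(ic$lower, is_$lower),
      upper = c(ic$upper, is_$upper),
      undefined = c(ic$undefined, is_$undefined))
    bc <- blandAltman(convScores[[p]][, 1], convScores[[p]][, 2])
    bs <- blandAltman(synScores[[p]][, 1], synScores[[p]][, 2])
    baRows[[p]] <- data.frame(
      parameter = p, pathway = c("conventional", "synthetic"),
      meanDiff = c(bc$meanDiff, bs$meanDiff),
      loaLower = c(bc$loaLower, bs$loaLower),
      loaUpper = c(bc$loaUpper, bs$loaUpper))
  }
  iccTab <- do.call(rbind, c(iccRows, list(make.row.names = FALSE)))
  baTab <- do.call(rbind, c(baRows, list(make.row.names = FALSE)))

  # ---- diagnostic AUROCs ----------------------------------------------------
  labs <- list(grade = man$label_grade[idx], idh = man$label_idh[idx])
  positive <- c(grade = "high", idh = "wildtype")
  synMean <- lapply(params, function(p)
    vapply(subj, function(s)
      subjectScore(meanMaps(predictions[[s$id]]), s$masks$enhancing_tumor)[[p]], 0))
  convMean <- lapply(params, function(p) rowMeans(convScores[[p]][, 1, drop = FALSE]))
  names(synMean) <- names(convMean) <- params
  aucRows <- list(); pairRows <- list()
  for (task in names(labs)) {
    for (p in params) {
      ra <- rocAUC(synMean[[p]], labs[[task]], positive = positive[[task]])
      rb <- rocAUC(convMean[[p]], labs[[task]], positive = positive[[task]])
      aucRows[[paste(task, p)]] <- data.frame(
        task = task, parameter = p, pathway = c("synthetic", "conventional"),
        auc = c(ra$auc, rb$auc), ciLower = c(ra$ciLower, rb$ciLower),
        ciUpper = c(ra$ciUpper, rb$ciUpper))
      dt <- delongPairedTest(synMean[[p]], convMean[[p]], labs[[task]],
                             positive = positive[[task]])
      pairRows[[paste(task, p)]] <- data.frame(
        task = task, parameter = p, aucSynthetic = dt$aucA,
        aucConventional = dt$aucB, diff = dt$diff, z = dt$z, p = dt$p)
    }
  }
  new("ReliabilityReport",
      similarity = similarity, icc = iccTab, blandAltman = baTab,
      auroc = do.call(rbind, c(aucRows, list(make.row.names = FALSE))),
      pairedTests = do.call(rbind, c(pairRows, list(make.row.names = FALSE))),
      info = list(subset = subset, n = length(idx), excluded = excluded,
                  nRaters = nRater, nSamples = nSamp,
                  dataRanges = as.list(ranges)))
}
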