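# Digital reference objects: glioma-like PK phantoms, DCE signal rendering
# with Rician noise / optional motion, and class-conditional cohorts with
# IDH / WHO-grade labels.

#' Default per-class PK distributions of the phantom
#'
#' Log-normal location (geometric mean) and log-scale per parameter for each
#' tissue class. Centres are ordered (ktrans, ve, vp); the tumour rim centre
#' describes a low-grade tumour — grade and IDH effects multiply it (see
#' \code{\link{cohortEffect}}). Vessel voxels are not drawn from a
#' distribution: they carry (ktrans = 0, ve = 0, vp = 1 - hct) so that their
#' concentration is the blood-scaled AIF.
#'
#' @param hct haematocrit (sets the vessel plasma fraction).
#' @return named list of class parameter lists.
#' @export
phantomClasses <- function(hct = 0.42) {
  list(
    normal       = list(center = c(ktrans = 0.010, ve = 0.05, vp = 0.010),
                        sdlog = c(ktrans = 0.2, ve = 0.2, vp = 0.2)),
    tumor_core   = list(center = c(ktrans = 0.003, ve = 0.45, vp = 0.004),
                        sdlog = c(ktrans = 0.2, ve = 0.2, vp = 0.2)),
    tumor_rim    = list(center = c(ktrans = 0.050, ve = 0.25, vp = 0.025),
                        sdlog = c(ktrans = 0.2, ve = 0.2, vp = 0.2)),
    infiltration = list(center = c(ktrans = 0.020, ve = 0.15, vp = 0.015),
                        sdlog = c(ktrans = 0.2, ve = 0.2, vp = 0.2)),
    vessel       = list(vp = 1 - hct)
  )
}

#' Specify a digital phantom
#'
#' Geometry and statistics of one synthetic subject: an elliptical "brain",
#' a three-layer ellipsoidal tumour (necrotic core, enhancing rim,
#' non-enhancing infiltrative halo), a small vessel patch, and per-class
#' log-normal PK distributions.
#'
#' @param shape integer (x, y, z) voxel counts, each >= (16, 16, 1).
#' @param classes per-class distributions, see \code{\link{phantomClasses}}.
#' @param tumorCenter tumour centre in voxels (default: slightly off-centre).
#' @param tumorRadii in-plane tumour radii in voxels (0 = no tumour).
#' @param coreFrac fraction of the tumour radius occupied by the core.
#' @param infiltrationFrac outer radius of the infiltrative halo as a
#'   multiple of the tumour radius.
#' @param noiseSd Rician noise sigma at signal scale (arbitrary units of the
#'   rendered signal; the default acquisition has baseline ~ 19).
#' @param motion "none" or "shift" (seeded per-frame +-1 voxel in-plane
#'   shifts).
#' @param seed integer seed driving all draws for this phantom.
#' @return validated list of class "PhantomSpec".
#' @export
phantomSpec <- function(shape = c(32L, 32L, 1L), classes = phantomClasses(),
                        tumorCenter = NULL, tumorRadii = c(7, 6),
                        coreFrac = 0.5, infiltrationFrac = 1.35,
                        noiseSd = 1.0, motion = c("none", "shift"),
                        seed = 1L) {
  motion <- match.arg(motion)
  shape <- as.integer(shape)
  if (length(shape) != 3L || shape[1] < 16L || shape[2] < 16L || shape[3] < 1L)
    stop("shape must be (x, y, z) with x, y >= 16 and z >= 1")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (is.null(tumorCenter)) tumorCenter <- c(shape[1] * 0.58, shape[2] * 0.55, (shape[3] + 1) / 2)
  if (any(tumorRadii * infiltrationFrac > pmin(shape[1], shape[2]) / 2))
    stop("tumour larger than the volume")
  structure(list(shape = shape, classes = classes, tumorCenter = tumorCenter,
                 tumorRadii = tumorRadii, coreFrac = coreFrac,
                 infiltrationFrac = infiltrationFrac, noiseSd = noiseSd,
                 motion = motion, seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Draw truncated log-normal PK triplets for n voxels of one class.
.drawClass <- function(n, cls) {
  kt <- exp(rnorm(n, log(cls$center[["ktrans"]]), cls$sdlog[["ktrans"]]))
  ve <- exp(rnorm(n, log(cls$center[["ve"]]), cls$sdlog[["ve"]]))
  vp <- exp(rnorm(n, log(cls$center[["vp"]]), cls$sdlog[["vp"]]))
  kt <- pmin(kt, 5); ve <- pmin(ve, 0.98); vp <- pmin(vp, 0.5)
  s <- ve + vp
  bad <- s > 0.99
  if (any(bad)) { ve[bad] <- ve[bad] * 0.99 / s[bad]; vp[bad] <- vp[bad] * 0.99 / s[bad] }
  list(ktrans = kt, ve = ve, vp = vp)
}

#' Build the ground-truth phantom for one spec
#'
#' Lays out the tissue classes geometrically (normalised ellipsoidal radius
#' rho: core rho <= coreFrac, rim coreFrac < rho <= 1, infiltration
#' 1 < rho <= infiltrationFrac) and draws per-voxel PK values from the class
#' distributions, truncated so the PK invariants hold voxelwise.
#' Deterministic for a fixed spec (all randomness from \code{spec$seed}).
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list: \code{gt} (\linkS4class{PKMaps}), \code{masks} (named list
#'   of logical arrays: brain, enhancing_tumor, whole_tumor, vessel),
#'   \code{classMap} (integer array coding the tissue classes).
#' @export
buildPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$shape
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  X <- array(rep(ax, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ay, each = d[1]), times = d[3]), d)
  Z <- array(rep(az, each = d[1] * d[2]), d)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  brain <- ((X - cx) / (d[1] * 0.44))^2 + ((Y - cy) / (d[2] * 0.44))^2 +
    (if (d[3] > 1L) ((Z - cz) / (d[3] * 0.48))^2 else 0) <= 1
  rz <- if (d[3] > 1L) max(spec$tumorRadii) * d[3] / max(d[1], d[2]) + 0.5 else 0.75
  rho <- if (all(spec$tumorRadii > 0)) {
    sqrt(((X - spec$tumorCenter[1]) / spec$tumorRadii[1])^2 +
         ((Y - spec$tumorCenter[2]) / spec$tumorRadii[2])^2 +
         ((Z - spec$tumorCenter[3]) / rz)^2)
  } else array(Inf, d)
  core <- brain & rho <= spec$coreFrac
  rim <- brain & rho > spec$coreFrac & rho <= 1
  infil <- brain & rho > 1 & rho <= spec$infiltrationFrac
  # small vessel patch in anterior brain, clear of the tumour
  vx <- round(d[1] * 0.25); vy <- round(d[2] * 0.22)
  vessel <- array(FALSE, d)
  vessel[vx:(vx + 1), vy:(vy + 1), ] <- TRUE
  vessel <- vessel & brain & rho > spec$infiltrationFrac
  normal <- brain & !core & !rim & !infil & !vessel
  classMap <- array(0L, d)
  classMap[normal] <- 1L; classMap[core] <- 2L; classMap[rim] <- 3L
  classMap[infil] <- 4L; classMap[vessel] <- 5L
  kt <- array(0, d); ve <- array(0, d); vp <- array(0, d)
  withSeed(spec$seed, {
    for (cl in list(c(1L, "normal"), c(2L, "tumor_core"), c(3L, "tumor_rim"),
                    c(4L, "infiltration"))) {
      idx <- which(classMap == as.integer(cl[1]))
      if (length(idx)) {
        v <- .drawClass(length(idx), spec$classes[[cl[2]]])
        kt[idx] <- v$ktrans; ve[idx] <- v$ve; vp[idx] <- v$vp
      }
    }
  })
  vp[vessel] <- spec$classes$vessel$vp
  gt <- pkMaps(kt, ve, vp)
  validObject(gt)
  list(gt = gt,
       masks = list(brain = brain, enhancing_tumor = rim,
                    whole_tumor = core | rim | infil, vessel = vessel),
       classMap = classMap)
}

#' Render a phantom to a 4D DCE signal series
#'
#' Per voxel: extended Tofts forward model then SPGR signal conversion.
#' Vessel voxels carry the AIF scaled by their plasma fraction (their PK
#' triplet is (0, 0, 1 - hct)), Rician noise is applied at signal scale
#' (sqrt((S + e1)^2 + e2^2), e ~ N(0, noiseSd)), and optional seeded
#' per-frame rigid +-1 voxel shifts emulate motion.
#'
#' @param gt ground-truth \linkS4class{PKMaps}.
#' @param aif an \linkS4class{AIFCurve}.
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param noiseSd Rician sigma at signal scale (>= 0).
#' @param motion "none" or "shift".
#' @param seed seed for noise and motion.
#' @param subjectId id stored on the series.
#' @return a \linkS4class{DCESeries}.
#' @export
renderDCE <- function(gt, aif, acq = acquisitionParams(), noiseSd = 0,
                      motion = c("none", "shift"), seed = 1L,
                      subjectId = "phantom") {
  motion <- match.arg(motion)
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  d <- dim(gt@ktrans)
  ct <- toftsForwardBatch(as.vector(gt@ktrans), as.vector(gt@ve),
                          as.vector(gt@vp), aif)        # [vox x T]
  S <- concentrationToSignal(ct, acq)
  Tn <- nFrames(aif)
  arr <- array(S, c(d, Tn))
  withSeed(seed, {
    if (motion == "shift") {
      for (f in seq_len(Tn)) {
        sx <- sample(-1:1, 1L); sy <- sample(-1:1, 1L)
        if (sx != 0 || sy != 0) {
          fr <- arr[, , , f, drop = FALSE]
          sh <- array(0, c(d, 1L))
          xs <- seq_len(d[1]); ys <- seq_len(d[2])
          xs2 <- xs - sx; ys2 <- ys - sy
          okx <- xs2 >= 1 & xs2 <= d[1]; oky <- ys2 >= 1 & ys2 <= d[2]
          sh[xs[okx], ys[oky], , 1] <- fr[xs2[okx], ys2[oky], , 1]
          arr[, , , f] <- sh
        }
      }
    }
    if (noiseSd > 0) {
      e1 <- array(rnorm(length(arr), 0, noiseSd), dim(arr))
      e2 <- array(rnorm(length(arr), 0, noiseSd), dim(arr))
      arr <- sqrt((arr + e1)^2 + e2^2)
    }
  })
  dceSeries(arr, aif@grid, acq, subjectId = subjectId)
}

#' Class-conditional cohort effect specification
#'
#' Multiplicative effects applied to the tumour rim/infiltration PK centres:
#' high-grade and IDH-wildtype tumours get elevated ktrans/vp (and mildly
#' elevated ve), and every subject draws a log-normal subject-level
#' multiplier, the between-subject variability that makes the diagnostic
#' tasks non-trivial. Ratios of 1 and sd of 0 give a null cohort.
#'
#' @param gradeRatio named (ktrans, ve, vp) multiplier for high-grade.
#' @param idhRatio named multiplier for IDH-wildtype.
#' @param subjectSd named subject-level log-normal sd.
#' @return list of class "CohortEffect".
#' @export
cohortEffect <- function(gradeRatio = c(ktrans = 3.0, ve = 1.4, vp = 2.4),
                         idhRatio = c(ktrans = 2.5, ve = 1.3, vp = 2.2),
                         subjectSd = c(ktrans = 0.6, ve = 0.3, vp = 0.6)) {
  structure(list(gradeRatio = gradeRatio, idhRatio = idhRatio,
                 subjectSd = subjectSd), class = "CohortEffect")
}

.applyEffect <- function(classes, grade, idh, effect, subjMult) {
  for (cl in c("tumor_rim", "infiltration")) {
    cc <- classes[[cl]]$center
    for (p in c("ktrans", "ve", "vp")) {
      m <- subjMult[[p]]
      if (grade == "high") m <- m * effect$gradeRatio[[p]]
      if (idh == "wildtype") m <- m * effect$idhRatio[[p]]
      cc[[p]] <- cc[[p]] * m
    }
    classes[[cl]]$center <- cc
  }
  classes
}

#' Generate a synthetic cohort with IDH / WHO-grade labels
#'
#' Draws \code{nSubjects} phantoms whose tumour PK distributions depend on
#' two independent binary labels (WHO grade low/high, IDH mutant/wildtype)
#' through \code{\link{cohortEffect}}, assigns train/valid/test splits, and
#' optionally renders each subject's 4D DCE series. Label information enters
#' only through the PK distributions. Fully reproducible: one cohort seed is
#' fanned out deterministically to per-subject seeds.
#'
#' @param nSubjects number of subjects (>= 3 for a 3-way split).
#' @param pHighGrade probability of the high-grade label.
#' @param pIDHwt probability of the IDH-wildtype label.
#' @param effect a \code{\link{cohortEffect}}.
#' @param split named fractions (train, valid, test) summing to 1; the
#'   default mirrors a roughly 50/19/31 cohort split.
#' @param seed master cohort seed.
#' @param shape phantom shape.
#' @param noiseSd Rician noise sigma at signal scale.
#' @param motion "none" or "shift".
#' @param render if FALSE, only ground-truth maps and masks are produced
#'   (fast mode for statistical experiments at large n).
#' @param grid,acq temporal grid and acquisition (defaults: 60 frames at
#'   5 s, standard SPGR settings).
#' @param aifModel population AIF model name for rendering.
#' @return list: \code{subjects} (list of "SyntheticSubject": id, dce, gt,
#'   masks, label, seed), \code{manifest} (data.frame id, label_idh,
#'   label_grade, split, seed), \code{aif} (the rendering AIF).
#' @export
generateCohort <- function(nSubjects, pHighGrade = 0.5, pIDHwt = 0.5,
                           effect = cohortEffect(),
                           split = c(train = 0.50, valid = 0.19, test = 0.31),
                           seed = 1L, shape = c(32L, 32L, 1L), noiseSd = 1.0,
                           motion = "none", render = TRUE,
                           grid = timeGrid(), acq = acquisitionParams(),
                           aifModel = "parker-mixed") {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (nSubjects < 3L && length(split) == 3L) stop("need >= 3 subjects for a 3-way split")
  aif <- populationAIF(grid, model = aifModel)
  draws <- withSeed(deriveSeed(seed, 1L), list(
    grade = ifelse(runif(nSubjects) < pHighGrade, "high", "low"),
    idh = ifelse(runif(nSubjects) < pIDHwt, "wildtype", "mutant"),
    order = sample.int(nSubjects)
  ))
  nTr <- round(split[["train"]] * nSubjects)
  nVa <- round(split[["valid"]] * nSubjects)
  splitLab <- character(nSubjects)
  splitLab[draws$order[seq_len(nTr)]] <- "train"
  splitLab[draws$order[nTr + seq_len(nVa)]] <- "valid"
  splitLab[splitLab == ""] <- "test"
  subjects <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    sseed <- deriveSeed(seed, 100L + i)
    subjMult <- withSeed(deriveSeed(sseed, 1L), {
      m <- lapply(c(ktrans = "ktrans", ve = "ve", vp = "vp"),
                  function(p) exp(rnorm(1, 0, effect$subjectSd[[p]])))
      jit <- list(center = runif(2, -2, 2), radii = runif(2, 0.85, 1.15))
      c(m, list(jit = jit))
    })
    classes <- .applyEffect(phantomClasses(), draws$grade[i], draws$idh[i],
                            effect, subjMult)
    spec <- phantomSpec(
      shape = shape, classes = classes,
      tumorCenter = c(shape[1] * 0.58 + subjMult$jit$center[1],
                      shape[2] * 0.55 + subjMult$jit$center[2],
                      (shape[3] + 1) / 2),
      tumorRadii = c(shape[1] * 0.21, shape[2] * 0.19) * subjMult$jit$radii,
      noiseSd = noiseSd, motion = motion, seed = deriveSeed(sseed, 2L))
    ph <- buildPhantom(spec)
    id <- sprintf("sub-%03d", i)
    dce <- if (render)
      renderDCE(ph$gt, aif, acq, noiseSd = noiseSd, motion = motion,
                seed = deriveSeed(sseed, 3L), subjectId = id) else NULL
    subjects[[i]] <- structure(list(
      id = id, dce = dce, gt = ph$gt, masks = ph$masks,
      label = list(idh = draws$idh[i], grade = draws$grade[i]),
      seed = sseed), class = "SyntheticSubject")
  }
  manifest <- data.frame(
    id = vapply(subjects, `[[`, "", "id"),
    label_idh = draws$idh, label_grade = draws$grade,
    split = splitLab,
    seed = vapply(subjects, `[[`, 0L, "seed"),
    stringsAsFactors = FALSE)
  list(subjects = subjects, manifest = manifest, aif = aif)
}
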