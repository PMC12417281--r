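# NIfTI + JSON-sidecar I/O and report serialisation. Volumes are NIfTI-1
# with the affine carried through unchanged; the sidecar schema is versioned
# and unknown keys survive a round-trip.

.sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a DCE series as 4D NIfTI plus JSON sidecar
#'
#' The sidecar records the acquisition (\code{tr_s}, \code{flip_deg},
#' \code{r1}, \code{t10_s}, \code{s0_scale}), the temporal grid
#' (\code{dt_min}, \code{n_baseline}), \code{subject_id} and
#' \code{schema_version}; extra keys are preserved.
#'
#' @param dce a \linkS4class{DCESeries}.
#' @param path output path ending in .nii or .nii.gz.
#' @param extra named list of additional sidecar entries.
#' @return invisibly, the path.
#' @export
writeDCE <- function(dce, path, extra = list()) {
  RNifti::writeNifti(dce@data, path)
  side <- c(list(schema_version = 1L,
                 tr_s = dce@acq@trS, flip_deg = dce@acq@flipDeg,
                 r1 = dce@acq@r1, t10_s = dce@acq@t10S,
                 s0_scale = dce@acq@s0Scale,
                 dt_min = dce@grid@dt, t0_min = dce@grid@times[1],
                 n_baseline = dce@grid@nBaseline,
                 subject_id = dce@subjectId), extra)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DCE series from 4D NIfTI plus JSON sidecar
#'
#' Validates the sidecar before touching the voxel data; unknown sidecar keys
#' are kept in the \code{sidecarExtras} attribute of the returned object.
#'
#' @param path path to the .nii/.nii.gz file; the sidecar is looked up next
#'   to it.
#' @return a \linkS4class{DCESeries}.
#' @export
readDCE <- function(path) {
  sidePath <- .sidecarPath(path)
  if (!file.exists(sidePath)) stop("sidecar missing: ", sidePath)
  side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
  need <- c("tr_s", "flip_deg", "r1", "t10_s", "dt_min", "n_baseline")
  if (!all(need %in% names(side)))
    stop("sidecar invalid: needs ", paste(need, collapse = ", "))
  for (k in c("tr_s", "flip_deg", "r1", "t10_s", "dt_min"))
    if (!is.numeric(side[[k]]) || side[[k]] <= 0)
      stop("sidecar invalid: ", k, " must be > 0")
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D volume, got %dD: %s", length(dim(arr)), path))
  grid <- timeGrid(nFrames = dim(arr)[4], dt = side$dt_min,
                   nBaseline = side$n_baseline,
                   t0 = side$t0_min %||% 0)
  acq <- acquisitionParams(trS = side$tr_s, flipDeg = side$flip_deg,
                           r1 = side$r1, t10S = side$t10_s,
                           s0Scale = side$s0_scale %||% 1000)
  dce <- dceSeries(arr, grid, acq, subjectId = side$subject_id %||% "subject")
  known <- c("schema_version", "tr_s", "flip_deg", "r1", "t10_s", "s0_scale",
             "dt_min", "t0_min", "n_baseline", "subject_id")
  attr(dce, "sidecarExtras") <- side[setdiff(names(side), known)]
  dce
}

#' Write PK maps as three NIfTI volumes
#'
#' @param maps a \linkS4class{PKMaps}.
#' @param dir output directory.
#' @param prefix filename prefix (files are <prefix>_ktrans.nii.gz etc.).
#' @return invisibly, the three paths.
#' @export
writePKMaps <- function(maps, dir, prefix = "pk") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("ktrans", "ve", "vp"), ".nii.gz"))
  RNifti::writeNifti(maps@ktrans, paths[1])
  RNifti::writeNifti(maps@ve, paths[2])
  RNifti::writeNifti(maps@vp, paths[3])
  invisible(paths)
}

#' Write a synthetic cohort to disk
#'
#' Per subject: dce.nii.gz + sidecar, ground-truth maps, masks; plus the
#' cohort manifest.csv.
#'
#' @param cohort from \code{\link{generateCohort}} (rendered).
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    sd_ <- file.path(dir, s$id)
    dir.create(sd_, showWarnings = FALSE)
    if (!is.null(s$dce))
      writeDCE(s$dce, file.path(sd_, "dce.nii.gz"),
               extra = list(label_idh = s$label$idh, label_grade = s$label$grade))
    writePKMaps(s$gt, sd_, prefix = "gt")
    for (m in names(s$masks))
      RNifti::writeNifti(s$masks[[m]] + 0L, file.path(sd_, paste0("mask_", m, ".nii.gz")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

.reportToList <- function(report) {
  list(similarity = report@similarity, icc = report@icc,
       bland_altman = report@blandAltman, auroc = report@auroc,
       paired_tests = report@pairedTests, info = report@info)
}

#' Write a ReliabilityReport as JSON and TSV tables
#'
#' @param report a \linkS4class{ReliabilityReport}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.reportToList(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tabs <- list(similarity = report@similarity, icc = report@icc,
               bland_altman = report@blandAltman, auroc = report@auroc,
               paired_tests = report@pairedTests)
  for (nm in names(tabs))
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
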