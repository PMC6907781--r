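# File adapters: CSI datasets as CSV + JSON header, maps/masks as NIfTI,
# time curves and cohorts as CSV, configs as YAML, reports as JSON.

requireFields <- function(x, fields, what, file) {
  miss <- setdiff(fields, names(x))
  if (length(miss) > 0)
    stop(sprintf("validation error in %s '%s': missing %s %s", what, file,
                 if (length(miss) == 1) "field" else "fields",
                 paste(miss, collapse = ", ")))
}

#' Write / read metabolite time curves as CSV
#'
#' Columns: t_s, pyr, lac, bic.
#'
#' @param curves a [TimeCurves-class]
#' @param path CSV path
#' @return `readTimeCurves` returns a [TimeCurves-class]
#' @export
writeTimeCurves <- function(curves, path) {
  stopifnot(is(curves, "TimeCurves"))
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeCurves
#' @export
readTimeCurves <- function(path) {
  df <- utils::read.csv(path)
  requireFields(df, c("t_s", "pyr", "lac", "bic"), "time-curve CSV", path)
  new("TimeCurves", t = df$t_s, pyr = df$pyr, lac = df$lac, bic = df$bic)
}

#' Write / read a CSI dataset
#'
#' The k-space grid is stored as a plain CSV (columns kx, ky, sample,
#' re, im; 0-based indices) next to a JSON header carrying every
#' acquisition parameter, the session metadata and any embedded truth
#' reference. `stem` is the common path without extension.
#'
#' @param ds a [CsiDataset-class]
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`
#' @return `readCsi` returns a [CsiDataset-class]
#' @export
writeCsi <- function(ds, stem) {
  stopifnot(is(ds, "CsiDataset"))
  d <- dim(ds@kspace)
  idx <- expand.grid(kx = 0:(d[1] - 1), ky = 0:(d[2] - 1),
                     sample = 0:(d[3] - 1))
  df <- data.frame(idx, re = as.vector(Re(ds@kspace)),
                   im = as.vector(Im(ds@kspace)))
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  p <- ds@params
  hdr <- list(matrix_size = p@matrixSize, tr_ms = p@trMs,
              flip_deg = p@flipDeg, bw_hz = p@bwHz,
              n_samples = p@nSamples, fov_mm = p@fovMm,
              slice_mm = p@sliceMm, carrier_ppm = p@carrierPpm,
              f0_mhz = p@f0Mhz, tr_dyn_s = p@trDynS,
              animal_id = ds@animalId, timepoint = ds@timepoint,
              seed = ds@seed, noise_sd = ds@noiseSd, truth = ds@truth)
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeCsi
#' @export
readCsi <- function(stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  for (f in c(csv, js))
    if (!file.exists(f))
      stop("validation error: missing file ", f)
  hdr <- jsonlite::read_json(js, simplifyVector = TRUE)
  requireFields(hdr, c("matrix_size", "tr_ms", "flip_deg", "bw_hz",
                       "n_samples", "fov_mm", "slice_mm", "carrier_ppm",
                       "f0_mhz", "tr_dyn_s", "animal_id", "timepoint",
                       "seed", "noise_sd"), "CSI header", js)
  df <- utils::read.csv(csv)
  requireFields(df, c("kx", "ky", "sample", "re", "im"), "CSI CSV", csv)
  n <- hdr$matrix_size; ns <- hdr$n_samples
  if (nrow(df) != n * n * ns)
    stop(sprintf("validation error in CSI CSV '%s': %d rows, expected %d",
                 csv, nrow(df), n * n * ns))
  df <- df[order(df$sample, df$ky, df$kx), ]
  ks <- array(complex(real = df$re, imaginary = df$im),
              dim = c(n, n, ns))
  params <- acqParams(matrixSize = n, trMs = hdr$tr_ms,
                      flipDeg = hdr$flip_deg, bwHz = hdr$bw_hz,
                      nSamples = ns, fovMm = hdr$fov_mm,
                      sliceMm = hdr$slice_mm,
                      carrierPpm = hdr$carrier_ppm, f0Mhz = hdr$f0_mhz,
                      trDynS = hdr$tr_dyn_s)
  new("CsiDataset", kspace = ks, params = params,
      animalId = hdr$animal_id, timepoint = hdr$timepoint,
      seed = as.integer(hdr$seed), noiseSd = hdr$noise_sd,
      truth = if (is.null(hdr$truth)) list() else hdr$truth)
}

#' Save / load metabolite maps as NIfTI
#'
#' One single-slice NIfTI volume per peak (`<dir>/<name>.nii.gz`) with
#' the interpolated in-plane resolution and slice thickness in pixdim,
#' plus a JSON sidecar with the phases applied, quality flags and the
#' parameter hash.
#'
#' @param maps a [MetaboliteMapSet-class]
#' @param dir output directory (created if needed)
#' @param sliceMm slice thickness recorded in the NIfTI header
#' @return `loadMaps` returns a [MetaboliteMapSet-class]
#' @export
saveMaps <- function(maps, dir, sliceMm = 5) {
  stopifnot(is(maps, "MetaboliteMapSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in maps@peaks$name) {
    img <- RNifti::asNifti(getMap(maps, nm),
                           pixdim = c(maps@resMm, maps@resMm, sliceMm))
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  side <- list(peaks = maps@peaks, factor = maps@factor,
               res_mm = maps@resMm,
               dataset_phase_rad = as.list(maps@datasetPhase),
               n_clamped = as.list(maps@nClamped),
               n_low_signal = as.list(maps@nLowSignal),
               provenance = maps@provenance, slice_mm = sliceMm)
  jsonlite::write_json(side, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveMaps
#' @export
loadMaps <- function(dir) {
  js <- file.path(dir, "maps.json")
  if (!file.exists(js)) stop("validation error: missing file ", js)
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  requireFields(side, c("peaks", "factor", "res_mm"), "maps sidecar", js)
  pk <- as.data.frame(side$peaks)
  arrs <- lapply(pk$name, function(nm) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    if (!file.exists(f)) stop("validation error: missing file ", f)
    as.matrix(RNifti::readNifti(f))
  })
  maps <- array(unlist(arrs), dim = c(dim(arrs[[1]]), length(arrs)),
                dimnames = list(NULL, NULL, pk$name))
  new("MetaboliteMapSet", maps = maps, peaks = pk,
      factor = as.integer(side$factor), resMm = side$res_mm,
      datasetPhase = unlist(side$dataset_phase_rad),
      nClamped = unlist(side$n_clamped),
      nLowSignal = unlist(side$n_low_signal),
      provenance = as.list(side$provenance))
}

#' Save / load a binary ROI mask as NIfTI (uint8)
#'
#' @param mask logical matrix
#' @param path NIfTI path
#' @param resMm in-plane resolution (mm)
#' @param sliceMm slice thickness (mm)
#' @return `loadMask` returns a logical matrix
#' @export
saveMask <- function(mask, path, resMm = 1, sliceMm = 5) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                         datatype = "uint8",
                         pixdim = c(resMm, resMm, sliceMm))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname saveMask
#' @export
loadMask <- function(path) {
  if (!file.exists(path)) stop("validation error: missing file ", path)
  as.matrix(RNifti::readNifti(path)) != 0
}

#' Write / read a cohort table as CSV
#'
#' Schema: id, group, pre_lacbic_tumor, post_lacbic_tumor,
#' pre_lacbic_normal, post_lacbic_normal, vol_pre_mm3, vol_post_mm3,
#' survival_day, event. Reading validates the schema, group levels and
#' event flags and reports the offending row/column.
#'
#' @param cohort cohort data.frame
#' @param path CSV path
#' @return `readCohort` returns the validated data.frame
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("validation error: missing file ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  requireFields(df, c("id", "group", "pre_lacbic_tumor",
                      "post_lacbic_tumor", "pre_lacbic_normal",
                      "post_lacbic_normal", "vol_pre_mm3",
                      "vol_post_mm3", "survival_day", "event"),
                "cohort CSV", path)
  bad <- which(!df$event %in% c(0L, 1L))
  if (length(bad) > 0)
    stop(sprintf("validation error in cohort CSV '%s': column 'event' row %d must be 0 or 1",
                 path, bad[1]))
  bad <- which(!df$group %in% c("deceased", "survivor", "control"))
  if (length(bad) > 0)
    stop(sprintf("validation error in cohort CSV '%s': column 'group' row %d has unknown level '%s'",
                 path, bad[1], df$group[bad[1]]))
  bad <- which(df$survival_day <= 0)
  if (length(bad) > 0)
    stop(sprintf("validation error in cohort CSV '%s': column 'survival_day' row %d must be > 0",
                 path, bad[1]))
  df
}

#' Write / read an experiment report as JSON
#'
#' @param report named list
#' @param path JSON path
#' @return `readReport` returns the list
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("validation error: missing file ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read an experiment configuration as YAML
#'
#' @param config named list (see [experimentConfig()])
#' @param path YAML path
#' @return `readConfig` returns the validated config list
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("validation error: missing file ", path)
  cfg <- yaml::read_yaml(path)
  do.call(experimentConfig, cfg)
}
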