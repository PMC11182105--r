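# File I/O: NIfTI images, CSV tables, YAML pipeline configuration.

#' Read an ASL series from NIfTI files
#'
#' @param controlPath,labelPath Paths to the control / label stacks (2-D
#'   with a repetition dimension, or 3-D with repetitions third).
#' @param m0Path Path to the M0 image (first volume is used if several).
#' @param params An [AcquisitionParams-class]; when `NULL`, defaults for
#'   `eye` are used with the pixel size taken from the NIfTI header.
#' @param eye `"left"` or `"right"` (used when `params` is `NULL`).
#' @return An [ASLSeries-class].
#' @export
readASLSeries <- function(controlPath, labelPath, m0Path, params = NULL,
                          eye = c("left", "right")) {
  for (p in c(controlPath, labelPath, m0Path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  ctl <- asRepArray(RNifti::readNifti(controlPath))
  lbl <- asRepArray(RNifti::readNifti(labelPath))
  m0 <- asRepArray(RNifti::readNifti(m0Path))[, , 1]
  if (is.null(params)) {
    eye <- match.arg(eye)
    pd <- RNifti::pixdim(RNifti::readNifti(controlPath))
    params <- acquisitionParams(eye, pixelMm = pd[1])
  }
  aslSeries(ctl, lbl, m0, params)
}

asRepArray <- function(x) {
  x <- unclass(x)
  d <- dim(x)
  if (is.null(d) || length(d) < 2 || length(d) > 4) {
    stop("expected a 2-D image or a stack with repetitions in dimension 3")
  }
  if (length(d) == 2) dim(x) <- c(d, 1L)
  if (length(d) == 4) {
    if (d[3] == 1) dim(x) <- c(d[1], d[2], d[4]) else
      stop("4-D input must be a single slice with repetitions in dimension 4")
  }
  array(as.numeric(x), dim(x))
}

#' Write a quantitative map as NIfTI
#'
#' The pixel size is stored in the header; masked-out pixels are written as
#' `NA`.
#'
#' @param qmap A [QuantMap-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
writeQuantMap <- function(qmap, path) {
  stopifnot(is(qmap, "QuantMap"))
  img <- qmap@bf
  img[!qmap@mask] <- NA_real_
  nim <- RNifti::asNifti(img)
  RNifti::pixdim(nim) <- c(qmap@pixelMm, qmap@pixelMm)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read per-eye records from CSV
#'
#' @param path CSV with columns `subject`, `group`, `eye`, `metric`,
#'   `value` and optionally `iop`.
#' @return `data.frame` with validated columns; `eye` normalised to
#'   `"left"`/`"right"`.
#' @export
readEyeRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "eye", "metric", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("records CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!nrow(df)) stop("records CSV has no rows")
  df$eye <- tolower(df$eye)
  df$eye[df$eye %in% c("le", "l")] <- "left"
  df$eye[df$eye %in% c("re", "r")] <- "right"
  if (!all(df$eye %in% c("left", "right"))) {
    stop("column 'eye' must contain left/right (or LE/RE)")
  }
  if (!is.numeric(df$value)) stop("column 'value' must be numeric")
  df
}

#' Read a printed group-summary table from CSV
#'
#' @param path CSV with columns `metric`, `group`, `eye`, `mean`, `sd` and
#'   optionally `n`.
#' @return Validated `data.frame`.
#' @export
readGroupSummaryTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metric", "group", "eye", "mean", "sd")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("summary CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$eye <- tolower(df$eye)
  df$eye[df$eye %in% c("le", "l")] <- "left"
  df$eye[df$eye %in% c("re", "r")] <- "right"
  df
}

#' Default pipeline configuration
#'
#' All acquisition constants, analysis options, simulation and phantom
#' settings with their package defaults; round-trips losslessly through
#' YAML.
#'
#' @return Nested list.
#' @export
defaultPipelineConfig <- function() {
  list(
    acquisition = list(
      te_s = 0.009,
      pld_s = list(left = 0.325, right = 0.381),
      label_duration_s = 2.542,
      alpha_label = 0.75,
      t1_blood_s = 1.8,
      t2star_blood_s = 0.035,
      lambda_a = 0.85,
      pixel_mm = 0.042
    ),
    analysis = list(
      interp_factor = 6,
      edge_frac = 0.1,
      secondary_frac = 0.125,
      span_mm = 1,
      onh_exclusion_mm = 0.2,
      vitreous_depth_mm = c(-0.3, -0.1),
      depth_range_mm = c(-0.4, 0.5),
      interp_method = "cubic"
    ),
    simulation = list(
      resolutions_um = seq(10, 250, by = 10),
      output_spacing_um = 7
    ),
    phantom = list(
      n_reps = 75,
      noise_sd = 0.06,
      matrix_size = 144
    ),
    seed = 1
  )
}

#' Read (and validate) a pipeline configuration
#'
#' Unknown keys are rejected with the offending key named; missing keys fall
#' back to the defaults.
#'
#' @param path YAML file.
#' @return Nested configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  mergeConfig(defaultPipelineConfig(), user, prefix = NULL)
}

mergeConfig <- function(def, user, prefix) {
  if (is.null(user)) return(def)
  for (k in names(user)) {
    full <- paste(c(prefix, k), collapse = ".")
    if (!k %in% names(def)) stop("unknown config key: ", full)
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- mergeConfig(def[[k]], user[[k]], full)
    } else {
      val <- user[[k]]
      if (is.list(val)) val <- unlist(val)
      def[[k]] <- val
    }
  }
  def
}

#' Write a pipeline configuration to YAML
#'
#' @param config Nested configuration list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Acquisition parameters from a configuration
#'
#' @param config Configuration list (see [defaultPipelineConfig()]).
#' @param eye `"left"` or `"right"`.
#' @return An [AcquisitionParams-class].
#' @export
configAcquisitionParams <- function(config, eye = c("left", "right")) {
  eye <- match.arg(eye)
  a <- config$acquisition
  acquisitionParams(
    eye = eye, te = a$te_s, pld = a$pld_s[[eye]],
    labelDuration = a$label_duration_s, alpha = a$alpha_label,
    t1Blood = a$t1_blood_s, t2starBlood = a$t2star_blood_s,
    lambdaA = a$lambda_a, pixelMm = a$pixel_mm
  )
}
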