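#' Dynamic perfusion image series
#'
#' Container for one physiological state's 4D first-pass stack: array with
#' dimensions (x, y, slice, frame), frame interval, frame times, slice
#' levels and pixel spacing.
#'
#' @param data 4D numeric array `(nx, ny, n_slices, n_frames)`.
#' @param dt Frame interval (s), > 0.
#' @param spacing In-plane pixel spacing (mm), `c(dx, dy)`.
#' @param levels Character vector of slice levels.
#' @param n_baseline Number of pre-contrast frames (metadata for baseline
#'   detection).
#' @return An object of class `perfusion_series`.
#' @export
perfusion_series <- function(data, dt, spacing = c(1, 1),
                             levels = c("base", "mid", "apex"),
                             n_baseline = 5L) {
  if (length(dim(data)) != 4L)
    stop("perfusion_series: 'data' must be a 4D array (x, y, slice, frame)")
  if (!is.numeric(dt) || dt <= 0)
    stop("perfusion_series: frame interval 'dt' must be > 0")
  nt <- dim(data)[4]
  structure(list(data = data, dt = dt, times = (seq_len(nt) - 1) * dt,
                 spacing = spacing, levels = levels,
                 n_baseline = as.integer(n_baseline)),
            class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("perfusion_series: %d x %d px, %d slices, %d frames, dt = %g s\n",
              d[1], d[2], d[3], d[4], x$dt))
  invisible(x)
}

#' Read / write a 4D perfusion series as NIfTI
#'
#' Dimension order x, y, slice, time; pixel spacing and the frame interval
#' are carried in the header `pixdim`. Reading rejects non-4D images and
#' headers without a positive time step.
#'
#' @param series A [perfusion_series()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param n_baseline Baseline-frame count to attach on read (default 5).
#' @return `write_perfusion_nifti` returns `path` invisibly;
#'   `read_perfusion_nifti` returns a [perfusion_series()].
#' @export
write_perfusion_nifti <- function(series, path) {
  stopifnot(inherits(series, "perfusion_series"))
  a <- series$data
  attr(a, "pixdim") <- c(series$spacing[1], series$spacing[2], 8, series$dt)
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), path)
  invisible(path)
}

#' @rdname write_perfusion_nifti
#' @export
read_perfusion_nifti <- function(path, n_baseline = 5L) {
  if (!file.exists(path))
    stop("read_perfusion_nifti: no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 4L)
    stop("read_perfusion_nifti: expected a 4D series, got ",
         length(dim(arr)), "D: ", path)
  pd <- RNifti::niftiHeader(path)$pixdim  # raw header: time step at [5]
  if (length(pd) < 5L || !is.finite(pd[5]) || pd[5] <= 0)
    stop("read_perfusion_nifti: header lacks a positive time step (dt): ",
         path)
  perfusion_series(arr, dt = pd[5], spacing = pd[2:3],
                   n_baseline = n_baseline)
}

#' Pipeline run configuration
#'
#' @param rest,stress Paths to the rest / stress 4D NIfTI series.
#' @param contours_dir Directory holding `contours_base.json`,
#'   `contours_mid.json`, `contours_apex.json`.
#' @param out_dir Output directory.
#' @param k Upslope window length in frames (>= 2).
#' @param register Run integer-shift registration before extraction.
#' @param threshold Deficit-flag fraction of the median, in (0, 1).
#' @param n_baseline Baseline frames.
#' @param lge Length-16 logical vector of per-segment LGE flags (or `NULL`).
#' @param seed Integer seed echoed into provenance.
#' @return A `run_config` list.
#' @export
run_config <- function(rest, stress, contours_dir, out_dir,
                       k = 3L, register = FALSE, threshold = 0.75,
                       n_baseline = 5L, lge = NULL, seed = 1L) {
  if (k < 2L) stop("run_config: 'k' must be >= 2")
  if (threshold <= 0 || threshold >= 1)
    stop("run_config: 'threshold' must be in (0, 1)")
  structure(list(rest = rest, stress = stress, contours_dir = contours_dir,
                 out_dir = out_dir, k = as.integer(k),
                 register = isTRUE(register), threshold = threshold,
                 n_baseline = as.integer(n_baseline), lge = lge,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("read_run_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

.read_contour_set <- function(contours_dir) {
  levels <- c("base", "mid", "apex")
  paths <- file.path(contours_dir, paste0("contours_", levels, ".json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("run_pipeline: missing contour file(s): ",
         paste(missing, collapse = ", "))
  lapply(paths, read_contours_json)
}

#' Run the full semi-quantitative perfusion pipeline
#'
#' Reads the rest and stress series and the per-slice contours, optionally
#' applies integer-shift registration, builds AHA 16-segment masks, extracts
#' TSI curves, computes per-segment and global MPRI, flags hypoperfused
#' segments in each state, classifies defects against the LGE flags, and
#' writes the result bundle (CSV + JSON + provenance) to the output
#' directory. Fully deterministic for fixed inputs and seed.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return Invisibly, a list with `mpri` ([compute_mpri()] result), `defects`
#'   data frame, `shifts` (registration corrections or `NULL`) and `files`
#'   (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$rest, config$stress))
    if (!file.exists(p)) stop("run_pipeline: missing input file: ", p)

  rest <- read_perfusion_nifti(config$rest, config$n_baseline)
  stress <- read_perfusion_nifti(config$stress, config$n_baseline)
  contours <- .read_contour_set(config$contours_dir)
  grid <- dim(rest$data)[1:2]
  masks <- lapply(contours, segment_aha16, grid = grid)

  shifts <- NULL
  if (config$register) {
    reg_rest <- register_frames(rest)
    reg_stress <- register_frames(stress)
    rest <- reg_rest$series
    stress <- reg_stress$series
    shifts <- list(rest = reg_rest$shifts, stress = reg_stress$shifts)
  }

  tsi_rest <- extract_tsi(rest, masks, state = "rest")
  tsi_stress <- extract_tsi(stress, masks, state = "stress")
  mpri <- compute_mpri(tsi_rest, tsi_stress, k = config$k)

  seg <- mpri$segments
  stress_def <- flag_deficit_segments(
    stats::setNames(seg$relupslope_stress, seg$segment), config$threshold)
  rest_def <- flag_deficit_segments(
    stats::setNames(seg$relupslope_rest, seg$segment), config$threshold)
  lge <- if (is.null(config$lge)) rep(FALSE, nrow(seg)) else
    as.logical(config$lge)[seg$segment]
  defects <- data.frame(
    segment = seg$segment,
    stress_deficit = unname(stress_def),
    rest_deficit = unname(rest_def),
    lge = lge,
    classification = classify_defect(stress_def, rest_def, lge))

  files <- write_results(mpri, defects, config, shifts)
  invisible(list(mpri = mpri, defects = defects, shifts = shifts,
                 files = files))
}

#' Write a pipeline result bundle
#'
#' Emits `results.csv` (per-segment table: segment, relupslope_rest,
#' relupslope_stress, mpri, level, deficit flags, classification),
#' `mpri.json`, `defects.json` and `provenance.json` (config echo, package
#' version, seed).
#'
#' @param mpri A [compute_mpri()] result.
#' @param defects Defect data frame (see [run_pipeline()]).
#' @param config The [run_config()] used.
#' @param shifts Registration corrections or `NULL`.
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(mpri, defects, config, shifts = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seg <- merge(mpri$segments, defects, by = "segment", sort = TRUE)
  seg <- seg[order(seg$segment),
             c("segment", "relupslope_rest", "relupslope_stress", "mpri",
               "level", "stress_deficit", "rest_deficit", "lge",
               "classification")]
  csv <- file.path(config$out_dir, "results.csv")
  utils::write.csv(seg, csv, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")

  mj <- file.path(config$out_dir, "mpri.json")
  jsonlite::write_json(
    list(global_mpri = mpri$global_mpri,
         level_means = as.list(mpri$level_means),
         n_segments = mpri$n_segments,
         segments = mpri$segments),
    mj, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  dj <- file.path(config$out_dir, "defects.json")
  jsonlite::write_json(defects, dj, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  pj <- file.path(config$out_dir, "provenance.json")
  prov <- list(package = "perfquant",
               version = as.character(utils::packageVersion("perfquant")),
               config = unclass(config),
               registered = !is.null(shifts))
  if (!is.null(shifts)) prov$shifts <- shifts
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, digits = NA,
                       null = "null")

  invisible(c(results = csv, mpri = mj, defects = dj, provenance = pj))
}
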