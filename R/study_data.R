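# Core data containers for dynamic PET studies.
#
# Conventions used throughout the package:
#   * time unit is minutes everywhere (schedule files are in minutes);
#   * voxels are linearized voxel-major with x fastest, then y, then z,
#     matching R's column-major array layout and hence the FFT layout;
#   * indices are 1-based at the R surface, frames run 1..T.

#' Frame schedule of a dynamic acquisition
#'
#' @param mid_times frame mid-point times in minutes, strictly increasing.
#' @param durations frame durations in minutes, all positive.
#' @param decay_constant isotope decay constant zeta in 1/min (0 disables
#'   decay weighting).
#' @return an object of class `frame_schedule`.
#' @export
frame_schedule <- function(mid_times, durations, decay_constant = 0) {
  mid_times <- as.numeric(mid_times)
  durations <- as.numeric(durations)
  if (length(mid_times) < 2L)
    stop("a frame schedule needs at least 2 frames")
  if (length(durations) != length(mid_times))
    stop("mid_times and durations differ in length")
  if (any(!is.finite(mid_times)) || any(!is.finite(durations)))
    stop("non-finite schedule entries")
  if (any(diff(mid_times) <= 0))
    stop("frame mid-times must be strictly increasing")
  if (any(durations <= 0))
    stop("frame durations must be positive")
  structure(
    list(mid_times = mid_times, durations = durations,
         decay_constant = as.numeric(decay_constant)),
    class = "frame_schedule")
}

#' Voxel grid geometry
#'
#' @param dim integer dimensions `c(nx, ny, nz)`; use `nz = 1` for 2-D and
#'   `ny = nz = 1` for 1-D studies.
#' @param spacing voxel spacing in mm per axis (recycled to length 3).
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(dim, spacing = c(1, 1, 1)) {
  dim <- as.integer(dim)
  if (length(dim) == 1L) dim <- c(dim, 1L, 1L)
  if (length(dim) == 2L) dim <- c(dim, 1L)
  if (length(dim) != 3L || any(dim < 1L))
    stop("grid dimensions must be 1-3 positive integers")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("voxel spacings must be positive")
  structure(list(dim = dim, spacing = spacing, n = prod(dim)),
            class = "voxel_grid")
}

#' Dynamic image (N voxels x T frames)
#'
#' @param values numeric N x T matrix of activity concentrations, voxels
#'   linearized x-fastest.
#' @param grid a [voxel_grid()].
#' @param schedule a [frame_schedule()].
#' @return an object of class `dynamic_image`.
#' @export
dynamic_image <- function(values, grid, schedule) {
  values <- as.matrix(values)
  stopifnot(inherits(grid, "voxel_grid"), inherits(schedule, "frame_schedule"))
  if (nrow(values) != grid$n)
    stop(sprintf("image has %d voxels but grid implies %d",
                 nrow(values), grid$n))
  if (ncol(values) != length(schedule$mid_times))
    stop(sprintf("image has %d frames but schedule has %d",
                 ncol(values), length(schedule$mid_times)))
  if (any(!is.finite(values))) stop("non-finite image values")
  structure(list(values = values, grid = grid, schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("dynamic_image: %d x %d x %d voxels, %d frames over %.1f min\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              ncol(x$values), max(x$schedule$mid_times +
                                  x$schedule$durations / 2)))
  invisible(x)
}

# one frame as a 3-D array in grid layout
frame_volume <- function(image, j) {
  array(image$values[, j], dim = image$grid$dim)
}

#' Arterial input function
#'
#' @param times sample times in minutes (increasing, starting at or before 0).
#' @param cp blood tracer concentration at `times`, non-negative, same units
#'   as the image data.
#' @return an object of class `input_function`.  Evaluate with
#'   [eval_input_function()]; values are linearly interpolated and 0 before
#'   the first sample.
#' @export
input_function <- function(times, cp) {
  times <- as.numeric(times); cp <- as.numeric(cp)
  if (length(times) != length(cp) || length(times) < 2L)
    stop("times and cp must be equal-length vectors (>= 2)")
  if (any(diff(times) <= 0)) stop("input function times must be increasing")
  if (any(cp < 0)) stop("input function must be non-negative")
  structure(list(times = times, cp = cp), class = "input_function")
}

#' Evaluate an arterial input function
#'
#' @param aif an [input_function()].
#' @param t times (minutes); values before the first sample or negative are 0,
#'   values beyond the last sample are clamped.
#' @return numeric vector of concentrations.
#' @export
eval_input_function <- function(aif, t) {
  out <- fast_interp(aif$times, aif$cp, t)
  out[t < aif$times[1] | t < 0] <- 0
  out
}

#' Volume-of-interest mask
#'
#' @param indicator logical vector, one entry per voxel.
#' @param label a name for the VOI.
#' @return an object of class `voi_mask`.
#' @export
voi_mask <- function(indicator, label = "voi") {
  indicator <- as.logical(indicator)
  if (!any(indicator)) stop("VOI mask selects no voxels")
  structure(list(indicator = indicator, label = label), class = "voi_mask")
}

#' Load a dynamic study from disk
#'
#' Reads a 4-D image (NIfTI-1 `.nii`, or an `.rds` packed array/previously
#' saved `dynamic_image`) together with a frame schedule CSV with header
#' `mid_time_min,duration_min` and optional `decay_per_min` column
#' (constant; first row used).
#'
#' @param image_path path to the image file.
#' @param schedule_path path to the schedule CSV.
#' @return a [dynamic_image()].
#' @export
load_dynamic_study <- function(image_path, schedule_path) {
  sched <- read_schedule(schedule_path)
  T_ <- length(sched$mid_times)
  if (grepl("\\.nii$", image_path, ignore.case = TRUE)) {
    nii <- read_nifti(image_path)
    arr <- nii$data
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 4L)
      stop("expected a 4-D NIfTI volume series")
    d <- dim(arr)
    if (d[4] != T_)
      stop(sprintf("image has %d frames but schedule has %d rows", d[4], T_))
    grid <- voxel_grid(d[1:3], nii$spacing[1:3])
    values <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
    dynamic_image(values, grid, sched)
  } else if (grepl("\\.rds$", image_path, ignore.case = TRUE)) {
    obj <- readRDS(image_path)
    if (inherits(obj, "dynamic_image")) {
      if (ncol(obj$values) != T_)
        stop("frame count of image does not match schedule")
      dynamic_image(obj$values, obj$grid, sched)
    } else if (is.array(obj) && length(dim(obj)) == 4L) {
      d <- dim(obj)
      if (d[4] != T_)
        stop(sprintf("image has %d frames but schedule has %d rows",
                     d[4], T_))
      dynamic_image(matrix(obj, prod(d[1:3]), d[4]),
                    voxel_grid(d[1:3]), sched)
    } else stop("unsupported packed-array contents")
  } else stop("unsupported image format (use .nii or .rds)")
}

#' Write a dynamic study to disk
#'
#' @param image a [dynamic_image()].
#' @param image_path output `.nii` path.
#' @param schedule_path optional output schedule CSV path.
#' @return `image_path`, invisibly.
#' @export
save_dynamic_study <- function(image, image_path, schedule_path = NULL) {
  stopifnot(inherits(image, "dynamic_image"))
  arr <- array(image$values, dim = c(image$grid$dim, ncol(image$values)))
  write_nifti(arr, image_path, spacing = image$grid$spacing)
  if (!is.null(schedule_path)) write_schedule(image$schedule, schedule_path)
  invisible(image_path)
}

read_schedule <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("mid_time_min", "duration_min")
  if (!all(need %in% names(tab)))
    stop("schedule CSV needs columns mid_time_min,duration_min")
  zeta <- if ("decay_per_min" %in% names(tab)) tab$decay_per_min[1] else 0
  frame_schedule(tab$mid_time_min, tab$duration_min, zeta)
}

write_schedule <- function(schedule, path) {
  utils::write.csv(
    data.frame(mid_time_min = schedule$mid_times,
               duration_min = schedule$durations,
               decay_per_min = schedule$decay_constant),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an arterial input function CSV (`time_min,cp`)
#'
#' @param path CSV path.
#' @return an [input_function()].
#' @export
read_input_function <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_min", "cp") %in% names(tab)))
    stop("input function CSV needs columns time_min,cp")
  input_function(tab$time_min, tab$cp)
}

# ---- fitted-model serialization ------------------------------------------

glm_fit_fields <- c("basis", "alpha", "sigma", "phi", "w0", "phi0", "kappa",
                    "qtransform", "spectrum", "zhat", "residuals",
                    "eta", "grid", "schedule")

#' Save / load a fitted image-domain model
#'
#' The fit is stored as a single self-describing container (R serialization
#' of the named component list).  All numeric fields round-trip losslessly.
#'
#' @param fit a `glm_fit` object from [fit_glm()].
#' @param path file path.
#' @return `load_fit` returns the restored `glm_fit`.
#' @export
save_fit <- function(fit, path) {
  stopifnot(inherits(fit, "glm_fit"))
  missing <- setdiff(glm_fit_fields, names(fit))
  if (length(missing))
    stop("fit is incomplete; missing fields: ", paste(missing, collapse = ", "))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_fit
#' @export
load_fit <- function(path) {
  fit <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt fit file: ",
                                           conditionMessage(e)))
  if (!inherits(fit, "glm_fit"))
    stop("corrupt fit file: not a glm_fit container")
  missing <- setdiff(glm_fit_fields, names(fit))
  if (length(missing))
    stop("corrupt fit file: missing fields ",
         paste(missing, collapse = ", "))
  fit
}
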