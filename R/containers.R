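#' Saturation image series (Z-spectrum per voxel)
#'
#' Container for a saturation-offset image series: a voxels-by-offsets
#' signal matrix, the offset axis in ppm, the unsaturated reference image
#' S0, the image grid shape, and a logical brain mask. Signals are stored
#' unnormalized; analysis functions divide by `reference` where needed.
#'
#' @param data Numeric matrix, voxels x offsets (voxels in column-major
#'   image order).
#' @param offsets Offset axis, ppm; one value per data column.
#' @param reference Unsaturated S0 image, one value per voxel.
#' @param shape Integer vector `c(nx, ny)` of the image grid.
#' @param mask Logical per voxel; defaults to `reference > 0`.
#' @return An object of class `zspectrum_series`.
#' @export
zspectrum_series <- function(data, offsets, reference, shape,
                             mask = reference > 0) {
  data <- as.matrix(data)
  if (ncol(data) != length(offsets))
    stop("data has ", ncol(data), " frames but offsets has ",
         length(offsets), " entries")
  if (nrow(data) != length(reference))
    stop("data and reference disagree on voxel count")
  if (anyDuplicated(offsets)) stop("offsets must be distinct")
  if (any(data[is.finite(data)] < 0)) stop("signals must be non-negative")
  if (prod(shape) != nrow(data))
    stop("shape ", paste(shape, collapse = "x"),
         " does not match voxel count ", nrow(data))
  structure(list(data = data, offsets = as.numeric(offsets),
                 reference = as.numeric(reference),
                 shape = as.integer(shape), mask = as.logical(mask)),
            class = "zspectrum_series")
}

#' @export
print.zspectrum_series <- function(x, ...) {
  cat("<zspectrum_series> ", paste(x$shape, collapse = " x "), " voxels, ",
      length(x$offsets), " offsets [",
      round(min(x$offsets), 2), ", ", round(max(x$offsets), 2), "] ppm, ",
      sum(x$mask), " in mask\n", sep = "")
  invisible(x)
}

# normalized Z = S/S0, NA outside mask
z_normalized <- function(z) {
  out <- z$data / z$reference
  out[!z$mask, ] <- NA_real_
  out
}

#' Relaxation / diffusion image series
#'
#' A voxels-by-points series along one acquisition axis: repetition time
#' (TR, ms), echo time (TE, ms), diffusion weighting (b, s/mm^2) or
#' inversion time (TI, ms). For FAIR data, `selective` marks which frames
#' belong to the slice-selective inversion condition.
#'
#' @param data Numeric matrix, voxels x points.
#' @param axis_values Acquisition axis values, one per column.
#' @param axis_kind One of "TR", "TE", "b", "TI".
#' @param shape Integer image grid shape.
#' @param mask Logical per voxel.
#' @param selective Optional logical per column (FAIR labeling condition).
#' @return An object of class `relaxation_series`.
#' @export
relaxation_series <- function(data, axis_values, axis_kind, shape,
                              mask = rep(TRUE, nrow(data)), selective = NULL) {
  data <- as.matrix(data)
  axis_kind <- match.arg(axis_kind, c("TR", "TE", "b", "TI"))
  if (ncol(data) != length(axis_values))
    stop("data has ", ncol(data), " frames but axis has ",
         length(axis_values), " values")
  if (prod(shape) != nrow(data)) stop("shape does not match voxel count")
  if (!is.null(selective)) {
    if (length(selective) != length(axis_values))
      stop("selective flag length mismatch")
    for (s in c(TRUE, FALSE)) {
      av <- axis_values[selective == s]
      if (length(av) > 1 && any(diff(av) <= 0))
        stop("axis values must be strictly increasing within each ",
             "labeling condition")
    }
  } else if (length(axis_values) > 1 && any(diff(axis_values) <= 0)) {
    stop("axis values must be strictly increasing")
  }
  structure(list(data = data, axis_values = as.numeric(axis_values),
                 axis_kind = axis_kind, shape = as.integer(shape),
                 mask = as.logical(mask), selective = selective),
            class = "relaxation_series")
}

#' @export
print.relaxation_series <- function(x, ...) {
  cat("<relaxation_series> axis ", x$axis_kind, " (", length(x$axis_values),
      " points), ", paste(x$shape, collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

#' Fitted scalar map
#'
#' A per-voxel scalar result (GluCEST percent, T1, T2, ADC, CBF, B0, B1)
#' with units, validity flags and optional fit diagnostics. Values are NA
#' wherever `valid` is FALSE; invalidity propagates, never silently fills.
#'
#' @param values Numeric per voxel.
#' @param shape Integer image grid shape.
#' @param units Unit string ("%", "ms", "mm^2/s", "mL/100g/min", "ppm", ...).
#' @param valid Logical per voxel.
#' @param diagnostics Optional per-voxel numeric (e.g. fit RMSE).
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, shape, units,
                           valid = is.finite(values), diagnostics = NULL) {
  if (prod(shape) != length(values)) stop("shape does not match voxel count")
  values[!valid] <- NA_real_
  structure(list(values = as.numeric(values), shape = as.integer(shape),
                 units = units, valid = as.logical(valid),
                 diagnostics = diagnostics),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat("<parametric_map> [", x$units, "] ", paste(x$shape, collapse = " x "),
      ", ", sum(x$valid), " valid voxels",
      if (length(v)) sprintf(", median %.4g", median(v)), "\n", sep = "")
  invisible(x)
}

#' Convert a parametric map to an image matrix
#'
#' @param map A [parametric_map()].
#' @return A numeric matrix of dimension `map$shape`.
#' @export
map_as_matrix <- function(map) {
  matrix(map$values, nrow = map$shape[1], ncol = map$shape[2])
}
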