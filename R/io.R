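# NIfTI + JSON-sidecar readers and writers, and the study manifest.
# Convention: image series are written as 4-D NIfTI volumes with the
# acquisition axis (offset/TR/TE/b/TI) as the 4th dimension; the sidecar
# carries the axis arrays with units. Voxel coordinates are 0-based
# column-major index space; no world/atlas coordinates.

series_to_array <- function(data, shape) {
  array(data, dim = c(shape, 1L, ncol(data)))
}

array_to_matrix <- function(a) {
  d <- dim(a)
  if (length(d) == 4L) matrix(a, prod(d[1:3]), d[4])
  else if (length(d) == 3L) matrix(a, prod(d[1:2]), d[3])
  else stop("expected a 3-D or 4-D volume, got ", length(d), " dimensions")
}

#' Write an image series with its JSON sidecar
#'
#' Writes the series as a 4-D NIfTI plus `<stem>.json` describing the
#' acquisition axis (values and units). Z-spectrum series additionally
#' write the unsaturated reference as `<stem>_s0.nii.gz` and the mask as
#' `<stem>_mask.nii.gz`.
#'
#' @param series A [zspectrum_series()] or [relaxation_series()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, the sidecar path.
#' @export
write_series <- function(series, path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  sh <- series$shape
  if (inherits(series, "zspectrum_series")) {
    RNifti::writeNifti(series_to_array(series$data, sh), path)
    RNifti::writeNifti(array(series$reference, dim = c(sh, 1L)),
                       paste0(stem, "_s0.nii.gz"))
    RNifti::writeNifti(array(as.integer(series$mask), dim = c(sh, 1L)),
                       paste0(stem, "_mask.nii.gz"))
    sidecar <- list(series_type = "zspectrum",
                    offsets = series$offsets, offsets_units = "ppm")
  } else if (inherits(series, "relaxation_series")) {
    RNifti::writeNifti(series_to_array(series$data, sh), path)
    RNifti::writeNifti(array(as.integer(series$mask), dim = c(sh, 1L)),
                       paste0(stem, "_mask.nii.gz"))
    units <- c(TR = "ms", TE = "ms", b = "s/mm^2", TI = "ms")
    sidecar <- list(series_type = "relaxation",
                    axis_kind = series$axis_kind,
                    axis_values = series$axis_values,
                    axis_units = unname(units[series$axis_kind]))
    if (!is.null(series$selective)) sidecar$selective <- series$selective
  } else stop("unsupported series class")
  sc_path <- paste0(stem, ".json")
  jsonlite::write_json(sidecar, sc_path, auto_unbox = TRUE, digits = NA)
  invisible(sc_path)
}

#' Read an image series written by [write_series()]
#'
#' Validates the frame count against the sidecar axis; a mismatch is
#' rejected with a message naming both counts.
#'
#' @param path Path to the 4-D NIfTI.
#' @param sidecar Optional sidecar path (default `<stem>.json`).
#' @return A [zspectrum_series()] or [relaxation_series()].
#' @export
read_series <- function(path, sidecar = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  if (is.null(sidecar)) sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(sc$series_type)) stop("sidecar lacks 'series_type'")
  vol <- RNifti::readNifti(path)
  dat <- array_to_matrix(vol)
  shape <- dim(vol)[1:2]
  maskfile <- paste0(stem, "_mask.nii.gz")
  mask <- if (file.exists(maskfile))
    as.vector(RNifti::readNifti(maskfile)) > 0 else rep(TRUE, nrow(dat))
  if (sc$series_type == "zspectrum") {
    axis <- sc$offsets
    if (is.null(axis)) stop("sidecar lacks 'offsets'")
    if (ncol(dat) != length(axis))
      stop("series has ", ncol(dat), " frames but sidecar lists ",
           length(axis), " offsets")
    ref <- as.vector(RNifti::readNifti(paste0(stem, "_s0.nii.gz")))
    zspectrum_series(dat, axis, ref, shape, mask = mask)
  } else {
    axis <- sc$axis_values
    if (is.null(axis) || is.null(sc$axis_kind))
      stop("sidecar lacks 'axis_values'/'axis_kind'")
    if (is.null(sc$axis_units)) stop("sidecar axis has no units")
    if (ncol(dat) != length(axis))
      stop("series has ", ncol(dat), " frames but sidecar lists ",
           length(axis), " axis values")
    relaxation_series(dat, axis, sc$axis_kind, shape, mask = mask,
                      selective = sc$selective)
  }
}

#' Write / read a parametric map as NIfTI + sidecar
#'
#' Invalid voxels are stored as NaN; the sidecar records the units.
#'
#' @param map A [parametric_map()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return Invisibly, the sidecar path (write) or the map (read).
#' @export
write_map <- function(map, path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  RNifti::writeNifti(array(map$values, dim = c(map$shape, 1L)), path)
  sc <- paste0(stem, ".json")
  jsonlite::write_json(list(map = TRUE, units = map$units), sc,
                       auto_unbox = TRUE)
  invisible(sc)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  sc <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  vol <- RNifti::readNifti(path)
  vals <- as.vector(vol)
  parametric_map(vals, dim(vol)[1:2], units = sc$units,
                 valid = is.finite(vals))
}

#' Write a simulated cohort to disk
#'
#' Per-animal NIfTI series plus sidecars, a label image, a ground-truth
#' JSON, and a manifest CSV tying them together.
#'
#' @param cohort A `glucest_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$animals, function(an) {
    ad <- file.path(dir, an$id)
    dir.create(ad, showWarnings = FALSE)
    paths <- list(animal = an$id, group = an$group)
    for (nm in intersect(names(an$data),
                         c("cest", "wassr", "t1", "t2", "adc", "fair"))) {
      p <- file.path(ad, paste0(nm, ".nii.gz"))
      write_series(an$data[[nm]], p)
      paths[[nm]] <- p
    }
    if (!is.null(an$data$b1_pair)) {
      bp <- an$data$b1_pair
      p <- file.path(ad, "b1_pair.nii.gz")
      RNifti::writeNifti(series_to_array(cbind(bp$flip_low, bp$flip_high),
                                         bp$shape), p)
      jsonlite::write_json(list(series_type = "b1_pair",
                                angles = bp$angles, angle_units = "deg"),
                           file.path(ad, "b1_pair.json"), auto_unbox = TRUE)
      paths$b1_pair <- p
    }
    truth <- an$data$truth
    RNifti::writeNifti(array(as.integer(truth$label_image),
                             dim = c(truth$shape, 1L)),
                       file.path(ad, "labels.nii.gz"))
    jsonlite::write_json(list(target_percent = an$target_percent,
                              glu_fraction = an$glu_fraction,
                              glu_concentration = an$glu_concentration,
                              units = list(target_percent = "%",
                                           glu_concentration = "umol/g")),
                         file.path(ad, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    paths$labels <- file.path(ad, "labels.nii.gz")
    as.data.frame(paths)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Load a cohort from a written manifest
#'
#' Reconstructs a cohort object from per-animal files referenced by a
#' manifest CSV (as written by [write_cohort()], or assembled by hand for
#' real acquisitions), so [run_pipeline()] can operate on on-disk
#' studies. Ground-truth JSONs are attached when present.
#'
#' @param manifest_path Manifest CSV path.
#' @param pools,water,schedule Forward model used for the B1-correction
#'   lookup.
#' @return A `glucest_cohort`.
#' @export
load_cohort <- function(manifest_path, pools = glu_pool(),
                        water = water_pool(),
                        schedule = acquisition_schedule()) {
  man <- read_manifest(manifest_path)
  animals <- lapply(seq_len(nrow(man)), function(i) {
    dat <- list()
    for (nm in intersect(names(man),
                         c("cest", "wassr", "t1", "t2", "adc", "fair")))
      dat[[nm]] <- read_series(man[[nm]][i])
    if ("b1_pair" %in% names(man)) {
      stem <- sub("\\.nii(\\.gz)?$", "", man$b1_pair[i])
      sc <- jsonlite::read_json(paste0(stem, ".json"),
                                simplifyVector = TRUE)
      vol <- array_to_matrix(RNifti::readNifti(man$b1_pair[i]))
      sh <- dim(RNifti::readNifti(man$b1_pair[i]))[1:2]
      mask <- if (!is.null(dat$cest)) dat$cest$mask else
        rep(TRUE, nrow(vol))
      dat$b1_pair <- list(flip_low = vol[, 1], flip_high = vol[, 2],
                          angles = sc$angles, shape = sh, mask = mask)
    }
    truth_path <- file.path(dirname(man$cest[i]), "truth.json")
    labels_path <- if ("labels" %in% names(man)) man$labels[i] else
      file.path(dirname(man$cest[i]), "labels.nii.gz")
    truth <- NULL
    if (file.exists(labels_path)) {
      lab <- RNifti::readNifti(labels_path)
      truth <- list(label_image = matrix(lab, dim(lab)[1], dim(lab)[2]),
                    shape = dim(lab)[1:2])
      if (file.exists(truth_path))
        truth <- c(truth, jsonlite::read_json(truth_path,
                                              simplifyVector = TRUE))
    }
    dat$truth <- truth
    list(id = man$animal[i], group = man$group[i],
         target_percent = if (!is.null(truth$target_percent))
           truth$target_percent else NA_real_,
         glu_fraction = if (!is.null(truth$glu_fraction))
           truth$glu_fraction else NA_real_,
         glu_concentration = if (!is.null(truth$glu_concentration))
           truth$glu_concentration else NA_real_,
         data = dat)
  })
  structure(list(animals = animals, groups = unique(man$group),
                 seed = NA_integer_,
                 pools = if (inherits(pools, "pool_parameters")) list(pools)
                         else pools,
                 water = water, schedule = schedule, noise_sd = NA_real_,
                 brain_fraction = NA_real_),
            class = "glucest_cohort")
}

#' Read a study manifest
#'
#' @param path Manifest CSV with one row per animal and columns naming
#'   the per-series file paths.
#' @return Data frame; errors if any referenced file is missing.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("animal", "group") %in% names(m)))
    stop("manifest needs 'animal' and 'group' columns")
  pathcols <- setdiff(names(m), c("animal", "group"))
  for (cc in pathcols) {
    missing <- m[[cc]][!file.exists(m[[cc]])]
    if (length(missing))
      stop("manifest references missing file(s) for animal ",
           m$animal[!file.exists(m[[cc]])][1], ": ", missing[1])
  }
  m
}
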