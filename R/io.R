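#' Write and read four-band scenes as TIFF + JSON sidecar
#'
#' Scenes are written as a 4-sample 32-bit TIFF in the fixed band order
#' green, red, red-edge, NIR (reflectance already lies in \[0, 1\]),
#' with the grid metadata (field id, GSD, plot grid, year, week) in a
#' JSON sidecar next to the raster, `<path>.json`.
#'
#' @param scene A [band_scene()].
#' @param path Output TIFF path.
#' @return `write_scene` returns `path` invisibly; `read_scene` the
#'   restored `band_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "band_scene"))
  arr <- array(0, c(dim(scene$bands$green), 4))
  arr[, , 1] <- scene$bands$green
  arr[, , 2] <- scene$bands$red
  arr[, , 3] <- scene$bands$rededge
  arr[, , 4] <- scene$bands$nir
  tiff::writeTIFF(arr, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(field_id = scene$field_id, gsd_cm = scene$gsd_cm,
         plot_size_m = scene$plot_size_m, grid_cols = scene$grid_cols,
         grid_rows = scene$grid_rows, year = scene$year,
         week = scene$week,
         band_order = c("green", "red", "rededge", "nir")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  # suppress the benign libtiff note about >3 samples per pixel: band
  # semantics live in the sidecar, not the photometric tag
  arr <- suppressWarnings(tiff::readTIFF(path))
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  band_scene(meta$field_id, green = arr[, , 1], red = arr[, , 2],
             rededge = arr[, , 3], nir = arr[, , 4],
             gsd_cm = meta$gsd_cm, grid_cols = meta$grid_cols,
             grid_rows = meta$grid_rows, year = meta$year,
             week = meta$week, plot_size_m = meta$plot_size_m)
}

#' Write and read index rasters as two-sample TIFF
#'
#' Index values in \[-1, 1\] are stored affinely rescaled to \[0, 1\]
#' ((v + 1) / 2) in sample 1; sample 2 is a 0/1 definedness mask so
#' undefined (NA) pixels survive the round trip, never silently zeroed.
#'
#' @param index An `index_raster`.
#' @param path Output TIFF path.
#' @return `write_index_tif` returns `path` invisibly;
#'   `read_index_tif` the restored `index_raster`.
#' @export
write_index_tif <- function(index, path) {
  arr <- array(0, c(dim(index), 2))
  v <- unclass(index)
  defined <- !is.na(v)
  v[!defined] <- -1
  arr[, , 1] <- (v + 1) / 2
  arr[, , 2] <- defined * 1
  tiff::writeTIFF(arr, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(index = attr(index, "index"),
         field_id = attr(index, "field_id"),
         encoding = "value = 2*sample1 - 1; sample2 = defined mask"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index_tif
#' @export
read_index_tif <- function(path) {
  arr <- suppressWarnings(tiff::readTIFF(path))
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  v <- 2 * arr[, , 1] - 1
  v[arr[, , 2] < 0.5] <- NA_real_
  index_raster(v, meta$index, meta$field_id)
}

#' Write and read artefact masks as single-band 0/1 TIFF
#'
#' @param mask An `artefact_mask`.
#' @param path Output TIFF path.
#' @return `write_mask_tif` returns `path` invisibly; `read_mask_tif` a
#'   logical matrix.
#' @export
write_mask_tif <- function(mask, path) {
  stopifnot(inherits(mask, "artefact_mask"))
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tif
#' @export
read_mask_tif <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Write and read ground-truth plot tables as CSV
#'
#' Columns: field_id, plot_col, plot_row, density_state (label), year,
#' week — the interchange format between the scene generator and the
#' gridding stage.
#'
#' @param observations Tibble of plot observations (with a `state`
#'   column).
#' @param path CSV path.
#' @return `write_truth_csv` returns `path` invisibly; `read_truth_csv`
#'   the observations tibble with `state` restored as ordered factor.
#' @export
write_truth_csv <- function(observations, path) {
  out <- tibble::tibble(
    field_id = observations$field_id,
    plot_col = observations$plot_col,
    plot_row = observations$plot_row,
    density_state = as.character(as_density_state(observations$state)),
    year = observations$year, week = observations$week
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           field_id = readr::col_character(),
                           plot_col = readr::col_integer(),
                           plot_row = readr::col_integer(),
                           density_state = readr::col_character(),
                           year = readr::col_integer(),
                           week = readr::col_integer()))
  out$state <- as_density_state(out$density_state)
  dplyr::select(out, -"density_state")
}

#' Write a subplot manifest (without tiles) as CSV
#'
#' @param manifest A manifest tibble (tile list-column is dropped).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(manifest, path) {
  out <- manifest[setdiff(names(manifest), "tile")]
  out$state <- as.character(out$state)
  readr::write_csv(out, path)
  invisible(path)
}
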