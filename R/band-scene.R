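#' Construct a four-band multispectral scene
#'
#' The unit a UAS flight produces: one field's co-registered reflectance
#' rasters in the four bands of the multispectral sensor (green 550 nm,
#' red 660 nm, red-edge 735 nm, NIR 790 nm), with the ground sample
#' distance and the ground-truth plot grid layout. Rasters are base
#' matrices with row 1 at the top (image convention); the plot grid is
#' indexed from the bottom-left corner.
#'
#' @param field_id Field identifier (string).
#' @param green,red,rededge,nir Reflectance matrices in \[0, 1\], all the
#'   same dimensions.
#' @param gsd_cm Ground sample distance, cm per pixel.
#' @param grid_cols,grid_rows Plot grid layout (columns x rows of
#'   20 x 20 m plots).
#' @param year,week Survey year and week-of-season (1-6).
#' @param plot_size_m Plot side, metres (fixed at 20 in this design).
#' @return An object of class `band_scene`.
#' @export
band_scene <- function(field_id, green, red, rededge, nir, gsd_cm,
                       grid_cols, grid_rows, year = NA_integer_,
                       week = NA_integer_, plot_size_m = 20) {
  bands <- list(green = green, red = red, rededge = rededge, nir = nir)
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1) {
    stop("all four band rasters must share identical dimensions",
         call. = FALSE)
  }
  rng <- range(unlist(lapply(bands, range), use.names = FALSE))
  if (rng[1] < 0 || rng[2] > 1) {
    stop("reflectance values must lie in [0, 1]", call. = FALSE)
  }
  if (gsd_cm <= 0) stop("gsd_cm must be positive", call. = FALSE)
  structure(
    list(field_id = as.character(field_id), bands = bands,
         gsd_cm = gsd_cm, plot_size_m = plot_size_m,
         grid_cols = as.integer(grid_cols), grid_rows = as.integer(grid_rows),
         year = as.integer(year), week = as.integer(week)),
    class = "band_scene"
  )
}

# Plot side in pixels implied by the scene's GSD.
plot_px <- function(scene) {
  as.integer(round(scene$plot_size_m * 100 / scene$gsd_cm))
}

#' @export
print.band_scene <- function(x, ...) {
  d <- dim(x$bands$green)
  cat("<band_scene> field", x$field_id, "-", d[1], "x", d[2], "px,",
      x$gsd_cm, "cm GSD,", x$grid_cols, "x", x$grid_rows, "plot grid\n")
  invisible(x)
}

#' Tabulate per-band summary statistics of a scene
#'
#' @param x A `band_scene`.
#' @param ... Unused.
#' @return A tibble with one row per band.
#' @export
tidy.band_scene <- function(x, ...) {
  purrr::imap(x$bands, function(m, nm) {
    tibble::tibble(band = nm, mean = mean(m), sd = stats::sd(m),
                   min = min(m), max = max(m))
  }) |> purrr::list_rbind()
}
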