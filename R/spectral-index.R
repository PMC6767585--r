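#' Vegetation index rasters
#'
#' `gndvi()` computes the green normalized differential vegetation index,
#' (f_n - f_g) / (f_n + f_g), the index this pipeline classifies on:
#' red-channel chlorophyll saturation in high-biomass wheat makes the
#' red-based NDVI uninformative late in the season, while the green band
#' does not saturate. `ndvi()` computes the red-based index; its
#' `"as_printed"` convention is (f_r - f_n) / (f_r + f_n), the
#' sign-reverse of the textbook definition (f_n - f_r) / (f_n + f_r),
#' which is available as `"conventional"`.
#'
#' Pixels whose band sum (the denominator) is exactly zero are undefined
#' and carried as `NA`, never silently zeroed; downstream stages treat
#' them as masked.
#'
#' @param scene A [band_scene()].
#' @param convention For `ndvi()`: `"as_printed"` (default) or
#'   `"conventional"`.
#' @return An `index_raster`: a numeric matrix of index values in
#'   \[-1, 1\] (NA where undefined) with attributes `index` (name) and
#'   `field_id` (provenance).
#' @examples
#' sc <- band_scene("f1", green = matrix(0.25, 2, 2),
#'                  red = matrix(0.2, 2, 2), rededge = matrix(0.4, 2, 2),
#'                  nir = matrix(0.5, 2, 2), gsd_cm = 1000,
#'                  grid_cols = 1, grid_rows = 1)
#' gndvi(sc)[1, 1]  # (0.5 - 0.25) / (0.5 + 0.25) = 1/3
#' @export
gndvi <- function(scene) {
  stopifnot(inherits(scene, "band_scene"))
  normalized_difference(scene$bands$nir, scene$bands$green, "GNDVI",
                        scene$field_id)
}

#' @rdname gndvi
#' @export
ndvi <- function(scene, convention = c("as_printed", "conventional")) {
  stopifnot(inherits(scene, "band_scene"))
  convention <- match.arg(convention)
  if (convention == "as_printed") {
    normalized_difference(scene$bands$red, scene$bands$nir,
                          "NDVI(as printed)", scene$field_id)
  } else {
    normalized_difference(scene$bands$nir, scene$bands$red,
                          "NDVI", scene$field_id)
  }
}

normalized_difference <- function(a, b, name, field_id) {
  if (!identical(dim(a), dim(b))) {
    stop("band rasters have mismatched shapes", call. = FALSE)
  }
  den <- a + b
  out <- (a - b) / den
  out[den == 0] <- NA_real_
  index_raster(out, name, field_id)
}

index_raster <- function(values, index, field_id) {
  structure(values, index = index, field_id = field_id,
            class = c("index_raster", "matrix", "array"))
}

#' @export
print.index_raster <- function(x, ...) {
  cat("<index_raster>", attr(x, "index"), "for field",
      attr(x, "field_id"), "-", nrow(x), "x", ncol(x), "px,",
      sum(is.na(x)), "undefined px\n")
  invisible(x)
}
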