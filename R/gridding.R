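#' Extract 20 x 20 m plot tiles from an index raster
#'
#' Overlays the ground-truth plot grid on an index raster and cuts one
#' tile per observation. Plot grid positions are indexed from the
#' bottom-left corner of the field, while rasters are stored top-down;
#' the conversion happens here, and pixel windows are half-open so
#' adjacent plots share no pixels. Observations whose window falls
#' outside the raster are rejected individually (reported in the
#' `rejected` attribute and a warning), never padded, and never affect
#' the remaining records.
#'
#' @param index An `index_raster` (see [gndvi()]).
#' @param observations Tibble of plot observations: `field_id`,
#'   `plot_col`, `plot_row`, `state`, and optionally `year`, `week`.
#' @param scene The [band_scene()] the raster came from (supplies GSD
#'   and grid layout).
#' @return A tibble with one row per accepted observation and a `tile`
#'   list-column of index matrices; attribute `rejected` holds the
#'   identifiers of any out-of-bounds records.
#' @export
extract_plots <- function(index, observations, scene) {
  stopifnot(inherits(scene, "band_scene"))
  px <- plot_px(scene)
  H <- nrow(index); W <- ncol(index)
  ok <- observations$plot_col >= 1 & observations$plot_col <= scene$grid_cols &
    observations$plot_row >= 1 & observations$plot_row <= scene$grid_rows &
    observations$plot_col * px <= W &
    (scene$grid_rows - observations$plot_row + 1) * px <= H
  if (any(!ok)) {
    bad <- observations[!ok, c("field_id", "plot_col", "plot_row")]
    warning("rejected ", sum(!ok), " observation(s) outside raster extent: ",
            paste(sprintf("%s(%d,%d)", bad$field_id, bad$plot_col,
                          bad$plot_row), collapse = ", "),
            call. = FALSE)
  }
  kept <- observations[ok, , drop = FALSE]
  tiles <- purrr::map2(kept$plot_col, kept$plot_row, function(pc, pr) {
    rows <- ((scene$grid_rows - pr) * px + 1):((scene$grid_rows - pr + 1) * px)
    cols <- ((pc - 1) * px + 1):(pc * px)
    unclass(index)[rows, cols, drop = FALSE]
  })
  out <- tibble::as_tibble(kept)
  out$tile <- tiles
  attr(out, "rejected") <- observations[!ok, , drop = FALSE]
  out
}

# Half-open pixel windows of the 4 subplot bands along one axis, in
# position order 1..4 counted from the low edge; band 4 absorbs any
# remainder (side not divisible by 4, at most 3 px).
subplot_breaks <- function(side) {
  base <- side %/% 4L
  w <- c(base, base, base, side - 3L * base)
  start <- cumsum(c(0L, w[-4])) + 1L
  cbind(start = start, end = start + w - 1L)
}

#' Split a plot tile into its 4 x 4 grid of subplots
#'
#' Cuts one 20 x 20 m plot tile into 16 subplot tiles. Positions
#' `(pos_col, pos_row)` are counted from the bottom-left subplot (1,1)
#' to the top-right (4,4); the raster itself is stored top-down and the
#' conversion is made explicitly here. Sides not divisible by 4 put
#' their remainder pixels (at most 3) into position 4 along that axis.
#' The 16 tiles partition the parent exactly: reassembling them by
#' position reproduces it pixel-for-pixel.
#'
#' @param tile A plot tile matrix, at least 4 px per side.
#' @return A tibble with columns `pos_col`, `pos_row` (1-4) and `tile`
#'   (list of matrices), 16 rows.
#' @export
subsample_plot <- function(tile) {
  side_r <- nrow(tile); side_c <- ncol(tile)
  if (side_r < 4 || side_c < 4) {
    stop("plot tile must be at least 4 px per side", call. = FALSE)
  }
  bc <- subplot_breaks(side_c)
  br <- subplot_breaks(side_r)  # in bottom-up position order
  grid <- tidyr::expand_grid(pos_row = 1:4, pos_col = 1:4)
  tiles <- purrr::map2(grid$pos_col, grid$pos_row, function(pc, pr) {
    # position row pr counts from the bottom; raster rows from the top
    rows <- (side_r - br[pr, "end"] + 1L):(side_r - br[pr, "start"] + 1L)
    tile[rows, bc[pc, "start"]:bc[pc, "end"], drop = FALSE]
  })
  tibble::tibble(pos_col = grid$pos_col, pos_row = grid$pos_row,
                 tile = tiles)
}

#' Reassemble 16 subplot tiles into their parent plot tile
#'
#' Inverse of [subsample_plot()]; used to verify the exact-tiling
#' invariant.
#'
#' @param subplots A tibble as returned by [subsample_plot()].
#' @return The parent tile matrix.
#' @export
reassemble_subplots <- function(subplots) {
  stopifnot(nrow(subplots) == 16)
  side_c <- sum(purrr::map_int(
    subplots$tile[subplots$pos_row == 1], ncol))
  side_r <- sum(purrr::map_int(
    subplots$tile[subplots$pos_col == 1], nrow))
  proto <- subplots$tile[[1]]
  out <- matrix(proto[NA_integer_][1], side_r, side_c)  # NA, same type
  bc <- subplot_breaks(side_c)
  br <- subplot_breaks(side_r)
  for (i in seq_len(16)) {
    pc <- subplots$pos_col[i]; pr <- subplots$pos_row[i]
    rows <- (side_r - br[pr, "end"] + 1L):(side_r - br[pr, "start"] + 1L)
    out[rows, bc[pc, "start"]:bc[pc, "end"]] <- subplots$tile[[i]]
  }
  out
}

#' Subsample every plot of a plot-tile table into subplot records
#'
#' Applies [subsample_plot()] to each row of an [extract_plots()] result
#' and builds the subplot manifest: 16 records per plot, each carrying
#' its grid position, subplot position, inherited density state and a
#' unique `subplot_id`.
#'
#' @param plots A tibble with `field_id`, `plot_col`, `plot_row`, `state`
#'   and a `tile` list-column (plus optional `year`, `week`).
#' @return The manifest tibble, `16 * nrow(plots)` rows.
#' @export
subsample_plots <- function(plots) {
  recs <- purrr::map(seq_len(nrow(plots)), function(i) {
    sub <- subsample_plot(plots$tile[[i]])
    meta <- plots[i, setdiff(names(plots), "tile"), drop = FALSE]
    out <- tidyr::crossing(meta, tibble::tibble(row = seq_len(16))) |>
      dplyr::select(-"row")
    out$pos_col <- sub$pos_col
    out$pos_row <- sub$pos_row
    out$tile <- sub$tile
    out
  })
  out <- purrr::list_rbind(recs)
  out$subplot_id <- sprintf("%s_p%02d-%02d_s%d%d", out$field_id,
                            out$plot_col, out$plot_row, out$pos_col,
                            out$pos_row)
  dplyr::relocate(out, "subplot_id")
}
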