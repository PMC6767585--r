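#' Ordinal black-grass density states
#'
#' The five ordinal density states used to score black-grass
#' (*Alopecurus myosuroides*) abundance in a 20 x 20 m plot of winter
#' wheat, together with the plant-count range (plants per 20 m^2) that
#' defines each state.
#'
#' @return A tibble with columns `index` (0-4, ordinal), `label`
#'   (`Absent` < `Low` < `Medium` < `High` < `VeryHigh`), `count_min`
#'   and `count_max` (plants per 20 m^2; `Inf` for the open top range).
#' @examples
#' density_states()
#' @export
density_states <- function() {
  tibble::tibble(
    index     = 0:4,
    label     = state_levels(),
    count_min = c(0, 1, 161, 451, 1451),
    count_max = c(0, 160, 450, 1450, Inf)
  )
}

#' @rdname density_states
#' @export
state_levels <- function() {
  c("Absent", "Low", "Medium", "High", "VeryHigh")
}

#' Coerce labels or indices to the ordered density-state factor
#'
#' @param x A character vector of state labels, an integer vector of
#'   ordinal indices (0-4), or an existing factor.
#' @return An ordered factor with the five density-state levels.
#' @examples
#' as_density_state(c("Low", "VeryHigh"))
#' as_density_state(c(0L, 4L))
#' @export
as_density_state <- function(x) {
  lv <- state_levels()
  if (is.numeric(x)) {
    if (any(!is.na(x) & (x < 0 | x > 4 | x != round(x)))) {
      stop("ordinal state indices must be integers in 0-4", call. = FALSE)
    }
    x <- lv[as.integer(x) + 1L]
  }
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), lv)
  if (length(bad) > 0) {
    stop("unknown density-state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' @rdname as_density_state
#' @export
state_index <- function(x) {
  as.integer(as_density_state(x)) - 1L
}
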