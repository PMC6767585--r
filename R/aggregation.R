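#' Upscale subplot predictions to the 20 x 20 m plot scale
#'
#' Ground truth exists only at the 20 x 20 m plot scale, so subplot
#' predictions are re-aggregated by the median before being compared
#' with it. Two readings of "median prediction" are offered:
#' `"median-classes"` (default) takes the lower median of the ordinal
#' argmax classes of the contributing subplots — ties at even counts
#' resolve to the lower state, keeping the result in the ordinal state
#' set and biasing conservatively toward lower density;
#' `"median-vectors"` takes the elementwise median of the 5-score
#' prediction vectors, renormalises, and takes the argmax. When
#' `clean_only` is set, only subplots flagged `clean` contribute; plots
#' whose subplots were all removed are emitted with
#' `predicted = NA` and `n_subplots = 0`, never silently dropped.
#'
#' @param predictions A tibble with one row per subplot: `field_id`,
#'   `plot_col`, `plot_row`, the five score columns named by state
#'   label, and optionally `quality` and `observed`/`state`.
#' @param method `"median-classes"` or `"median-vectors"`.
#' @param clean_only Restrict to subplots with `quality == "clean"`.
#' @return A tibble with one row per plot: identifiers, `predicted`
#'   (ordered state factor, NA if unpredictable), `n_subplots`, scores
#'   (per-plot median vector, renormalised), and `observed` when
#'   available.
#' @export
upscale_predictions <- function(predictions,
                                method = c("median-classes",
                                           "median-vectors"),
                                clean_only = FALSE) {
  method <- match.arg(method)
  lv <- state_levels()
  stopifnot(all(lv %in% names(predictions)))
  sums <- rowSums(as.matrix(predictions[lv]))
  if (any(abs(sums - 1) > 1e-6)) {
    stop("prediction vectors must sum to 1 (tolerance 1e-6)",
         call. = FALSE)
  }
  keys <- c("field_id", "plot_col", "plot_row")
  has_obs <- "observed" %in% names(predictions) ||
    "state" %in% names(predictions)
  obs_col <- if ("observed" %in% names(predictions)) "observed" else "state"

  contributing <- predictions
  if (clean_only) {
    stopifnot("quality" %in% names(predictions))
    contributing <- dplyr::filter(predictions, .data$quality == "clean")
  }

  agg <- contributing |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_subplots = dplyr::n(),
      predicted = {
        if (method == "median-classes") {
          cls <- max.col(as.matrix(dplyr::pick(dplyr::all_of(lv))),
                         ties.method = "first")
          lower_median(cls)
        } else {
          med <- apply(dplyr::pick(dplyr::all_of(lv)), 2, stats::median)
          which.max(med / sum(med))
        }
      },
      dplyr::across(dplyr::all_of(lv), stats::median),
      .groups = "drop"
    )
  sc <- as.matrix(agg[lv])
  agg[lv] <- sc / rowSums(sc)
  agg$predicted <- as_density_state(agg$predicted - 1L)

  # plots present in the input but with no contributing subplots
  all_plots <- dplyr::distinct(predictions,
                               dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::left_join(all_plots, agg, by = keys)
  out$n_subplots[is.na(out$n_subplots)] <- 0L
  if (has_obs) {
    obs <- predictions |>
      dplyr::distinct(dplyr::across(dplyr::all_of(c(keys, obs_col))))
    names(obs)[names(obs) == obs_col] <- "observed"
    out <- dplyr::left_join(out, obs, by = keys)
  }
  out
}

# Lower median: the ceiling(n/2)-th order statistic, an element of the
# input set even at even n.
lower_median <- function(x) {
  sort(x)[ceiling(length(x) / 2)]
}
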