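#' Balance class counts by random downsampling
#'
#' Randomly downsamples every density state, without replacement, to the
#' smallest class count, mirroring the survey's balanced training set
#' (565 examples of each of the 5 states = 2825 images). Deterministic
#' under `seed`.
#'
#' @param records A data frame with a `state` column.
#' @param seed Integer seed.
#' @return A tibble: subset of `records` with equal class counts.
#' @export
balance_classes <- function(records, seed = 1L) {
  st <- as_density_state(records$state)
  counts <- table(st)
  missing <- names(counts)[counts == 0]
  if (length(missing) > 0) {
    stop("cannot balance: no records for state(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- min(counts)
  with_seed(derive_seed(seed, "balance"), {
    keep <- unlist(lapply(state_levels(), function(lv) {
      idx <- which(st == lv)
      if (length(idx) == m) idx else sample(idx, m)
    }))
  })
  tibble::as_tibble(records[sort(keep), , drop = FALSE])
}

#' Flag subplot quality from artefact masks or a label file
#'
#' Attaches a `quality` column (`"clean"` or `"artefact"`) to a subplot
#' manifest. In oracle mode the generator's artefact masks play the role
#' of the manual screening the original surveys used (which was manual
#' and not reproducible): a subplot is flagged `artefact` when the
#' fraction of its pixels lying under an artefact object exceeds
#' `threshold`. In file mode a table of `(subplot_id, quality)` labels
#' is joined instead, so manually curated labels can be supplied.
#'
#' @param manifest Subplot manifest from [subsample_plots()].
#' @param masks Named list of `artefact_mask` objects (one per field),
#'   e.g. `survey$masks`. Oracle mode.
#' @param scenes Named list of [band_scene()] objects matching `masks`.
#' @param labels A data frame with columns `subplot_id`, `quality`.
#'   File mode; overrides `masks`.
#' @param threshold Masked-pixel fraction above which a subplot is an
#'   artefact (default 0.05).
#' @param strict Error on subplots left unlabelled (default TRUE).
#' @return The manifest with a `quality` column.
#' @export
flag_quality <- function(manifest, masks = NULL, scenes = NULL,
                         labels = NULL, threshold = 0.05, strict = TRUE) {
  if (!is.null(labels)) {
    stopifnot(all(c("subplot_id", "quality") %in% names(labels)))
    out <- dplyr::left_join(manifest,
                            labels[, c("subplot_id", "quality")],
                            by = "subplot_id")
  } else {
    if (is.null(masks) || is.null(scenes)) {
      stop("supply either `labels` or both `masks` and `scenes`",
           call. = FALSE)
    }
    frac <- artefact_fraction(manifest, masks, scenes)
    out <- manifest
    out$quality <- ifelse(is.na(frac), NA_character_,
                          ifelse(frac > threshold, "artefact", "clean"))
  }
  if (strict && anyNA(out$quality)) {
    stop(sum(is.na(out$quality)), " subplot(s) left unlabelled",
         call. = FALSE)
  }
  out
}

# Fraction of each manifest subplot's pixels flagged in its field's
# artefact mask, by re-deriving the subplot pixel window.
artefact_fraction <- function(manifest, masks, scenes) {
  purrr::map_dbl(seq_len(nrow(manifest)), function(i) {
    fid <- manifest$field_id[i]
    mask <- masks[[fid]]; scene <- scenes[[fid]]
    if (is.null(mask) || is.null(scene)) return(NA_real_)
    px <- plot_px(scene)
    pr <- manifest$plot_row[i]; pc <- manifest$plot_col[i]
    rows <- ((scene$grid_rows - pr) * px + 1):((scene$grid_rows - pr + 1) * px)
    cols <- ((pc - 1) * px + 1):(pc * px)
    tile <- mask$mask[rows, cols, drop = FALSE]
    bc <- subplot_breaks(ncol(tile)); br <- subplot_breaks(nrow(tile))
    sc <- manifest$pos_col[i]; sr <- manifest$pos_row[i]
    srows <- (nrow(tile) - br[sr, "end"] + 1L):(nrow(tile) - br[sr, "start"] + 1L)
    mean(tile[srows, bc[sc, "start"]:bc[sc, "end"]])
  })
}

#' Partition a quality-flagged manifest into clean and artefact sets
#'
#' @param manifest A manifest with a `quality` column (see
#'   [flag_quality()]).
#' @return A list with disjoint, exhaustive tibbles `clean` and
#'   `artefact`.
#' @export
partition_quality <- function(manifest) {
  stopifnot("quality" %in% names(manifest))
  list(clean = dplyr::filter(manifest, .data$quality == "clean"),
       artefact = dplyr::filter(manifest, .data$quality == "artefact"))
}

coverage_levels <- function() c("<20%", "20-40%", "40-60%", "60-80%", ">80%")

#' Bracket plots by their clean-subplot coverage
#'
#' Assigns each plot to one of five contiguous coverage brackets by the
#' percentage of its 16 subplots that survived cleaning. Boundaries are
#' left-closed, right-open on the percentage scale (\[0,20), \[20,40),
#' \[40,60), \[60,80), \[80,100\]), which places 12/16 = 75% in 60-80%
#' and 13/16 = 81.25% in >80%, matching the survey's "13-16 subplots"
#' top bracket.
#'
#' @param clean_count Integer vector of clean-subplot counts, 0-16.
#' @return A factor with the five bracket levels.
#' @examples
#' coverage_bracket(c(3, 12, 13, 16))
#' @export
coverage_bracket <- function(clean_count) {
  if (any(clean_count < 0 | clean_count > 16 |
            clean_count != round(clean_count))) {
    stop("clean_count must be integers in 0-16", call. = FALSE)
  }
  pct <- 100 * clean_count / 16
  idx <- findInterval(pct, c(20, 40, 60, 80)) + 1L
  factor(coverage_levels()[idx], levels = coverage_levels())
}

#' Split records into train/validation/test sets
#'
#' Random split at image (record) level, stratified by density state by
#' default, mirroring the surveys' simple baseline design of holding out
#' a random 10% of all images. Deterministic under `seed`.
#'
#' @param records A data frame with a `state` column.
#' @param test_frac,val_frac Fractions held out for test / validation.
#' @param seed Integer seed.
#' @param stratify Stratify the split by state (default TRUE).
#' @return `records` with a `split` column
#'   (`"train"`/`"validation"`/`"test"`).
#' @export
split_records <- function(records, test_frac = 0.1, val_frac = 0,
                          seed = 1L, stratify = TRUE) {
  stopifnot(test_frac >= 0, val_frac >= 0, test_frac + val_frac < 1)
  n <- nrow(records)
  strata <- if (stratify) as.character(as_density_state(records$state)) else
    rep("all", n)
  split <- character(n)
  with_seed(derive_seed(seed, "split"), {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      k <- length(idx)
      n_test <- round(k * test_frac)
      n_val <- round(k * val_frac)
      shuffled <- sample(idx)
      split[shuffled[seq_len(n_test)]] <- "test"
      split[shuffled[n_test + seq_len(n_val)]] <- "validation"
      if (n_test + n_val < k) {
        split[shuffled[(n_test + n_val + 1):k]] <- "train"
      }
    }
  })
  out <- tibble::as_tibble(records)
  out$split <- split
  out
}
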