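#' Build the GNDVI subplot manifest of a whole survey
#'
#' Runs every scene of a survey through the index -> plot-extraction ->
#' subsampling -> quality-flagging chain, producing one tidy manifest of
#' subplot records (16 per plot) with tiles, inherited density states
#' and oracle clean/artefact flags.
#'
#' @param survey A `weed_survey` from [generate_survey()].
#' @param threshold Masked-pixel fraction above which a subplot is
#'   flagged artefact (see [flag_quality()]).
#' @return The manifest tibble with `tile` list-column and `quality`.
#' @export
survey_manifest <- function(survey, threshold = 0.05) {
  stopifnot(inherits(survey, "weed_survey"))
  manifest <- purrr::map(survey$fields$field_id, function(fid) {
    scene <- survey$scenes[[fid]]
    obs <- dplyr::filter(survey$observations, .data$field_id == fid)
    plots <- extract_plots(gndvi(scene), obs, scene)
    subsample_plots(plots)
  }) |> purrr::list_rbind()
  flag_quality(manifest, masks = survey$masks, scenes = survey$scenes,
               threshold = threshold)
}

# Train on one record set, score another; returns the test records with
# the five score columns and `.pred` attached.
train_predict <- function(train, test, schedule, arch,
                          max_train = NULL) {
  if (!is.null(max_train) && nrow(train) > max_train) {
    with_seed(derive_seed(schedule$seed, "max-train"), {
      train <- train[sort(sample.int(nrow(train), max_train)), ]
    })
  }
  model <- fit_density_cnn(train$tile, train$state, schedule, arch)
  scored <- predict(model, test$tile)
  out <- dplyr::bind_cols(test[setdiff(names(test), "tile")], scored)
  list(model = model, predictions = out)
}

new_experiment <- function(name, plot_predictions, seed, recipe,
                           model = NULL) {
  scored <- dplyr::filter(plot_predictions, !is.na(.data$predicted))
  metrics <- score_predictions(scored)
  structure(
    list(name = name, metrics = metrics,
         plot_predictions = plot_predictions, seed = seed,
         recipe = recipe, config_hash = rlang::hash(recipe),
         model = model),
    class = "weed_experiment"
  )
}

#' @export
print.weed_experiment <- function(x, ...) {
  cat("<weed_experiment>", x$name, "- seed", x$seed, "\n")
  cat("macro AUC", format(x$metrics$roc$macro_auc, digits = 4),
      "| kappa", format(x$metrics$kappa, digits = 3),
      "| weighted kappa", format(x$metrics$weighted_kappa_paper,
                                 digits = 3),
      "| misclassification",
      sprintf("%.1f%%", x$metrics$misclassification_overall), "\n")
  invisible(x)
}

#' @export
tidy.weed_experiment <- function(x, ...) x$metrics$roc$auc

#' @export
glance.weed_experiment <- function(x, ...) {
  tibble::tibble(
    experiment = x$name,
    macro_auc = x$metrics$roc$macro_auc,
    kappa = x$metrics$kappa,
    weighted_kappa_paper = x$metrics$weighted_kappa_paper,
    weighted_kappa_squared = x$metrics$weighted_kappa_squared,
    misclassification_overall = x$metrics$misclassification_overall,
    misclassification_per_class = x$metrics$misclassification_per_class,
    n_plots = nrow(x$plot_predictions),
    seed = x$seed, config_hash = x$config_hash
  )
}

#' Baseline experiment: random 10% held out at subplot level
#'
#' The simple benchmark all refinements are compared against: a random
#' stratified 90/10 split of the individual subplot images (so not
#' truly out of sample — the model sees most of every field; the
#' contrast with [run_lofo()] is the point), training on 90%,
#' predicting the held-out 10%, upscaling the test subplots to plot
#' level by the median rule and computing the full metric suite.
#'
#' @param manifest A [survey_manifest()] (or compatible) subplot table.
#' @param seed Split/training seed.
#' @param schedule,arch Model configuration; the default schedule is the
#'   desk-scale one used throughout the experiment suite.
#' @param shuffle_labels Permute training labels (null-control variant).
#' @param max_train Cap on training subplots (random subsample).
#' @return A `weed_experiment`.
#' @export
run_baseline <- function(manifest, seed = 1L,
                         schedule = training_schedule(
                           lr0 = 0.03, epochs = 5L, halve_every = 300L, seed = seed),
                         arch = architecture_spec(),
                         shuffle_labels = FALSE, max_train = 6000L) {
  if (shuffle_labels) {
    # break the tile-label association everywhere (train and test), so
    # held-out scores are label-independent by construction
    with_seed(derive_seed(seed, "shuffle"), {
      manifest$state <- sample(manifest$state)
    })
  }
  recs <- split_records(manifest, test_frac = 0.1, seed = seed)
  train <- dplyr::filter(recs, .data$split == "train")
  test <- dplyr::filter(recs, .data$split == "test")
  tp <- train_predict(train, test, schedule, arch, max_train)
  plots <- upscale_predictions(tp$predictions)
  new_experiment(if (shuffle_labels) "baseline-shuffled" else "baseline",
                 plots, seed,
                 recipe = list(split = "random-10pct-subplot",
                               shuffle = shuffle_labels,
                               schedule = unclass(schedule),
                               arch = unclass(arch)),
                 model = tp$model)
}

#' Balanced experiment: equal class counts in every split
#'
#' As [run_baseline()], but the training and test sets are each
#' downsampled to equal class counts first (the survey's balanced
#' design: every state cut to the smallest class).
#'
#' @inheritParams run_baseline
#' @return A `weed_experiment`.
#' @export
run_balanced <- function(manifest, seed = 1L,
                         schedule = training_schedule(
                           lr0 = 0.03, epochs = 5L, halve_every = 300L, seed = seed),
                         arch = architecture_spec(),
                         max_train = 6000L) {
  recs <- split_records(manifest, test_frac = 0.1, seed = seed)
  train <- balance_classes(dplyr::filter(recs, .data$split == "train"),
                           seed = derive_seed(seed, "bal-train"))
  test <- balance_classes(dplyr::filter(recs, .data$split == "test"),
                          seed = derive_seed(seed, "bal-test"))
  tp <- train_predict(train, test, schedule, arch, max_train)
  plots <- upscale_predictions(tp$predictions)
  new_experiment("balanced", plots, seed,
                 recipe = list(split = "random-10pct-balanced",
                               schedule = unclass(schedule),
                               arch = unclass(arch)),
                 model = tp$model)
}

#' Clean/artefact cross-prediction: four train/test combinations
#'
#' Trains one model on the clean partition and one on the artefact
#' partition, then scores each model on both partitions' test sets
#' (clean->clean, artefact->artefact, clean->artefact, artefact->clean),
#' upscaling to plot level before metrics. Cross-prediction measures
#' whether the features the artefact model learns carry any weed signal.
#'
#' @inheritParams run_baseline
#' @return A named list of four `weed_experiment`s.
#' @export
run_clean_artefact <- function(manifest, seed = 1L,
                               schedule = training_schedule(
                                 lr0 = 0.03, epochs = 5L, halve_every = 300L,
                                 seed = seed),
                               arch = architecture_spec(),
                               max_train = 6000L) {
  stopifnot("quality" %in% names(manifest))
  parts <- partition_quality(manifest)
  if (nrow(parts$clean) == 0 || nrow(parts$artefact) == 0) {
    stop("clean/artefact cross-prediction needs both partitions ",
         "non-empty (clean: ", nrow(parts$clean), ", artefact: ",
         nrow(parts$artefact), ")", call. = FALSE)
  }
  split_part <- function(p, stream) {
    split_records(p, test_frac = 0.1, seed = derive_seed(seed, stream))
  }
  clean <- split_part(parts$clean, "clean")
  artefact <- split_part(parts$artefact, "artefact")
  models <- list(
    clean = train_predict(dplyr::filter(clean, .data$split == "train"),
                          dplyr::filter(clean, .data$split == "test"),
                          schedule, arch, max_train)$model,
    artefact = train_predict(
      dplyr::filter(artefact, .data$split == "train"),
      dplyr::filter(artefact, .data$split == "test"),
      schedule, arch, max_train)$model
  )
  combos <- tidyr::expand_grid(model = c("clean", "artefact"),
                               test = c("clean", "artefact"))
  out <- purrr::pmap(combos, function(model, test) {
    test_set <- dplyr::filter(if (test == "clean") clean else artefact,
                              .data$split == "test")
    scored <- predict(models[[model]], test_set$tile)
    preds <- dplyr::bind_cols(
      test_set[setdiff(names(test_set), "tile")], scored)
    new_experiment(paste0(model, "->", test),
                   upscale_predictions(preds), seed,
                   recipe = list(train_on = model, test_on = test,
                                 schedule = unclass(schedule),
                                 arch = unclass(arch)),
                   model = models[[model]])
  })
  stats::setNames(out, paste0(combos$model, "->", combos$test))
}

#' Coverage-bracket experiment
#'
#' Trains on the clean training subplots, then scores the clean test
#' subplots grouped by their parent plot's coverage bracket (the share
#' of the plot's 16 subplots that are clean), measuring how much
#' usable image area a plot needs before its prediction is reliable.
#'
#' @inheritParams run_baseline
#' @return A list: `reports` (named `weed_experiment`s per scorable
#'   bracket), `membership` (tibble of test plots with brackets).
#' @export
run_coverage <- function(manifest, seed = 1L,
                         schedule = training_schedule(
                           lr0 = 0.03, epochs = 5L, halve_every = 300L, seed = seed),
                         arch = architecture_spec(),
                         max_train = 6000L) {
  stopifnot("quality" %in% names(manifest))
  coverage <- manifest |>
    dplyr::group_by(.data$field_id, .data$plot_col, .data$plot_row) |>
    dplyr::summarise(
      clean_count = sum(.data$quality == "clean"), .groups = "drop") |>
    dplyr::mutate(bracket = coverage_bracket(.data$clean_count))
  clean <- dplyr::filter(manifest, .data$quality == "clean")
  recs <- split_records(clean, test_frac = 0.1, seed = seed)
  tp <- train_predict(dplyr::filter(recs, .data$split == "train"),
                      dplyr::filter(recs, .data$split == "test"),
                      schedule, arch, max_train)
  plots <- upscale_predictions(tp$predictions) |>
    dplyr::left_join(coverage,
                     by = c("field_id", "plot_col", "plot_row"))
  reports <- purrr::map(levels(plots$bracket), function(b) {
    sub <- dplyr::filter(plots, .data$bracket == b,
                         !is.na(.data$predicted))
    if (nrow(sub) < 2 || length(unique(sub$observed)) < 2) return(NULL)
    new_experiment(paste0("coverage ", b), sub, seed,
                   recipe = list(bracket = b,
                                 schedule = unclass(schedule),
                                 arch = unclass(arch)))
  })
  names(reports) <- levels(plots$bracket)
  list(reports = purrr::compact(reports),
       membership = dplyr::select(plots, "field_id", "plot_col",
                                  "plot_row", "clean_count", "bracket"))
}

#' Leave-one-field-out cross-validation
#'
#' The true out-of-sample transferability test: one model per field,
#' trained on the clean subplots of every other field and scored on the
#' held-out field's plots. Metrics are reported at field level as the
#' macro AUC over that field's scorable classes only, because most
#' single fields do not contain all five density states; kappa is
#' deliberately not computed at field level for the same reason.
#'
#' @param manifest A quality-flagged [survey_manifest()].
#' @param seed Training seed.
#' @param schedule,arch Model configuration.
#' @param clean_only Train/test on clean subplots only (default TRUE).
#' @param max_train Cap on training subplots per model.
#' @return A `lofo_result` tibble: field_id, year, week, n_plots,
#'   n_scorable_states, macro AUC (NA when unscorable).
#' @export
run_lofo <- function(manifest, seed = 1L,
                     schedule = training_schedule(
                       lr0 = 0.03, epochs = 5L, halve_every = 300L, seed = seed),
                     arch = architecture_spec(),
                     clean_only = TRUE, max_train = 6000L) {
  fields <- unique(manifest$field_id)
  if (length(fields) < 2) stop("LOFO-CV needs at least 2 fields",
                               call. = FALSE)
  pool <- if (clean_only) {
    dplyr::filter(manifest, .data$quality == "clean")
  } else {
    manifest
  }
  res <- purrr::map(fields, function(fid) {
    train <- dplyr::filter(pool, .data$field_id != fid)
    test <- dplyr::filter(pool, .data$field_id == fid)
    sched <- schedule
    sched$seed <- derive_seed(seed, paste0("lofo:", fid))
    meta <- manifest[manifest$field_id == fid, ][1, ]
    if (nrow(test) == 0) {
      return(tibble::tibble(field_id = fid, year = meta$year,
                            week = meta$week, n_plots = 0L,
                            n_scorable_states = 0L,
                            macro_auc = NA_real_))
    }
    tp <- train_predict(train, test, sched, arch, max_train)
    plots <- dplyr::filter(upscale_predictions(tp$predictions),
                           !is.na(.data$predicted))
    roc <- roc_ovr(as.matrix(plots[state_levels()]), plots$observed)
    tibble::tibble(
      field_id = fid, year = meta$year, week = meta$week,
      n_plots = nrow(plots),
      n_scorable_states = sum(roc$auc$scorable),
      macro_auc = if (any(roc$auc$scorable)) roc$macro_auc else NA_real_
    )
  })
  out <- purrr::list_rbind(res)
  class(out) <- c("lofo_result", class(out))
  attr(out, "seed") <- seed
  out
}

#' Temporal grouping of LOFO-CV results
#'
#' Groups the per-field out-of-sample AUCs by survey year and by week of
#' season (mean and standard error each), and fits two single-predictor
#' ordinary-least-squares regressions of AUC: on year as a categorical
#' factor and on week as a numeric covariate, reporting adjusted R^2 —
#' the check that the time a field was surveyed does not drive its
#' predictability.
#'
#' @param lofo A [run_lofo()] result (needs `year`, `week`,
#'   `macro_auc`).
#' @return A list: `by_year`, `by_week` (tibbles with mean, se, n;
#'   groups of fewer than 2 fields carry `se = NA`), `year_model`,
#'   `week_model` (lm fits) and `summary` (one-row tibble of adjusted
#'   R^2 values).
#' @export
run_temporal <- function(lofo) {
  stopifnot(all(c("year", "week", "macro_auc") %in% names(lofo)))
  dat <- dplyr::filter(lofo, !is.na(.data$macro_auc))
  grp <- function(var) {
    dat |>
      dplyr::group_by(dplyr::across(dplyr::all_of(var))) |>
      dplyr::summarise(
        mean_auc = mean(.data$macro_auc),
        se = ifelse(dplyr::n() >= 2,
                    stats::sd(.data$macro_auc) / sqrt(dplyr::n()),
                    NA_real_),
        n = dplyr::n(), .groups = "drop")
  }
  by_year <- grp("year")
  by_week <- grp("week")
  if (anyNA(by_year$se) || anyNA(by_week$se)) {
    warning("group(s) with fewer than 2 fields: standard error undefined",
            call. = FALSE)
  }
  ym <- stats::lm(macro_auc ~ factor(year), data = dat)
  wm <- stats::lm(macro_auc ~ week, data = dat)
  # a constant response has nothing to explain: report adjusted R^2 = 0
  # rather than the 0/0 the sums of squares would produce
  adj <- function(m) {
    if (stats::var(dat$macro_auc) < 1e-12) 0 else
      summary(m)$adj.r.squared
  }
  list(
    by_year = by_year, by_week = by_week,
    year_model = ym, week_model = wm,
    summary = tibble::tibble(
      adj_r2_year = adj(ym),
      adj_r2_week = adj(wm),
      n_fields = nrow(dat))
  )
}
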