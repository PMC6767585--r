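# One shared strong-signal survey keeps the experiment tests fast; all
# stochastic stages re-derive their own streams from the seeds given.
mf_strong <- small_manifest(n_fields = 6, seed = 11)

fast_schedule <- function(seed) {
  training_schedule(lr0 = 0.05, epochs = 3, halve_every = 200,
                    seed = seed)
}

test_that("the baseline experiment recovers a strong synthetic signal", {
  bl <- run_baseline(mf_strong, seed = 5,
                     schedule = fast_schedule(5), max_train = 4000)
  g <- glance(bl)
  expect_gte(g$macro_auc, 0.85)
  expect_gt(g$kappa, 0)
  # report bookkeeping: seed and config hash recorded
  expect_equal(bl$seed, 5)
  expect_match(bl$config_hash, "^[0-9a-f]+$")
})

test_that("baseline splits are disjoint and reproducible", {
  sp1 <- split_records(mf_strong, test_frac = 0.1, seed = 5)
  sp2 <- split_records(mf_strong, test_frac = 0.1, seed = 5)
  expect_identical(sp1$split, sp2$split)
  ids_train <- sp1$subplot_id[sp1$split == "train"]
  ids_test <- sp1$subplot_id[sp1$split == "test"]
  expect_length(intersect(ids_train, ids_test), 0)
  expect_equal(length(ids_train) + length(ids_test), nrow(mf_strong))
})

test_that("shuffled labels drive the baseline to chance", {
  bl <- run_baseline(mf_strong, seed = 7, schedule = fast_schedule(7),
                     shuffle_labels = TRUE, max_train = 4000)
  expect_lt(abs(glance(bl)$macro_auc - 0.5), 0.07)
})

test_that("the balanced experiment balances every split it trains on", {
  sp <- split_records(mf_strong, test_frac = 0.1, seed = 9)
  train_pool <- dplyr::filter(sp, split == "train")
  bal <- balance_classes(train_pool, seed = 9)
  expect_equal(nrow(bal),
               5 * min(table(train_pool$state)))
  expect_true(all(table(bal$state) == min(table(train_pool$state))))

  rb <- run_balanced(mf_strong, seed = 9, schedule = fast_schedule(9),
                     max_train = 4000)
  expect_s3_class(rb, "weed_experiment")
  # balanced vs unbalanced recover the same strong signal
  bl <- run_baseline(mf_strong, seed = 9, schedule = fast_schedule(9),
                     max_train = 4000)
  expect_lt(abs(glance(rb)$macro_auc - glance(bl)$macro_auc), 0.1)
})

test_that("clean/artefact cross-prediction orders as constructed", {
  reps <- run_clean_artefact(mf_strong, seed = 5,
                             schedule = fast_schedule(5),
                             max_train = 4000)
  expect_named(reps, c("clean->clean", "clean->artefact",
                       "artefact->clean", "artefact->artefact"),
               ignore.order = TRUE)
  # artefact tiles carry no class signal by construction, so a model
  # trained on them cannot beat the clean model on clean data
  expect_gte(glance(reps[["clean->clean"]])$macro_auc,
             glance(reps[["artefact->clean"]])$macro_auc)
  # accounting: confusion totals = scored plots
  for (r in reps) {
    scored <- sum(!is.na(r$plot_predictions$predicted))
    expect_equal(sum(r$metrics$confusion), scored)
  }
})

test_that("coverage brackets partition the test plots", {
  cov <- run_coverage(mf_strong, seed = 5, schedule = fast_schedule(5),
                      max_train = 4000)
  expect_true(all(cov$membership$bracket %in%
                    c("<20%", "20-40%", "40-60%", "60-80%", ">80%")))
  expect_false(anyNA(cov$membership$bracket))
  for (nm in names(cov$reports)) {
    expect_equal(cov$reports[[nm]]$name, paste0("coverage ", nm))
  }
})

test_that("LOFO-CV yields one result per field and respects holdout", {
  lofo <- run_lofo(mf_strong, seed = 5, schedule = fast_schedule(5),
                   max_train = 4000)
  expect_equal(nrow(lofo), length(unique(mf_strong$field_id)))
  expect_setequal(lofo$field_id, unique(mf_strong$field_id))
  ok <- !is.na(lofo$macro_auc)
  expect_true(all(lofo$macro_auc[ok] >= 0 & lofo$macro_auc[ok] <= 1))
  # strong shared signal transfers across fields
  expect_gte(mean(lofo$macro_auc, na.rm = TRUE), 0.8)
})

test_that("a single-class field is reported unscorable, not dropped", {
  # restrict one field's records to a single state
  mf2 <- mf_strong
  f1 <- unique(mf2$field_id)[1]
  mf2 <- dplyr::bind_rows(
    dplyr::filter(mf2, field_id != f1),
    dplyr::filter(mf2, field_id == f1, state == "Low"))
  lofo <- run_lofo(mf2, seed = 5, schedule = fast_schedule(5),
                   max_train = 3000)
  row1 <- lofo[lofo$field_id == f1, ]
  expect_equal(row1$n_scorable_states, 0L)
  expect_true(is.na(row1$macro_auc))
})

test_that("temporal grouping and regressions behave at fixed points", {
  # constant AUC: nothing to explain
  lofo_const <- tibble::tibble(
    field_id = sprintf("F%02d", 1:12),
    year = rep(c(2016L, 2017L), each = 6),
    week = rep(1:6, 2), n_plots = 40L, n_scorable_states = 5L,
    macro_auc = 0.7)
  tp <- run_temporal(lofo_const)
  expect_lte(tp$summary$adj_r2_year, 0)
  expect_lte(tp$summary$adj_r2_week, 0)
  expect_true(all(tp$by_year$mean_auc == 0.7))

  # perfectly linear in week
  lofo_lin <- lofo_const
  lofo_lin$macro_auc <- lofo_lin$week / 10
  tp2 <- run_temporal(lofo_lin)
  expect_equal(summary(tp2$week_model)$r.squared, 1)

  # adjusted R^2 matches its closed form on a 10-point set
  withr::with_seed(71, {
    lofo10 <- tibble::tibble(
      field_id = sprintf("F%02d", 1:10),
      year = rep(c(2016L, 2017L), each = 5),
      week = rep(1:5, 2), n_plots = 40L, n_scorable_states = 5L,
      macro_auc = runif(10, 0.4, 0.9))
  })
  tp3 <- run_temporal(lofo10)
  r2 <- summary(tp3$week_model)$r.squared
  expect_equal(tp3$summary$adj_r2_week,
               1 - (1 - r2) * (10 - 1) / (10 - 1 - 1),
               tolerance = 1e-12)

  # a singleton group flags its undefined standard error
  expect_warning(run_temporal(lofo_const[c(1, 2, 3, 7), ]),
                 "standard error undefined")
})
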