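test_that("generator configuration is validated", {
  expect_error(field_config(mixture = c(0.5, 0.5, 0, 0, 0.1)), "sum to 1")
  expect_error(field_config(mixture = c(-0.1, 0.6, 0.2, 0.2, 0.1)),
               "non-negative")
  expect_error(field_config(plots_per_field = 0), "positive integer")
  expect_error(field_config(autocorr_length = -1), ">= 0")
  expect_error(field_config(noise_sd = -0.1), ">= 0")
  expect_error(field_config(artefact_types = "barn"), "unknown artefact")
  expect_error(generate_survey(field_config(), 5, years = integer(0)),
               "non-empty")
})

test_that("density states are calibrated to the configured mixture", {
  # coarse pixels keep 50 fields cheap; 50 x 110 = 5500 plots
  mix <- c(0.145, 0.531, 0.173, 0.082, 0.069)
  cfg <- field_config(gsd_cm = 500, artefact_density = 0, seed = 77)
  states <- unlist(lapply(1:50, function(i) {
    as.integer(generate_field(cfg, paste0("C", i))$observations$state)
  })) - 1L
  n <- length(states)
  expect_equal(n, 5500)
  freq <- tabulate(states + 1L, 5) / n
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(freq - mix) <= 3 * se + 1 / 110))
})

test_that("a degenerate mixture produces only weed-free wheat", {
  cfg <- field_config(mixture = c(1, 0, 0, 0, 0), plots_per_field = 12,
                      gsd_cm = 250, artefact_density = 0,
                      noise_sd = 0.005, seed = 5)
  f <- generate_field(cfg, "D")
  expect_true(all(f$observations$state == "Absent"))
  # no weed clusters: every plot's mean GNDVI sits at the wheat level
  g <- gndvi(f$scene)
  plots <- extract_plots(g, f$observations, f$scene)
  mu <- vapply(plots$tile, mean, numeric(1))
  expect_true(all(abs(mu - cfg$wheat_gndvi_mean) < 0.05))
})

test_that("spatial autocorrelation increases like-state adjacency", {
  # brute-force join-count statistic over the plot grid
  join_count <- function(states) {
    sum(states[-1, ] == states[-nrow(states), ]) +
      sum(states[, -1] == states[, -ncol(states)])
  }
  total <- function(len, seed) {
    cfg <- field_config(autocorr_length = len, gsd_cm = 500,
                        artefact_density = 0, seed = seed)
    sum(vapply(1:60, function(i) {
      f <- generate_field(cfg, paste0("A", i))
      obs <- f$observations
      g <- matrix(0L, max(obs$plot_row), max(obs$plot_col))
      g[cbind(obs$plot_row, obs$plot_col)] <- as.integer(obs$state)
      join_count(g)
    }, numeric(1)))
  }
  expect_gt(total(5, seed = 13), total(0, seed = 13))
})

test_that("weed signal rises with density state under the defaults", {
  cfg <- field_config(gsd_cm = 125, artefact_density = 0, seed = 21)
  obs_mu <- list()
  for (i in 1:6) {
    f <- generate_field(cfg, paste0("S", i))
    g <- gndvi(f$scene)
    plots <- extract_plots(g, f$observations, f$scene)
    obs_mu[[i]] <- tibble::tibble(
      state = plots$state, mu = vapply(plots$tile, mean, numeric(1)))
  }
  mu_by_state <- dplyr::bind_rows(obs_mu) |>
    dplyr::group_by(state) |>
    dplyr::summarise(mu = mean(mu), .groups = "drop")
  expect_true(all(diff(mu_by_state$mu) > 0))
})

test_that("artefact masks are sound and aligned", {
  cfg <- field_config(plots_per_field = 12, gsd_cm = 125,
                      artefact_density = 6, seed = 9)
  f <- generate_field(cfg, "M")
  expect_identical(dim(f$mask$mask), dim(f$scene$bands$green))
  # every recorded object contributed flagged pixels, and the flagged
  # count never exceeds the per-object total (objects may overlap)
  expect_true(all(f$mask$objects$n_pixels > 0))
  expect_lte(sum(f$mask$mask), sum(f$mask$objects$n_pixels))
  expect_gt(sum(f$mask$mask), 0)

  # no artefacts configured -> empty mask
  f0 <- generate_field(field_config(plots_per_field = 12, gsd_cm = 125,
                                    artefact_density = 0, seed = 9), "Z")
  expect_equal(sum(f0$mask$mask), 0)
  expect_equal(nrow(f0$mask$objects), 0)
})

test_that("surveys assign every field one (year, week) cell, round-robin", {
  cfg <- field_config(plots_per_field = 4, gsd_cm = 500, seed = 3)
  sv <- generate_survey(cfg, 81, years = c(2016, 2017),
                        weeks_per_year = 6, year_counts = c(38, 43))
  expect_equal(nrow(sv$fields), 81)
  expect_equal(as.integer(table(sv$fields$year)), c(38, 43))
  wk <- table(sv$fields$year, sv$fields$week)
  expect_true(all(wk > 0))
  expect_true(all(sv$fields$week %in% 1:6))
  # one metadata row per field; observations carry the assignment
  expect_equal(anyDuplicated(sv$fields$field_id), 0)
  m <- dplyr::distinct(sv$observations, field_id, year, week)
  expect_equal(nrow(m), 81)

  sv1 <- generate_survey(cfg, 1)
  expect_equal(nrow(sv1$fields), 1)
  expect_length(sv1$scenes, 1)
})

test_that("identical config and seed reproduce the survey byte-for-byte", {
  cfg <- field_config(plots_per_field = 12, gsd_cm = 250, seed = 17)
  sv1 <- generate_survey(cfg, 3)
  sv2 <- generate_survey(cfg, 3)
  expect_identical(sv1$observations, sv2$observations)
  expect_identical(sv1$scenes, sv2$scenes)
  expect_identical(sv1$masks, sv2$masks)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_truth_csv(sv1$observations, f1)
  write_truth_csv(sv2$observations, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("per-field dataset shift changes fields, not within-field labels", {
  cfg <- example_config("dataset-shift", seed = 31, plots_per_field = 12,
                        gsd_cm = 250)
  f1 <- generate_field(cfg, "X1")
  f2 <- generate_field(cfg, "X2")
  # same config, different fields: different appearance
  expect_false(identical(f1$scene$bands$nir, f2$scene$bands$nir))
  # observations remain a valid state table
  expect_true(all(!is.na(f1$observations$state)))
})
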