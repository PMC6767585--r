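make_records <- function(counts) {
  tibble::tibble(
    id = seq_len(sum(counts)),
    state = as_density_state(rep(0:4, times = counts))
  )
}

test_that("balancing downsamples every class to the minimum count", {
  rec <- make_records(c(10, 53, 17, 8, 7))
  bal <- balance_classes(rec, seed = 3)
  expect_equal(nrow(bal), 35)
  expect_true(all(table(bal$state) == 7))
  expect_true(all(bal$id %in% rec$id))

  # idempotent on class counts when already balanced
  bal2 <- balance_classes(bal, seed = 4)
  expect_equal(sort(table(bal2$state)), sort(table(bal$state)))

  # deterministic under seed
  expect_identical(balance_classes(rec, seed = 3), bal)
  expect_false(identical(balance_classes(rec, seed = 99)$id, bal$id))
})

test_that("balancing errors name the absent class", {
  rec <- make_records(c(5, 5, 5, 5, 0))
  expect_error(balance_classes(rec), "VeryHigh")
})

test_that("oracle quality flags follow mask overlap thresholds", {
  # one-plot scene, 8 px; artefact mask covers the left half
  px <- 8
  mask <- matrix(FALSE, px, px)
  mask[, 1:4] <- TRUE
  am <- structure(list(mask = mask, object_id = (mask) * 1L,
                       objects = tibble::tibble(object = 1L,
                                                type = "tree",
                                                n_pixels = sum(mask))),
                  class = "artefact_mask")
  scene <- make_scene(green = matrix(0.5, px, px), gsd_cm = 2000 / px,
                      grid_cols = 1, grid_rows = 1, field_id = "Q")
  plots <- tibble::tibble(field_id = "Q", plot_col = 1L, plot_row = 1L,
                          state = as_density_state(0L),
                          tile = list(matrix(0.2, px, px)))
  mf <- subsample_plots(plots)
  out <- flag_quality(mf, masks = list(Q = am), scenes = list(Q = scene))
  # left two subplot columns are fully masked, right two untouched
  expect_true(all(out$quality[out$pos_col <= 2] == "artefact"))
  expect_true(all(out$quality[out$pos_col >= 3] == "clean"))

  # full coverage -> all 16 artefact
  am2 <- am; am2$mask[] <- TRUE
  out2 <- flag_quality(mf, masks = list(Q = am2), scenes = list(Q = scene))
  expect_true(all(out2$quality == "artefact"))
})

test_that("an almost fully contaminated plot keeps only the named clean subplots", {
  # artefacts everywhere except subplot positions (1,2) and (1,3):
  # the canonical pure-wheat remnant pattern
  px <- 16
  br <- weedmapr:::subplot_breaks(px)
  mask <- matrix(TRUE, px, px)
  for (pr in c(2L, 3L)) {  # pos_col = 1, pos_row = 2 and 3
    rows <- (px - br[pr, "end"] + 1L):(px - br[pr, "start"] + 1L)
    mask[rows, br[1, "start"]:br[1, "end"]] <- FALSE
  }
  am <- structure(list(mask = mask, object_id = mask * 1L,
                       objects = tibble::tibble(object = 1L,
                                                type = "hedgerow",
                                                n_pixels = sum(mask))),
                  class = "artefact_mask")
  scene <- make_scene(green = matrix(0.5, px, px), gsd_cm = 2000 / px,
                      grid_cols = 1, grid_rows = 1, field_id = "W")
  plots <- tibble::tibble(field_id = "W", plot_col = 1L, plot_row = 1L,
                          state = as_density_state(4L),
                          tile = list(matrix(0.2, px, px)))
  out <- flag_quality(subsample_plots(plots),
                      masks = list(W = am), scenes = list(W = scene))
  clean <- out[out$quality == "clean", c("pos_col", "pos_row")]
  expect_equal(nrow(clean), 2)
  expect_setequal(paste(clean$pos_col, clean$pos_row),
                  c("1 2", "1 3"))
})

test_that("quality labels can come from a file and strictness is enforced", {
  withr::with_seed(41, {
    plots <- tibble::tibble(field_id = "L", plot_col = 1L, plot_row = 1L,
                            state = as_density_state(1L),
                            tile = list(matrix(rnorm(64), 8, 8)))
  })
  mf <- subsample_plots(plots)
  labels <- tibble::tibble(subplot_id = mf$subplot_id,
                           quality = rep(c("clean", "artefact"), 8))
  out <- flag_quality(mf, labels = labels)
  expect_equal(sum(out$quality == "clean"), 8)
  expect_error(flag_quality(mf, labels = labels[-1, ]), "unlabelled")

  parts <- partition_quality(out)
  expect_equal(nrow(parts$clean) + nrow(parts$artefact), nrow(mf))
  expect_length(intersect(parts$clean$subplot_id,
                          parts$artefact$subplot_id), 0)
})

test_that("coverage brackets partition 0-16 with the stated boundaries", {
  expect_equal(as.character(coverage_bracket(3)), "<20%")
  expect_equal(as.character(coverage_bracket(12)), "60-80%")
  expect_equal(as.character(coverage_bracket(13)), ">80%")
  expect_equal(as.character(coverage_bracket(16)), ">80%")

  all_counts <- coverage_bracket(0:16)
  expect_false(anyNA(all_counts))
  # monotone in the clean count
  expect_true(all(diff(as.integer(all_counts)) >= 0))
  expect_error(coverage_bracket(17), "0-16")
})

test_that("record splitting is disjoint, sized and reproducible", {
  rec <- make_records(c(40, 120, 60, 30, 30))
  sp <- split_records(rec, test_frac = 0.1, val_frac = 0.1, seed = 9)
  expect_equal(nrow(sp), nrow(rec))
  expect_equal(sum(sp$split == "test"), 28)
  expect_equal(sum(sp$split == "validation"), 28)
  # stratification: each class contributes ~10% to test
  per_class <- table(sp$state[sp$split == "test"])
  expect_equal(as.integer(per_class), c(4, 12, 6, 3, 3))
  expect_identical(split_records(rec, test_frac = 0.1, val_frac = 0.1,
                                 seed = 9),
                   sp)
})
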