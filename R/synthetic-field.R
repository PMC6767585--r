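#' Configuration for the synthetic multispectral field generator
#'
#' Describes the statistical structure of the scenes the generator
#' emulates: an ~8 ha wheat field surveyed at 20 x 20 m plot resolution,
#' five ordinal black-grass density states with a strongly imbalanced
#' class mixture, spatially aggregated weed patches, partially
#' overlapping GNDVI signatures for wheat and weed pixels, and non-crop
#' artefacts (trees, tramlines, hedgerows) that contaminate plots.
#'
#' @param plots_per_field Number of 20 x 20 m plots per field (default
#'   110, the survey average).
#' @param mixture Length-5 probability vector over the density states
#'   Absent..VeryHigh. Default is the survey's observed imbalance:
#'   14.5, 53.1, 17.3, 8.2 and 6.9 per cent.
#' @param autocorr_length Spatial autocorrelation length of the latent
#'   density field, in plots (Gaussian smoothing sd). 0 gives spatially
#'   independent states.
#' @param gsd_cm Ground sample distance, cm per pixel. 8 cm (the surveys'
#'   mean of 8.27 cm) gives 250 px plot sides; coarser values give the
#'   small tiles used for desk-scale model fitting.
#' @param wheat_gndvi_mean,wheat_gndvi_sd GNDVI distribution of the wheat
#'   background.
#' @param weed_gndvi_mean Length-4 vector: mean GNDVI of weed pixels in
#'   states Low..VeryHigh (non-decreasing, so denser states carry a
#'   stronger signal).
#' @param weed_gndvi_sd Spread of weed-pixel GNDVI around its state mean.
#' @param weed_fraction Length-4 vector: fraction of a plot's pixels
#'   covered by weed patches in states Low..VeryHigh, scaled with the
#'   plant-count range midpoints.
#' @param weed_patch_scale Autocorrelation length of within-plot weed
#'   patches, as a fraction of the plot side.
#' @param artefact_density Expected number of artefact objects per field
#'   (Poisson).
#' @param artefact_types Artefact types to draw from.
#' @param noise_sd Sensor noise sd added per band (reflectance units).
#' @param field_shift_sd Between-field sd of an additive GNDVI shift
#'   applied to the whole field (wheat and weed alike). 0 means all
#'   fields share one distribution; positive values create dataset
#'   (covariate) shift between fields.
#' @param field_contrast_sd Between-field sd of a multiplicative factor
#'   on the weed-wheat GNDVI contrast.
#' @param field_contrast_flip Probability that a field's weed-wheat
#'   contrast is sign-inverted (weed darker than wheat in the index).
#' @param field_state_permute If TRUE, each field maps the five density
#'   states to a random permutation of the five signal profiles (no
#'   weed, and the four weed coverage/contrast levels). This makes the
#'   class-conditional signal disjoint between fields: within any one
#'   field the states are separable, but no field-invariant mapping from
#'   tile appearance to state exists, so models transfer wrongly to
#'   unseen fields while an in-sample model can exploit each training
#'   field's own mapping (via `field_shift_sd` offsets).
#' @param seed Master seed; every stochastic draw in a run derives its
#'   own stream from it.
#' @return A `field_config` list, validated.
#' @export
field_config <- function(plots_per_field = 110,
                         mixture = c(0.145, 0.531, 0.173, 0.082, 0.069),
                         autocorr_length = 2,
                         gsd_cm = 8,
                         wheat_gndvi_mean = 0.45,
                         wheat_gndvi_sd = 0.07,
                         weed_gndvi_mean = c(0.62, 0.66, 0.70, 0.74),
                         weed_gndvi_sd = 0.05,
                         weed_fraction = c(0.05, 0.15, 0.35, 0.60),
                         weed_patch_scale = 0.10,
                         artefact_density = 4,
                         artefact_types = c("tree", "tramline", "hedgerow"),
                         noise_sd = 0.02,
                         field_shift_sd = 0,
                         field_contrast_sd = 0,
                         field_contrast_flip = 0,
                         field_state_permute = FALSE,
                         seed = 1L) {
  stopifnot(field_contrast_flip >= 0, field_contrast_flip <= 1,
            is.logical(field_state_permute))
  if (length(plots_per_field) != 1 || plots_per_field < 1 ||
      plots_per_field != round(plots_per_field)) {
    stop("plots_per_field must be a positive integer", call. = FALSE)
  }
  if (length(mixture) != 5 || any(mixture < 0)) {
    stop("mixture must be 5 non-negative probabilities", call. = FALSE)
  }
  if (abs(sum(mixture) - 1) > 1e-9) {
    stop("mixture must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (autocorr_length < 0) stop("autocorr_length must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (gsd_cm <= 0) stop("gsd_cm must be positive", call. = FALSE)
  stopifnot(length(weed_gndvi_mean) == 4, length(weed_fraction) == 4,
            all(weed_fraction >= 0), all(weed_fraction <= 1))
  bad <- setdiff(artefact_types, c("tree", "tramline", "hedgerow"))
  if (length(bad)) stop("unknown artefact type(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(as.list(environment()), class = "field_config")
}

#' Ready-made generator profiles for the experiment suite
#'
#' Three documented study conditions at desk scale (48 plots per field,
#' 62.5 cm GSD giving 32 px plots and 8 px subplots, so the whole
#' experiment suite trains in minutes on one CPU):
#'
#' * `"realistic"` — the package defaults: heavy class imbalance,
#'   strongly overlapping wheat/weed GNDVI distributions and sparse weed
#'   cover in the Low state, so subplot-level discrimination is genuinely
#'   hard (as it is in real surveys).
#' * `"strong-signal"` — weed coverage and GNDVI contrast raised until
#'   the states are separable by construction (non-overlapping per-state
#'   index distributions at subplot level); used to verify that the
#'   pipeline recovers a signal it is guaranteed to contain, with every
#'   field drawn from one shared distribution.
#' * `"dataset-shift"` — the strong-signal condition plus per-field
#'   random shifts of the whole GNDVI field and per-field rescaling
#'   (occasionally sign-flipping) of the weed-wheat contrast, creating
#'   the between-field covariate shift that breaks model transfer.
#'
#' @param profile One of `"realistic"`, `"strong-signal"`,
#'   `"dataset-shift"`.
#' @param seed Master seed stored in the config.
#' @param ... Overrides passed on to [field_config()].
#' @return A `field_config`.
#' @export
example_config <- function(profile = c("realistic", "strong-signal",
                                       "dataset-shift"),
                           seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- list(plots_per_field = 48, gsd_cm = 62.5, seed = seed)
  extra <- switch(profile,
    "realistic" = list(),
    "strong-signal" = list(
      weed_fraction = c(0.35, 0.55, 0.75, 0.92),
      weed_gndvi_mean = c(0.60, 0.70, 0.80, 0.90),
      weed_gndvi_sd = 0.03, wheat_gndvi_sd = 0.05,
      artefact_density = 3, noise_sd = 0.01),
    "dataset-shift" = list(
      weed_fraction = c(0.35, 0.55, 0.75, 0.92),
      weed_gndvi_mean = c(0.60, 0.70, 0.80, 0.90),
      weed_gndvi_sd = 0.03, wheat_gndvi_sd = 0.05,
      artefact_density = 3, noise_sd = 0.01,
      field_shift_sd = 0.15, field_state_permute = TRUE)
  )
  args <- utils::modifyList(c(base, extra), list(...))
  do.call(field_config, args)
}

# Near-square plot grid for n plots: rows = largest divisor <= sqrt(n).
grid_dims <- function(n) {
  r <- max(Filter(function(d) n %% d == 0, seq_len(floor(sqrt(n)))))
  c(cols = as.integer(n / r), rows = as.integer(r))
}

#' Generate one synthetic field
#'
#' Draws a spatially autocorrelated latent field over the plot grid,
#' thresholds it at the mixture quantiles to assign each plot an ordinal
#' density state, paints per-plot GNDVI-bearing band rasters (wheat
#' background plus clustered weed patches whose coverage and mean index
#' rise with state), stamps artefact objects (trees, tramlines,
#' hedgerows) over the bands, and records every artefact pixel in a mask.
#'
#' @param config A [field_config()].
#' @param field_id Unique field identifier.
#' @param year,week Survey metadata copied onto the scene and
#'   observations (optional at field level).
#' @return A list with components `scene` ([band_scene()]),
#'   `observations` (tibble: field_id, plot_col, plot_row, state, year,
#'   week) and `mask` (an `artefact_mask`).
#' @examples
#' f <- generate_field(field_config(plots_per_field = 12, gsd_cm = 250),
#'                     "demo")
#' table(f$observations$state)
#' @export
generate_field <- function(config, field_id, year = NA_integer_,
                           week = NA_integer_) {
  stopifnot(inherits(config, "field_config"))
  with_seed(derive_seed(config$seed, paste0("field:", field_id)), {
    g <- grid_dims(config$plots_per_field)
    states <- draw_states(g, config)
    px <- as.integer(round(2000 / config$gsd_cm))  # 20 m plot side in px
    if (px < 4) stop("gsd_cm too coarse: plots smaller than 4 px",
                     call. = FALSE)
    H <- g[["rows"]] * px
    W <- g[["cols"]] * px

    # per-field dataset-shift draws (0-sd means every field is identical
    # in distribution)
    shift <- stats::rnorm(1, 0, config$field_shift_sd)
    contrast <- stats::rnorm(1, 1, config$field_contrast_sd)
    if (stats::runif(1) < config$field_contrast_flip) contrast <- -contrast
    # state -> signal-profile map (0 = no weed, 1..4 = weed levels);
    # identity unless per-field permutation shift is enabled
    perm <- if (isTRUE(config$field_state_permute)) {
      sample(0:4)
    } else {
      0:4
    }

    v <- matrix(0, H, W)       # target GNDVI
    bright <- matrix(0.7, H, W) # f_n + f_g
    for (r in seq_len(g[["rows"]])) {
      for (cc in seq_len(g[["cols"]])) {
        rows <- ((g[["rows"]] - r) * px + 1):((g[["rows"]] - r + 1) * px)
        cols <- ((cc - 1) * px + 1):(cc * px)
        v[rows, cols] <- paint_plot(states[r, cc], px, config, shift,
                                    contrast, perm)
      }
    }
    art <- stamp_artefacts(v, bright, H, W, px, config)
    v <- art$v; bright <- art$bright

    f_n <- clamp01(bright * (1 + v) / 2 +
                     matrix(stats::rnorm(length(v), 0, config$noise_sd), H, W))
    f_g <- clamp01(bright * (1 - v) / 2 +
                     matrix(stats::rnorm(length(v), 0, config$noise_sd), H, W))
    f_r <- clamp01(0.05 + 0.10 * (1 - v) +
                     matrix(stats::rnorm(length(v), 0, config$noise_sd), H, W))
    f_re <- clamp01((f_n + f_r) / 2 +
                      matrix(stats::rnorm(length(v), 0, config$noise_sd), H, W))

    scene <- band_scene(field_id, green = f_g, red = f_r, rededge = f_re,
                        nir = f_n, gsd_cm = config$gsd_cm,
                        grid_cols = g[["cols"]], grid_rows = g[["rows"]],
                        year = year, week = week)
    obs <- tidyr::expand_grid(plot_row = seq_len(g[["rows"]]),
                              plot_col = seq_len(g[["cols"]]))
    obs <- tibble::tibble(
      field_id = as.character(field_id),
      plot_col = obs$plot_col, plot_row = obs$plot_row,
      state = as_density_state(states[cbind(obs$plot_row, obs$plot_col)]),
      year = as.integer(year), week = as.integer(week)
    )
    list(scene = scene, observations = obs, mask = art$mask)
  })
}

# Latent Gaussian field over the plot grid -> ordinal states via rank
# transform and mixture-quantile thresholds. plot_row 1 = bottom of grid;
# matrix row r holds plot_row r.
draw_states <- function(g, config) {
  z <- matrix(stats::rnorm(g[["rows"]] * g[["cols"]]), g[["rows"]],
              g[["cols"]])
  z <- smooth_gaussian(z, config$autocorr_length)
  u <- (rank(z, ties.method = "first") - 0.5) / length(z)
  matrix(findInterval(u, cumsum(config$mixture)[1:4]), g[["rows"]],
         g[["cols"]])
}

# Target-GNDVI tile for one plot: wheat texture plus, for weed-bearing
# states, clustered patches thresholded from smoothed noise at the
# configured coverage fraction.
paint_plot <- function(state, px, config, shift, contrast, perm = 0:4) {
  wheat <- config$wheat_gndvi_mean + shift +
    config$wheat_gndvi_sd * smooth_unit_noise(px, max(1, 0.03 * px))
  si <- perm[state + 1L]  # signal profile: 0 = pure wheat, 1..4 = weed
  if (si == 0) return(wheat)
  frac <- config$weed_fraction[si]
  if (frac == 0) return(wheat)
  patch <- smooth_unit_noise(px, config$weed_patch_scale * px)
  mask <- patch >= stats::quantile(patch, 1 - frac)
  delta <- contrast * (config$weed_gndvi_mean[si] -
                         config$wheat_gndvi_mean)
  weed <- config$wheat_gndvi_mean + shift + delta +
    config$weed_gndvi_sd * smooth_unit_noise(px, max(1, 0.03 * px))
  wheat[mask] <- weed[mask]
  wheat
}

# Smoothed white noise standardised to unit sd (dimensionless texture).
smooth_unit_noise <- function(px, sigma) {
  z <- smooth_gaussian(matrix(stats::rnorm(px * px), px, px), sigma)
  s <- stats::sd(z)
  if (s == 0) return(z * 0)
  (z - mean(z)) / s
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Stamp artefact objects over the target-GNDVI and brightness canvases;
# returns updated canvases plus the pixel mask with per-object labels.
stamp_artefacts <- function(v, bright, H, W, px, config) {
  n_art <- stats::rpois(1, config$artefact_density)
  mask <- matrix(FALSE, H, W)
  ids <- matrix(0L, H, W)
  objs <- list()
  if (n_art > 0) {
    types <- sample(config$artefact_types, n_art, replace = TRUE)
    for (i in seq_len(n_art)) {
      m <- switch(types[i],
        tree = disc_blob(H, W, px),
        hedgerow = edge_stripe(H, W, px),
        tramline = tram_stripe(H, W, px)
      )
      if (types[i] == "tramline") {
        v[m] <- 0.05; bright[m] <- 0.15
      } else {
        v[m] <- 0.85; bright[m] <- 0.9  # dense canopy: high NIR, low green
      }
      mask[m] <- TRUE
      ids[m] <- i
      objs[[i]] <- tibble::tibble(object = i, type = types[i],
                                  n_pixels = sum(m))
    }
  }
  structure_mask <- structure(
    list(mask = mask, object_id = ids,
         objects = if (length(objs)) purrr::list_rbind(objs) else
           tibble::tibble(object = integer(), type = character(),
                          n_pixels = integer())),
    class = "artefact_mask"
  )
  list(v = v, bright = bright, mask = structure_mask)
}

# Irregular canopy blob: union of a few overlapping discs.
disc_blob <- function(H, W, px) {
  m <- matrix(FALSE, H, W)
  cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
  for (k in seq_len(3)) {
    r <- stats::runif(1, 0.25, 0.6) * px
    oy <- cy + stats::rnorm(1, 0, 0.3 * px)
    ox <- cx + stats::rnorm(1, 0, 0.3 * px)
    yy <- outer(seq_len(H) - oy, rep(1, W))
    xx <- outer(rep(1, H), seq_len(W) - ox)
    m <- m | (yy^2 + xx^2 <= r^2)
  }
  m
}

# Hedgerow: stripe along one randomly chosen scene edge.
edge_stripe <- function(H, W, px) {
  m <- matrix(FALSE, H, W)
  th <- max(2L, as.integer(round(stats::runif(1, 0.3, 0.6) * px)))
  side <- sample(c("top", "bottom", "left", "right"), 1)
  switch(side,
    top = { m[seq_len(th), ] <- TRUE },
    bottom = { m[(H - th + 1):H, ] <- TRUE },
    left = { m[, seq_len(th)] <- TRUE },
    right = { m[, (W - th + 1):W] <- TRUE }
  )
  m
}

# Tramline: thin straight low-reflectance stripe across the whole scene.
tram_stripe <- function(H, W, px) {
  m <- matrix(FALSE, H, W)
  wdt <- max(1L, as.integer(round(0.06 * px)))
  if (stats::runif(1) < 0.5) {
    at <- sample.int(H - wdt + 1L, 1)
    m[at:(at + wdt - 1L), ] <- TRUE
  } else {
    at <- sample.int(W - wdt + 1L, 1)
    m[, at:(at + wdt - 1L)] <- TRUE
  }
  m
}

#' @export
print.artefact_mask <- function(x, ...) {
  cat("<artefact_mask>", nrow(x$objects), "object(s),",
      sum(x$mask), "masked px of", length(x$mask), "\n")
  invisible(x)
}

#' Generate a multi-field synthetic survey
#'
#' Generates `n_fields` fields and assigns each to a (year, week) cell
#' round-robin, emulating a two-year campaign of six-week field seasons
#' with the same number of fields visited each week.
#'
#' @param config A [field_config()].
#' @param n_fields Number of fields (>= 1).
#' @param years Survey years (non-empty).
#' @param weeks_per_year Weeks in each field season (default 6).
#' @param year_counts Optional field count per year (sums to `n_fields`);
#'   defaults to an even split with remainders to the later years.
#' @return A `weed_survey`: list with `fields` (tibble field_id, year,
#'   week), `scenes` and `masks` (named lists), `observations` (one
#'   tibble over all fields) and `config`.
#' @export
generate_survey <- function(config, n_fields, years = c(2016L, 2017L),
                            weeks_per_year = 6L, year_counts = NULL) {
  stopifnot(inherits(config, "field_config"))
  if (n_fields < 1) stop("n_fields must be >= 1", call. = FALSE)
  if (length(years) == 0) stop("years must be non-empty", call. = FALSE)
  if (is.null(year_counts)) {
    base <- n_fields %/% length(years)
    year_counts <- rep(base, length(years))
    extra <- n_fields - sum(year_counts)
    if (extra > 0) {
      year_counts[seq(length(years) - extra + 1, length(years))] <-
        year_counts[seq(length(years) - extra + 1, length(years))] + 1L
    }
  }
  if (sum(year_counts) != n_fields) {
    stop("year_counts must sum to n_fields", call. = FALSE)
  }
  fields <- tibble::tibble(
    field_id = sprintf("F%03d", seq_len(n_fields)),
    year = rep(as.integer(years), times = year_counts)
  )
  fields <- fields |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(week = as.integer((dplyr::row_number() - 1L) %%
                                      weeks_per_year + 1L)) |>
    dplyr::ungroup()

  gen <- purrr::pmap(fields, function(field_id, year, week) {
    generate_field(config, field_id, year = year, week = week)
  })
  out <- list(
    fields = fields,
    scenes = stats::setNames(purrr::map(gen, "scene"), fields$field_id),
    masks = stats::setNames(purrr::map(gen, "mask"), fields$field_id),
    observations = purrr::list_rbind(purrr::map(gen, "observations")),
    config = config
  )
  class(out) <- "weed_survey"
  out
}

#' @export
print.weed_survey <- function(x, ...) {
  cat("<weed_survey>", nrow(x$fields), "fields,",
      nrow(x$observations), "plots; years",
      paste(unique(x$fields$year), collapse = "/"), "\n")
  print(table(x$observations$state))
  invisible(x)
}
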