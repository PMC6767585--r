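#' Architecture presets for the density classifier
#'
#' Both presets share the same topology — stacked 3x3 convolution +
#' ReLU + 2x2 max-pool blocks feeding a fully connected ReLU layer and
#' a 5-way softmax head — the four canonical CNN components
#' (convolution, non-linearity, pooling, fully connected softmax
#' classifier). `"small-cnn"` (default) is sized to train in seconds on
#' a CPU; `"googlenet-style"` is a wider variant of the same blocks,
#' echoing the large inception-style network the original analysis
#' trained from scratch, without attempting parameter-for-parameter
#' fidelity. Input is a single-channel GNDVI tile, resized to
#' `input_side` by nearest neighbour so index values are preserved.
#'
#' @param preset `"small-cnn"` or `"googlenet-style"`.
#' @param input_side Tile side in pixels fed to the network (must be
#'   divisible by 4).
#' @param conv1,conv2 Filter counts of the two convolution blocks.
#' @param hidden Width of the fully connected layer.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(preset = c("small-cnn", "googlenet-style"),
                              input_side = NULL, conv1 = NULL,
                              conv2 = NULL, hidden = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    "small-cnn" = list(input_side = 16L, conv1 = 8L, conv2 = 16L,
                       hidden = 32L),
    "googlenet-style" = list(input_side = 32L, conv1 = 16L, conv2 = 32L,
                             hidden = 64L)
  )
  out <- list(preset = preset,
              input_side = as.integer(input_side %||% def$input_side),
              conv1 = as.integer(conv1 %||% def$conv1),
              conv2 = as.integer(conv2 %||% def$conv2),
              hidden = as.integer(hidden %||% def$hidden),
              channels = 1L, n_classes = 5L)
  if (out$input_side %% 4 != 0 || out$input_side < 4) {
    stop("input_side must be a positive multiple of 4", call. = FALSE)
  }
  structure(out, class = "architecture_spec")
}

#' Training schedule for the density classifier
#'
#' The optimizer is stochastic gradient descent with momentum under a
#' step-halving schedule: the rate starts at `lr0` and halves every
#' `halve_every` steps (one step = one minibatch), with categorical
#' cross-entropy loss and a default batch size of 128 — the training
#' recipe the original analysis settled on (rate 0.1 halving every
#' 32,000 steps). Desk-scale runs shorten `halve_every` in proportion
#' to their much smaller step budget.
#'
#' @param lr0 Initial step size (> 0).
#' @param halve_every Steps between halvings of the rate (> 0).
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Passes over the training set.
#' @param momentum Momentum coefficient.
#' @param seed Seed for weight initialisation and shuffling.
#' @return A `training_schedule` list.
#' @export
training_schedule <- function(lr0 = 0.1, halve_every = 32000L,
                              batch_size = 128L, epochs = 10L,
                              momentum = 0.9, seed = 1L) {
  stopifnot(lr0 > 0, halve_every >= 1, batch_size >= 1, epochs >= 1,
            momentum >= 0, momentum < 1)
  structure(list(lr0 = lr0, halve_every = as.integer(halve_every),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 seed = as.integer(seed)),
            class = "training_schedule")
}

# Stack a list of tiles (or an already-stacked matrix) into the n x side^2
# input matrix: nearest-neighbour resize, undefined (NA) pixels -> 0.
stack_tiles <- function(tiles, side) {
  if (is.matrix(tiles) && !is.list(tiles)) return(tiles)
  X <- t(vapply(tiles, function(m) {
    m <- resize_nn(m, side)
    m[is.na(m)] <- 0
    as.numeric(m)
  }, numeric(side * side)))
  X
}

init_weights <- function(arch) {
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  flat <- (arch$input_side / 4)^2 * arch$conv2
  list(W1 = he(9, arch$conv1, 9), b1 = numeric(arch$conv1),
       W2 = he(9 * arch$conv1, arch$conv2, 9 * arch$conv1),
       b2 = numeric(arch$conv2),
       W3 = he(flat, arch$hidden, flat), b3 = numeric(arch$hidden),
       W4 = he(arch$hidden, 5, arch$hidden), b4 = numeric(5))
}

#' Fit the convolutional density-state classifier
#'
#' Trains the network from random initialisation (no pretrained
#' weights) on single-channel GNDVI tiles labelled with the five
#' ordinal density states. All randomness derives from the schedule's
#' seed, so a rerun with the same inputs reproduces the same model.
#'
#' @param tiles A list of tile matrices (or a pre-stacked numeric
#'   matrix, one tile per row).
#' @param states Density-state labels, one per tile; every state must
#'   be represented.
#' @param schedule A [training_schedule()].
#' @param arch An [architecture_spec()].
#' @param validation Optional list(tiles, states) scored once per
#'   epoch.
#' @return A `density_cnn` object: weights, architecture, schedule,
#'   per-batch training-loss history and per-epoch validation loss.
#' @export
fit_density_cnn <- function(tiles, states,
                            schedule = training_schedule(),
                            arch = architecture_spec(),
                            validation = NULL) {
  y <- as_density_state(states)
  missing <- setdiff(state_levels(), as.character(unique(y)))
  if (length(missing) > 0) {
    stop("training set has no examples of state(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- stack_tiles(tiles, arch$input_side)
  if (ncol(X) != arch$input_side^2) {
    stop("tile shape does not match architecture input side",
         call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("one label per tile required",
                                 call. = FALSE)
  n <- nrow(X)
  fit <- with_seed(derive_seed(schedule$seed, "cnn"), {
    w0 <- init_weights(arch)
    order <- vapply(seq_len(schedule$epochs), function(e) sample.int(n),
                    integer(n)) - 1L
    if (!is.null(validation)) {
      Xv <- stack_tiles(validation$tiles, arch$input_side)
      yv <- as.integer(as_density_state(validation$states)) - 1L
    } else {
      Xv <- matrix(0, 0, arch$input_side^2)
      yv <- integer(0)
    }
    cnn_train_cpp(w0, X, as.integer(y) - 1L, arch$input_side, order,
                  schedule$batch_size, schedule$lr0, schedule$halve_every,
                  schedule$momentum, Xv, yv)
  })
  structure(
    list(weights = fit$weights, arch = arch, schedule = schedule,
         history = tibble::tibble(step = seq_along(fit$batch_loss),
                                  loss = as.numeric(fit$batch_loss)),
         val_loss = as.numeric(fit$val_loss),
         n_train = n, steps = fit$steps),
    class = "density_cnn"
  )
}

#' Predict density-state scores for tiles
#'
#' Softmax class scores — each row is a prediction vector of five
#' non-negative scores summing to 1 — plus the argmax state.
#'
#' @param object A fitted `density_cnn`.
#' @param tiles A list of tile matrices or a pre-stacked matrix.
#' @param ... Unused.
#' @return A tibble with the five score columns (named by state) and
#'   `.pred` (ordered factor).
#' @export
predict.density_cnn <- function(object, tiles, ...) {
  X <- stack_tiles(tiles, object$arch$input_side)
  if (ncol(X) != object$arch$input_side^2) {
    stop("tile shape does not match architecture input side",
         call. = FALSE)
  }
  p <- cnn_predict_cpp(object$weights, X, object$arch$input_side)
  colnames(p) <- state_levels()
  out <- tibble::as_tibble(p)
  out$.pred <- as_density_state(max.col(p, ties.method = "first") - 1L)
  out
}

#' @export
print.density_cnn <- function(x, ...) {
  cat("<density_cnn>", x$arch$preset, "-", x$n_train, "tiles,",
      x$steps, "steps, final batch loss",
      format(utils::tail(x$history$loss, 1), digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.density_cnn <- function(x, ...) x$history

#' @export
glance.density_cnn <- function(x, ...) {
  tibble::tibble(
    preset = x$arch$preset,
    n_train = x$n_train,
    steps = as.integer(x$steps),
    final_loss = utils::tail(x$history$loss, 1),
    final_val_loss = if (length(x$val_loss)) utils::tail(x$val_loss, 1)
      else NA_real_,
    n_parameters = sum(vapply(x$weights, length, integer(1)))
  )
}

#' Serialize / restore a fitted classifier
#'
#' Model handles are written as versioned JSON (weights flattened with
#' dimensions retained) so experiments are resumable without binary
#' artefacts.
#'
#' @param model A `density_cnn`.
#' @param path File path.
#' @return `write_density_cnn` returns `path` invisibly;
#'   `read_density_cnn` the restored model.
#' @export
write_density_cnn <- function(model, path) {
  payload <- list(
    format = "weedmapr-cnn", version = 1L,
    arch = unclass(model$arch), schedule = unclass(model$schedule),
    n_train = model$n_train, steps = model$steps,
    history = model$history, val_loss = model$val_loss,
    weights = lapply(model$weights, function(w) {
      list(dim = dim(w) %||% length(w), values = as.numeric(w))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_density_cnn
#' @export
read_density_cnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "weedmapr-cnn")) {
    stop("not a weedmapr model file", call. = FALSE)
  }
  weights <- lapply(p$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$values, w$dim[1], w$dim[2])
    else as.numeric(w$values)
  })
  structure(
    list(weights = weights,
         arch = structure(as.list(p$arch), class = "architecture_spec"),
         schedule = structure(as.list(p$schedule),
                              class = "training_schedule"),
         history = tibble::as_tibble(p$history),
         val_loss = as.numeric(p$val_loss),
         n_train = p$n_train, steps = p$steps),
    class = "density_cnn"
  )
}
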