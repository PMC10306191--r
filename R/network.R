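#' Network configuration
#'
#' Describes a small sequential recognition network: a stack of dense
#' rectified layers (the flattened image is the input), each optionally
#' carrying lateral recurrent weights and intrinsic-suppression adaptation,
#' topped by a linear readout over `n_categories`. The readout deliberately
#' applies no saturating transform (no softmax), so representational traces
#' stay smooth over model steps, and per-layer normalization statistics are
#' time-invariant (frozen once, never updated during a run).
#'
#' @param input_dim number of input pixels (images are flattened; values are
#'   expected in `[0, 1]`).
#' @param hidden_sizes integer vector of hidden-layer widths (>= 1 layer).
#' @param n_categories number of readout categories C (>= 2).
#' @param lateral logical, one value per hidden layer (recycled): does the
#'   layer have lateral recurrent weights?
#' @param adaptation [adaptation_params()] applied to every rectified layer;
#'   the linear readout carries no rectifier and hence no adaptation.
#' @param seed integer seed for weight initialization.
#' @return an object of class `network_config`.
#' @export
network_config <- function(input_dim, hidden_sizes, n_categories,
                           lateral = TRUE,
                           adaptation = adaptation_preset("none"),
                           seed = 1L) {
  stopifnot_scalar_number(input_dim, "input_dim", lower = 1, integer = TRUE)
  stopifnot_scalar_number(n_categories, "n_categories", lower = 2,
                          integer = TRUE)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1)) {
    stop("need at least one hidden layer of width >= 1", call. = FALSE)
  }
  stopifnot(inherits(adaptation, "adaptation_params"))
  lateral <- rep_len(as.logical(lateral), length(hidden_sizes))
  structure(
    list(input_dim = as.integer(input_dim),
         hidden_sizes = as.integer(hidden_sizes),
         n_categories = as.integer(n_categories),
         lateral = lateral,
         adaptation = adaptation,
         seed = as.integer(seed)),
    class = "network_config"
  )
}

#' Build a sequential recognition network
#'
#' Weights are drawn deterministically from the config seed (Gaussian,
#' scaled by 1/sqrt(fan-in)); two identically-seeded builds produce identical
#' outputs on identical inputs. Each hidden layer holds feedforward weights
#' `W` and bias `b`, optional lateral weights `W_lat`, and frozen
#' normalization (`norm_shift`, `norm_scale`; identity until
#' [freeze_normalization()] is called). The readout is linear with zero bias.
#'
#' @param config a [network_config()].
#' @return an object of class `rsvp_network`: a list with `config`, `layers`
#'   (each a list `W`, `b`, `W_lat`, `norm_shift`, `norm_scale`) and `W_out`.
#'   Tests and power users may replace weight matrices directly; shapes are
#'   validated at run time.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  with_seed(config$seed, {
    sizes <- c(config$input_dim, config$hidden_sizes)
    layers <- vector("list", length(config$hidden_sizes))
    for (l in seq_along(layers)) {
      n_in <- sizes[l]
      n_out <- sizes[l + 1L]
      layer <- list(
        W = matrix(stats::rnorm(n_out * n_in, sd = 1 / sqrt(n_in)),
                   nrow = n_out),
        b = stats::rnorm(n_out, sd = 0.1),
        W_lat = NULL,
        norm_shift = numeric(n_out),
        norm_scale = rep(1, n_out)
      )
      if (config$lateral[l]) {
        layer$W_lat <- matrix(stats::rnorm(n_out * n_out,
                                           sd = 0.5 / sqrt(n_out)),
                              nrow = n_out)
      }
      layers[[l]] <- layer
    }
    n_last <- utils::tail(sizes, 1)
    W_out <- matrix(stats::rnorm(config$n_categories * n_last,
                                 sd = 1 / sqrt(n_last)),
                    nrow = config$n_categories)
    structure(list(config = config, layers = layers, W_out = W_out),
              class = "rsvp_network")
  })
}

#' @export
print.rsvp_network <- function(x, ...) {
  cfg <- x$config
  cat("Sequential recognition network\n")
  cat("  input dim :", cfg$input_dim, "\n")
  cat("  hidden    :", paste(cfg$hidden_sizes, collapse = " -> "),
      sprintf("(lateral: %s)", paste(ifelse(cfg$lateral, "yes", "no"),
                                     collapse = ", ")), "\n")
  cat("  readout   :", cfg$n_categories, "categories (linear)\n")
  cat("  adaptation:", cfg$adaptation$kind, "\n")
  invisible(x)
}

#' Freeze per-layer normalization statistics
#'
#' Runs a pure feedforward pass (no recurrence, no adaptation) on a
#' calibration batch, records per-unit mean and standard deviation of each
#' layer's drive, and stores them as the network's fixed normalization:
#' drives are standardized by these constants at every future step. The
#' statistics never update again, keeping the network stable over long
#' sequences.
#'
#' @param network an [build_network()] result.
#' @param images list of calibration images (numeric arrays matching the
#'   input shape).
#' @param eps floor on the standard deviation to avoid division blow-ups.
#' @return the network with `norm_shift`/`norm_scale` set on every layer.
#' @export
freeze_normalization <- function(network, images, eps = 1e-3) {
  stopifnot(inherits(network, "rsvp_network"))
  if (length(images) < 2L) {
    stop("need at least 2 calibration images", call. = FALSE)
  }
  drives <- vector("list", length(network$layers))
  for (img in images) {
    x <- as.numeric(img)
    if (length(x) != network$config$input_dim) {
      stop("calibration image size does not match network input",
           call. = FALSE)
    }
    for (l in seq_along(network$layers)) {
      layer <- network$layers[[l]]
      d <- as.numeric(layer$W %*% x + layer$b)
      drives[[l]] <- rbind(drives[[l]], d)
      x <- pmax(d, 0)
    }
  }
  for (l in seq_along(network$layers)) {
    mu <- colMeans(drives[[l]])
    sdv <- pmax(apply(drives[[l]], 2, stats::sd), eps)
    network$layers[[l]]$norm_shift <- mu
    network$layers[[l]]$norm_scale <- 1 / sdv
  }
  network
}

#' Build a stimulus sequence of repeated frames
#'
#' Presentation duration is emulated by repeating each image for
#' `steps_per_image` consecutive model steps, so a sequence of m images spans
#' `T = m * steps_per_image` steps.
#'
#' @param images non-empty list of numeric arrays with a shared shape.
#' @param steps_per_image repetitions n >= 1 per image.
#' @return an object of class `stimulus_sequence`: list with `images`,
#'   `steps_per_image`, `n_steps`, `step_to_image` (1-based image index per
#'   step) and `boundaries` (data frame `image`, `first_step`, `last_step`).
#' @export
make_sequence <- function(images, steps_per_image) {
  stopifnot_scalar_number(steps_per_image, "steps_per_image", lower = 1,
                          integer = TRUE)
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a non-empty list", call. = FALSE)
  }
  lens <- vapply(images, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all images in a sequence must share one shape", call. = FALSE)
  }
  n <- as.integer(steps_per_image)
  m <- length(images)
  step_to_image <- rep(seq_len(m), each = n)
  boundaries <- data.frame(
    image = seq_len(m),
    first_step = (seq_len(m) - 1L) * n + 1L,
    last_step = seq_len(m) * n
  )
  structure(
    list(images = images, steps_per_image = n, n_steps = m * n,
         step_to_image = step_to_image, boundaries = boundaries),
    class = "stimulus_sequence"
  )
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat("Stimulus sequence:", length(x$images), "images x",
      x$steps_per_image, "steps/image =", x$n_steps, "model steps\n")
  invisible(x)
}

new_output_trace <- function(values, step_to_image) {
  structure(list(values = values, step_to_image = step_to_image),
            class = "output_trace")
}

#' @export
print.output_trace <- function(x, ...) {
  cat("Output trace:", nrow(x$values), "steps x", ncol(x$values),
      "categories\n")
  invisible(x)
}

#' Tidy data-frame view of an output trace
#'
#' @param x an `output_trace`.
#' @param ... unused.
#' @return data frame with columns `step`, `image_index`, `category`,
#'   `activation`.
#' @export
as.data.frame.output_trace <- function(x, ...) {
  T_ <- nrow(x$values)
  C_ <- ncol(x$values)
  data.frame(
    step = rep(seq_len(T_), times = C_),
    image_index = rep(x$step_to_image, times = C_),
    category = rep(seq_len(C_), each = T_),
    activation = as.numeric(x$values)
  )
}

run_steps <- function(network, frames_by_step, step_to_image) {
  cfg <- network$config
  params <- cfg$adaptation
  n_layers <- length(network$layers)
  h <- lapply(network$layers, function(l) numeric(length(l$b)))
  s <- lapply(network$layers,
              function(l) adapt_state_init(params, length(l$b)))
  T_ <- length(frames_by_step)
  y <- matrix(NA_real_, nrow = T_, ncol = cfg$n_categories)
  for (t in seq_len(T_)) {
    x <- frames_by_step[[t]]
    for (l in seq_len(n_layers)) {
      layer <- network$layers[[l]]
      drive <- as.numeric(layer$W %*% x + layer$b)
      if (!is.null(layer$W_lat)) {
        drive <- drive + as.numeric(layer$W_lat %*% h[[l]])
      }
      drive <- (drive - layer$norm_shift) * layer$norm_scale
      a <- apply_suppression(drive, s[[l]], params)
      s[[l]] <- adapt_step(s[[l]], a, params)
      h[[l]] <- a
      x <- a
    }
    y[t, ] <- as.numeric(network$W_out %*% x)
  }
  new_output_trace(y, step_to_image)
}

#' Run a network over a sequence, carrying state across images
#'
#' Recurrent and adaptation state persists across image boundaries: step t's
#' lateral input is the layer state at t-1, so preceding time steps influence
#' the processing of the current one. The first step, starting from zero
#' state, is a pure feedforward pass.
#'
#' @param network a built [rsvp_network][build_network()].
#' @param sequence a [make_sequence()] result whose frame shape matches the
#'   network input.
#' @return an `output_trace`: `values` is a T x C matrix of linear readout
#'   activations, `step_to_image` maps each model step to the presented
#'   image.
#' @export
run_sequential <- function(network, sequence) {
  stopifnot(inherits(network, "rsvp_network"),
            inherits(sequence, "stimulus_sequence"))
  flat <- lapply(sequence$images, as.numeric)
  if (length(flat[[1]]) != network$config$input_dim) {
    stop("sequence frame size does not match network input", call. = FALSE)
  }
  frames_by_step <- flat[sequence$step_to_image]
  run_steps(network, frames_by_step, sequence$step_to_image)
}

#' Run a network on one image with fresh state
#'
#' State is zeroed before the image, removing all history; equivalent to
#' [run_sequential()] on a one-image sequence.
#'
#' @inheritParams run_sequential
#' @param image numeric array matching the network input shape.
#' @param n_steps number of model steps the image is presented for.
#' @return an `output_trace` with `n_steps` rows.
#' @export
run_single_image <- function(network, image, n_steps) {
  run_sequential(network, make_sequence(list(image), n_steps))
}
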