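#' Per-step and per-image top-k accuracy
#'
#' A model step is correct if the presented image's true category is among
#' the k largest readout activations at that step (top-5 by convention for
#' recognition streams, tolerating lingering representations of previous
#' images). Ties inside the top-k boundary are broken toward the smallest
#' category index for reproducibility. Per-image accuracy is the mean of
#' per-step correctness within that image's presentation window;
#' `aggregate = "final"` scores only the last step of each window instead.
#'
#' @param trace an `output_trace`.
#' @param labels integer vector of true category indices, either one per
#'   model step (length T) or one per image (recycled across each image's
#'   window).
#' @param k top-k cutoff, `1 <= k <= C`.
#' @param aggregate `"mean"` (default) or `"final"` per-image aggregation.
#' @return list with `step_correct` (logical, length T), `step_accuracy`,
#'   `image_accuracy` (named by image index) and `accuracy` (mean over
#'   images).
#' @export
topk_accuracy <- function(trace, labels, k = 5L,
                          aggregate = c("mean", "final")) {
  stopifnot(inherits(trace, "output_trace"))
  aggregate <- match.arg(aggregate)
  T_ <- nrow(trace$values)
  C_ <- ncol(trace$values)
  stopifnot_scalar_number(k, "k", lower = 1, upper = C_, integer = TRUE)
  imgs <- trace$step_to_image
  if (length(labels) == length(unique(imgs))) {
    labels <- labels[imgs]
  }
  if (length(labels) != T_) {
    stop("labels must have one entry per step or per image", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > C_)) {
    stop("label out of category range", call. = FALSE)
  }
  step_correct <- vapply(seq_len(T_), function(t) {
    topk <- order(-trace$values[t, ], seq_len(C_))[seq_len(k)]
    labels[t] %in% topk
  }, logical(1))
  per_image <- if (aggregate == "mean") {
    tapply(step_correct, imgs, mean)
  } else {
    tapply(seq_len(T_), imgs, function(ix) {
      step_correct[max(ix)]
    })
  }
  list(step_correct = step_correct,
       step_accuracy = mean(step_correct),
       image_accuracy = as.numeric(per_image),
       accuracy = mean(as.numeric(per_image)))
}

#' Sequential-recognition accuracy protocol
#'
#' Samples random image sequences (each image from a different category)
#' from a labelled bank and measures top-k accuracy at each presentation
#' duration in `steps_grid`, in two regimes: `sequential` (state carried
#' across images) and `single_image` (state reset before every image).
#' The reference protocol uses 500 sequences of 6 images; smaller settings
#' are useful for toy networks.
#'
#' @param network a built [rsvp_network][build_network()].
#' @param image_bank an `image_bank` from [generate_image_bank()], or any
#'   list with `images` (list of arrays) and `labels` (integer categories).
#' @param n_sequences number of random sequences.
#' @param images_per_sequence images per sequence (distinct categories).
#' @param steps_grid integer vector of steps-per-image conditions.
#' @param k top-k cutoff (default 5, capped at C).
#' @param aggregate per-image aggregation passed to [topk_accuracy()].
#' @param seed RNG seed; the sampled sequences are deterministic given it.
#' @return data frame with columns `mode`, `steps_per_image`,
#'   `adaptation_kind`, `accuracy`, `n`.
#' @export
sequential_recognition_protocol <- function(network, image_bank,
                                            n_sequences = 500L,
                                            images_per_sequence = 6L,
                                            steps_grid = c(1L, 2L, 4L, 8L),
                                            k = 5L,
                                            aggregate = "mean",
                                            seed = 1L) {
  stopifnot(inherits(network, "rsvp_network"))
  labels <- image_bank$labels
  cats <- unique(labels)
  if (length(cats) < images_per_sequence) {
    stop("image bank must hold at least `images_per_sequence` categories",
         call. = FALSE)
  }
  k <- min(k, network$config$n_categories)
  draws <- with_seed(seed, {
    lapply(seq_len(n_sequences), function(i) {
      chosen_cats <- sample(cats, images_per_sequence)
      vapply(chosen_cats, function(cc) {
        ix <- which(labels == cc)
        if (length(ix) == 1L) ix else sample(ix, 1L)
      }, integer(1))
    })
  })
  rows <- list()
  for (n_steps in steps_grid) {
    acc_seq <- numeric(n_sequences)
    acc_sing <- numeric(n_sequences)
    for (i in seq_len(n_sequences)) {
      idx <- draws[[i]]
      imgs <- image_bank$images[idx]
      labs <- labels[idx]
      sq <- make_sequence(imgs, n_steps)
      acc_seq[i] <- topk_accuracy(run_sequential(network, sq), labs, k,
                                  aggregate)$accuracy
      single <- vapply(seq_along(imgs), function(j) {
        tr <- run_single_image(network, imgs[[j]], n_steps)
        topk_accuracy(tr, labs[j], k, aggregate)$accuracy
      }, numeric(1))
      acc_sing[i] <- mean(single)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      mode = c("sequential", "single_image"),
      steps_per_image = n_steps,
      adaptation_kind = network$config$adaptation$kind,
      accuracy = c(mean(acc_seq), mean(acc_sing)),
      n = n_sequences
    )
  }
  do.call(rbind, rows)
}
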