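#' Exemplar set for prototype construction
#'
#' Holds the readout states evoked by category exemplars together with a
#' reference vector: the mean readout state of the trial's target and foil
#' image. Whatever the target and foil share approximates the intended
#' category, so correlation with this reference serves as a marker of
#' semantic relevance when exemplar pools are noisy or ambiguous.
#'
#' @param activations E x C numeric matrix, one row per exemplar.
#' @param reference length-C numeric vector (mean of target and foil readout
#'   states).
#' @param category_label optional identifier.
#' @return an object of class `exemplar_set`.
#' @export
exemplar_set <- function(activations, reference, category_label = NA) {
  activations <- as.matrix(activations)
  if (nrow(activations) < 1L || any(!is.finite(activations))) {
    stop("need >= 1 exemplar with finite activations", call. = FALSE)
  }
  if (length(reference) != ncol(activations)) {
    stop("reference length must equal the readout dimension", call. = FALSE)
  }
  structure(
    list(activations = activations, reference = as.numeric(reference),
         category_label = category_label),
    class = "exemplar_set"
  )
}

#' Rank exemplars by semantic relevance
#'
#' Orders exemplars by descending similarity between each exemplar's readout
#' state and the reference vector. The default metric is the Pearson
#' correlation; Euclidean distance (ascending) is available via `metric`.
#' Ties keep the original order (stable sort).
#'
#' @param exemplars an [exemplar_set()].
#' @param metric `"pearson"` (default) or `"euclidean"`.
#' @return integer vector of exemplar row indices, most relevant first.
#' @export
rank_exemplars <- function(exemplars, metric = c("pearson", "euclidean")) {
  stopifnot(inherits(exemplars, "exemplar_set"))
  metric <- match.arg(metric)
  ref <- exemplars$reference
  A <- exemplars$activations
  if (metric == "pearson") {
    if (stats::sd(ref) == 0) {
      stop("reference vector has zero variance; relevance is undefined",
           call. = FALSE)
    }
    score <- apply(A, 1, function(row) {
      if (stats::sd(row) == 0) -Inf else stats::cor(row, ref)
    })
    order(-score, seq_len(nrow(A)))
  } else {
    score <- apply(A, 1, function(row) sqrt(sum((row - ref)^2)))
    order(score, seq_len(nrow(A)))
  }
}

#' Compute a categorical prototype
#'
#' The prototype is the geometric centre (arithmetic mean) of the readout
#' states of the k most relevant exemplars. Typical choices for k are 10, 50
#' or 100; results are reported for k = 10 by default elsewhere in the
#' package.
#'
#' @param exemplars an [exemplar_set()].
#' @param k number of top-ranked exemplars to average, `1 <= k <= E`.
#' @param metric relevance metric passed to [rank_exemplars()].
#' @return an object of class `prototype`: list with `phi` (length-C vector)
#'   and `k`.
#' @export
compute_prototype <- function(exemplars, k, metric = "pearson") {
  stopifnot(inherits(exemplars, "exemplar_set"))
  E <- nrow(exemplars$activations)
  stopifnot_scalar_number(k, "k", lower = 1, integer = TRUE)
  if (k > E) stop("k exceeds the number of exemplars", call. = FALSE)
  idx <- rank_exemplars(exemplars, metric)[seq_len(k)]
  phi <- colMeans(exemplars$activations[idx, , drop = FALSE])
  structure(list(phi = as.numeric(phi), k = as.integer(k),
                 category_label = exemplars$category_label),
            class = "prototype")
}

#' @export
print.prototype <- function(x, ...) {
  cat("Category prototype (k =", x$k, "exemplars,",
      length(x$phi), "dims)\n")
  invisible(x)
}

pearson_or_na <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Representational-strength trace
#'
#' Correlates the readout state at every model step with a target vector:
#' `p_t = r(target, y_t)` (Pearson). The target can be a category prototype,
#' a one-hot category vector, or the readout state of the target image
#' processed in isolation. A zero-variance readout row yields `NA` — an
#' undefined-correlation sentinel treated as "no evidence" downstream rather
#' than an error, since degenerate all-zero outputs can occur in small
#' rectified networks.
#'
#' @param trace an `output_trace`.
#' @param target length-C numeric vector, or a `prototype` (its `phi` is
#'   used).
#' @param target_kind label recorded on the result: `"prototype"`,
#'   `"onehot"` or `"image_state"`.
#' @return object of class `strength_trace`: list with `p` (length-T vector
#'   in `[-1, 1]` where defined), `target_kind`, `step_to_image`.
#' @export
strength_trace <- function(trace, target,
                           target_kind = c("prototype", "onehot",
                                           "image_state")) {
  stopifnot(inherits(trace, "output_trace"))
  target_kind <- match.arg(target_kind)
  if (inherits(target, "prototype")) target <- target$phi
  target <- as.numeric(target)
  if (length(target) != ncol(trace$values)) {
    stop("target length must equal the readout dimension", call. = FALSE)
  }
  if (stats::sd(target) == 0) {
    stop("target vector has zero variance; correlation is undefined",
         call. = FALSE)
  }
  p <- apply(trace$values, 1, pearson_or_na, y = target)
  structure(list(p = as.numeric(p), target_kind = target_kind,
                 step_to_image = trace$step_to_image),
            class = "strength_trace")
}

#' @export
print.strength_trace <- function(x, ...) {
  cat("Representational-strength trace (", x$target_kind, "): ",
      length(x$p), " steps, peak ",
      format(suppressWarnings(max(x$p, na.rm = TRUE))), "\n", sep = "")
  invisible(x)
}
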