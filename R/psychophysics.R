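#' Peak prototype correlation (PPC)
#'
#' Summarizes a trial's sensory evidence as the peak of the
#' representational-strength trace: `PPC = max(p)`. In sequential mode the
#' maximum runs over model steps; in single-image mode over per-image values
#' (one `p` per image processed in isolation). Undefined (`NA`) entries are
#' treated as "no evidence" and ignored; a trace with no defined entry is a
#' degenerate input.
#'
#' @param trace a `strength_trace`, or a bare numeric vector of per-step
#'   (or per-image) correlation values.
#' @param mode `"sequential"` or `"single_image"` (recorded only; the
#'   caller supplies per-step or per-image values accordingly).
#' @return scalar PPC value.
#' @export
peak_prototype_correlation <- function(trace,
                                       mode = c("sequential",
                                                "single_image")) {
  mode <- match.arg(mode)
  p <- if (inherits(trace, "strength_trace")) trace$p else as.numeric(trace)
  if (length(p) == 0L) stop("empty trace", call. = FALSE)
  if (all(is.na(p))) {
    stop("all correlation values undefined; PPC is degenerate",
         call. = FALSE)
  }
  max(p, na.rm = TRUE)
}

#' Assemble a PPC table
#'
#' One row per trial x steps-per-image condition, carrying the trial's peak
#' prototype correlation and ground truth. This is the tidy container the
#' sensitivity and predictivity analyses consume.
#'
#' @param trial_id vector of trial identifiers.
#' @param steps_per_image integer condition label per row.
#' @param ppc numeric PPC values (may contain `NA` sentinels).
#' @param target_present logical ground truth per row.
#' @return data frame of class `ppc_table`.
#' @export
ppc_table <- function(trial_id, steps_per_image, ppc, target_present) {
  out <- data.frame(trial_id = trial_id,
                    steps_per_image = as.integer(steps_per_image),
                    ppc = as.numeric(ppc),
                    target_present = as.logical(target_present))
  if (anyDuplicated(out[, c("trial_id", "steps_per_image")])) {
    stop("one row per trial x condition required", call. = FALSE)
  }
  class(out) <- c("ppc_table", "data.frame")
  out
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney estimator with midranks for ties: the probability that a
#' randomly chosen positive PPC exceeds a randomly chosen negative one
#' (ties counted half). Equivalent to integrating TPR over FPR while
#' sweeping a criterion across the pooled PPC values.
#'
#' @param positive,negative numeric evidence values for target-present and
#'   target-absent trials.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(positive, negative) {
  positive <- positive[is.finite(positive)]
  negative <- negative[is.finite(negative)]
  n_p <- length(positive)
  n_n <- length(negative)
  if (n_p == 0L || n_n == 0L) {
    stop("need at least one value in each class", call. = FALSE)
  }
  r <- rank(c(positive, negative))
  (sum(r[seq_len(n_p)]) - n_p * (n_p + 1) / 2) / (n_p * n_n)
}

#' Model sensitivity from PPC distributions
#'
#' Perceptual sensitivity of a model is the separation between the PPC
#' distributions of target-present and target-absent trials:
#' `d' = sqrt(2) * qnorm(AUC)`, with the AUC estimated by the midrank
#' Mann-Whitney statistic. An AUC of exactly 0 or 1 would map to an infinite
#' d', so the AUC is clipped to `[1/(2n+2), 1 - 1/(2n+2)]` (n = total trials
#' used) before the probit; the clamp is configurable via `auc_clip`.
#' Rows with an undefined (`NA`) PPC are excluded with a message.
#'
#' @param ppc a `ppc_table` (a single steps-per-image condition), or a data
#'   frame with columns `ppc` and `target_present`.
#' @param auc_clip optional length-2 numeric overriding the default clip
#'   bounds.
#' @return list with `dprime`, `auc`, `n_present`, `n_absent`,
#'   `n_excluded`.
#' @export
model_dprime <- function(ppc, auc_clip = NULL) {
  stopifnot(is.data.frame(ppc),
            all(c("ppc", "target_present") %in% names(ppc)))
  bad <- is.na(ppc$ppc)
  if (any(bad)) {
    message(sum(bad), " trial(s) with undefined PPC excluded")
    ppc <- ppc[!bad, , drop = FALSE]
  }
  pos <- ppc$ppc[ppc$target_present]
  neg <- ppc$ppc[!ppc$target_present]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("need >= 1 target-present and >= 1 target-absent trial",
         call. = FALSE)
  }
  auc <- roc_auc(pos, neg)
  n <- length(pos) + length(neg)
  clip <- if (is.null(auc_clip)) c(1 / (2 * n + 2), 1 - 1 / (2 * n + 2)) else auc_clip
  auc_clipped <- min(max(auc, clip[1]), clip[2])
  list(dprime = sqrt(2) * stats::qnorm(auc_clipped),
       auc = auc,
       n_present = length(pos), n_absent = length(neg),
       n_excluded = sum(bad))
}

#' Signal-detection trial counts
#'
#' @param TP,FN,FP,TN non-negative counts: hits, misses, false alarms and
#'   correct rejections.
#' @return object of class `sdt_counts`.
#' @export
sdt_counts <- function(TP, FN, FP, TN) {
  for (nm in c("TP", "FN", "FP", "TN")) {
    stopifnot_scalar_number(get(nm), nm, lower = 0, integer = TRUE)
  }
  structure(list(TP = TP, FN = FN, FP = FP, TN = TN), class = "sdt_counts")
}

#' Tally SDT counts from per-trial binary responses
#'
#' @param response logical/0-1 vector: did the observer report a target?
#' @param target_present logical ground truth, same length.
#' @return an [sdt_counts()] object.
#' @export
sdt_counts_from_responses <- function(response, target_present) {
  response <- as.logical(response)
  target_present <- as.logical(target_present)
  stopifnot(length(response) == length(target_present))
  sdt_counts(TP = sum(response & target_present),
             FN = sum(!response & target_present),
             FP = sum(response & !target_present),
             TN = sum(!response & !target_present))
}

#' Human sensitivity with the log-linear correction
#'
#' `d' = z(TPR) - z(FPR)` from binary reports, with the log-linear method
#' guarding against 0% and 100% rates: 0.5 is added to every cell, so
#' `TPR = (TP + 0.5) / (TP + FN + 1)` and `FPR = (FP + 0.5) / (FP + TN + 1)`.
#' The result is finite for every count table.
#'
#' @param counts an [sdt_counts()] object.
#' @return list with `dprime`, `tpr`, `fpr` (corrected rates).
#' @export
human_dprime_loglinear <- function(counts) {
  stopifnot(inherits(counts, "sdt_counts"))
  tpr <- (counts$TP + 0.5) / (counts$TP + counts$FN + 1)
  fpr <- (counts$FP + 0.5) / (counts$FP + counts$TN + 1)
  list(dprime = stats::qnorm(tpr) - stats::qnorm(fpr),
       tpr = tpr, fpr = fpr)
}
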