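#' Observer report panel
#'
#' Binary "target present" reports from a panel of subjects over a shared
#' trial set, with a presentation-duration label per trial (e.g. 13, 40, 80
#' or 160 ms/image). The group-average report rate per trial is the
#' behavioural quantity the model's PPC is compared against; using the
#' report rate rather than the hit rate keeps target-absent trials in the
#' analysis.
#'
#' @param reports subjects x trials matrix with entries in `{0, 1}`.
#' @param duration per-trial duration label (length = number of trials).
#' @param subject_ids optional subject identifiers (default `S1..Sn`).
#' @param trial_ids optional trial identifiers (default column names or
#'   `1..n`).
#' @return object of class `observer_reports`.
#' @export
observer_reports <- function(reports, duration, subject_ids = NULL,
                             trial_ids = NULL) {
  reports <- as.matrix(reports)
  if (!all(reports %in% c(0, 1))) {
    stop("reports must be binary (0/1)", call. = FALSE)
  }
  if (length(duration) != ncol(reports)) {
    stop("one duration label per trial required", call. = FALSE)
  }
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(reports)))
  if (is.null(trial_ids)) {
    trial_ids <- colnames(reports)
    if (is.null(trial_ids)) trial_ids <- as.character(seq_len(ncol(reports)))
  }
  structure(
    list(reports = unname(reports), duration = duration,
         subject_ids = subject_ids, trial_ids = as.character(trial_ids)),
    class = "observer_reports"
  )
}

#' @export
print.observer_reports <- function(x, ...) {
  cat("Observer reports:", nrow(x$reports), "subjects x",
      ncol(x$reports), "trials;",
      "durations:", paste(sort(unique(x$duration)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-trial report rate
#'
#' `RR = (# yes responses) / (# subjects)` per trial, over all trials with
#' the given duration label (all trials if `duration` is `NULL`); includes
#' target-absent trials by construction.
#'
#' @param reports an [observer_reports()].
#' @param duration optional duration label to restrict to.
#' @param subjects optional integer subject indices (used by the bootstrap;
#'   repeats allowed).
#' @return named numeric vector of RR values, one per trial.
#' @export
report_rate <- function(reports, duration = NULL, subjects = NULL) {
  stopifnot(inherits(reports, "observer_reports"))
  keep <- if (is.null(duration)) seq_along(reports$duration) else
    which(reports$duration == duration)
  if (length(keep) == 0L) {
    stop("no trials at that duration", call. = FALSE)
  }
  R <- reports$reports
  if (!is.null(subjects)) R <- R[subjects, , drop = FALSE]
  rr <- colMeans(R[, keep, drop = FALSE])
  names(rr) <- reports$trial_ids[keep]
  rr
}

#' Trial-by-trial predictivity
#'
#' Spearman correlation (midranks) between a model's per-trial PPC values
#' and the group-average report rate over the same trials. Returns the
#' undefined sentinel `NA` when either side is constant.
#'
#' @param ppc numeric PPC values per trial.
#' @param rr numeric report rates per trial, same order.
#' @return scalar Spearman rho or `NA_real_`.
#' @export
trial_predictivity <- function(ppc, rr) {
  if (length(ppc) != length(rr)) {
    stop("ppc and rr must be aligned per trial", call. = FALSE)
  }
  if (sum(is.finite(ppc) & is.finite(rr)) < 3L) {
    stop("need >= 3 trials with both quantities", call. = FALSE)
  }
  spearman_rho(ppc, rr)
}

profile_rho <- function(ppc_tab, reports, steps, durations, subjects = NULL) {
  rho <- matrix(NA_real_, nrow = length(steps), ncol = length(durations),
                dimnames = list(steps = as.character(steps),
                                duration = as.character(durations)))
  for (j in seq_along(durations)) {
    rr <- report_rate(reports, durations[j], subjects)
    for (i in seq_along(steps)) {
      sub <- ppc_tab[ppc_tab$steps_per_image == steps[i], , drop = FALSE]
      m <- match(names(rr), as.character(sub$trial_id))
      ok <- !is.na(m)
      if (sum(ok) >= 3L) {
        rho[i, j] <- spearman_rho(sub$ppc[m[ok]], rr[ok])
      }
    }
  }
  rho
}

resample_trial_reports <- function(reports, ix) {
  observer_reports(reports$reports[, ix, drop = FALSE],
                   reports$duration[ix],
                   subject_ids = reports$subject_ids,
                   trial_ids = paste0(seq_along(ix), ":",
                                      reports$trial_ids[ix]))
}

resample_trials <- function(ppc, ix, trial_ids) {
  orig <- as.character(trial_ids[ix])
  new_id <- paste0(seq_along(ix), ":", orig)
  out <- do.call(rbind, lapply(sort(unique(ppc$steps_per_image)),
                               function(s) {
    sub <- ppc[ppc$steps_per_image == s, , drop = FALSE]
    m <- match(orig, as.character(sub$trial_id))
    data.frame(trial_id = new_id, steps_per_image = s,
               ppc = sub$ppc[m], target_present = sub$target_present[m])
  }))
  ppc_table(out$trial_id, out$steps_per_image, out$ppc, out$target_present)
}

#' Predictivity profile with subject-level bootstrap
#'
#' For every (model steps-per-image x human presentation duration) cell,
#' computes the Spearman correlation between the model's PPC and the
#' group-average report rate across trials, then bootstraps subjects with
#' replacement (trials are never resampled by default) to attach 95%
#' percentile confidence intervals. Deterministic given `seed`; the drawn
#' subject indices are stored on the result for exact reproducibility.
#'
#' @param ppc a [ppc_table()] covering one or more steps-per-image
#'   conditions, with `trial_id` matching the report panel's trial ids.
#' @param reports an [observer_reports()].
#' @param n_boot number of bootstrap resamples (reference analyses use
#'   1000).
#' @param seed RNG seed.
#' @param resample what to resample: `"subjects"` (default, the reference
#'   procedure) or `"trials"` (off the default path; subjects held fixed).
#' @return object of class `predictivity_profile`: `rho`, `ci_low`,
#'   `ci_high` (steps x durations matrices), `boot` (n_boot x steps x
#'   durations array), `boot_indices`, `steps`, `durations`.
#' @export
bootstrap_profile <- function(ppc, reports, n_boot = 1000L, seed = 1L,
                              resample = c("subjects", "trials")) {
  stopifnot(is.data.frame(ppc), inherits(reports, "observer_reports"))
  stopifnot_scalar_number(n_boot, "n_boot", lower = 1, integer = TRUE)
  resample <- match.arg(resample)
  steps <- sort(unique(ppc$steps_per_image))
  durations <- sort(unique(reports$duration))
  n_subj <- nrow(reports$reports)
  if (resample == "subjects" && n_subj < 2L) {
    warning("single subject: bootstrap CIs are degenerate")
  }
  rho <- profile_rho(ppc, reports, steps, durations)
  n_units <- if (resample == "subjects") n_subj else ncol(reports$reports)
  idx <- with_seed(seed, {
    matrix(sample.int(n_units, n_boot * n_units, replace = TRUE),
           nrow = n_boot)
  })
  boot <- array(NA_real_, dim = c(n_boot, length(steps), length(durations)),
                dimnames = list(NULL, as.character(steps),
                                as.character(durations)))
  for (b in seq_len(n_boot)) {
    boot[b, , ] <- if (resample == "subjects") {
      profile_rho(ppc, reports, steps, durations, idx[b, ])
    } else {
      profile_rho(resample_trials(ppc, idx[b, ], reports$trial_ids),
                  resample_trial_reports(reports, idx[b, ]),
                  steps, durations)
    }
  }
  ci_low <- apply(boot, c(2, 3), stats::quantile, probs = 0.025,
                  na.rm = TRUE, names = FALSE)
  ci_high <- apply(boot, c(2, 3), stats::quantile, probs = 0.975,
                   na.rm = TRUE, names = FALSE)
  dimnames(ci_low) <- dimnames(ci_high) <- dimnames(rho)
  structure(
    list(rho = rho, ci_low = ci_low, ci_high = ci_high, boot = boot,
         boot_indices = idx, steps = steps, durations = durations,
         n_boot = n_boot, seed = seed),
    class = "predictivity_profile"
  )
}

#' @export
print.predictivity_profile <- function(x, ...) {
  cat("Predictivity profile: Spearman rho over",
      length(x$steps), "steps-per-image x",
      length(x$durations), "durations,",
      x$n_boot, "subject bootstraps\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Upper and lower noise ceilings
#'
#' Bounds on the model-human correlation attainable given inter-subject
#' variability. Upper: the mean over subjects of the Spearman correlation
#' between each subject's single-trial reports and the group-average report
#' rate (all N subjects). Lower: the same with the focal subject left out of
#' the group average (N - 1 subjects).
#'
#' @param reports an [observer_reports()] with >= 2 subjects.
#' @param duration optional duration label to restrict to.
#' @return object of class `noise_ceiling`: list with `lower`, `upper`,
#'   `n_subjects`, `n_trials`. Constant group rates yield `NA` sentinels.
#' @export
noise_ceilings <- function(reports, duration = NULL) {
  stopifnot(inherits(reports, "observer_reports"))
  n_subj <- nrow(reports$reports)
  if (n_subj < 2L) stop("need >= 2 subjects", call. = FALSE)
  keep <- if (is.null(duration)) seq_along(reports$duration) else
    which(reports$duration == duration)
  R <- reports$reports[, keep, drop = FALSE]
  grand_sum <- colSums(R)
  upper <- vapply(seq_len(n_subj), function(s) {
    spearman_rho(R[s, ], grand_sum / n_subj)
  }, numeric(1))
  lower <- vapply(seq_len(n_subj), function(s) {
    spearman_rho(R[s, ], (grand_sum - R[s, ]) / (n_subj - 1))
  }, numeric(1))
  structure(
    list(lower = mean(lower), upper = mean(upper),
         n_subjects = n_subj, n_trials = length(keep)),
    class = "noise_ceiling"
  )
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("Noise ceiling: lower %.3f, upper %.3f (%d subjects, %d trials)\n",
              x$lower, x$upper, x$n_subjects, x$n_trials))
  invisible(x)
}

#' Noise ceilings for every duration
#'
#' @param reports an [observer_reports()].
#' @return data frame with columns `duration`, `lower`, `upper`, `n_trials`.
#' @export
noise_ceiling_table <- function(reports) {
  durs <- sort(unique(reports$duration))
  do.call(rbind, lapply(durs, function(d) {
    nc <- noise_ceilings(reports, d)
    data.frame(duration = d, lower = nc$lower, upper = nc$upper,
               n_trials = nc$n_trials)
  }))
}

argmax_first <- function(v) {
  if (all(is.na(v))) return(NA_integer_)
  which.max(replace(v, is.na(v), -Inf))
}

#' Temporal correspondence: most predictive model step per duration
#'
#' For every presentation duration, the steps-per-image whose predictivity
#' rho is highest; ties resolve to the smallest step count (the more
#' parsimonious temporal mapping). When the profile carries bootstrap
#' replicates, the argmax is recomputed per replicate to give a distribution
#' of best steps. Monotonicity of the duration -> best-step map is reported
#' by the caller's inspection, never enforced.
#'
#' @param profile a [predictivity_profile][bootstrap_profile()].
#' @return list with `best` (data frame `duration`, `best_step`, `rho`)
#'   and `boot_best` (n_boot x durations matrix of best steps, or `NULL`).
#' @export
temporal_correspondence <- function(profile) {
  stopifnot(inherits(profile, "predictivity_profile"))
  keep <- which(!apply(profile$rho, 2, function(col) all(is.na(col))))
  if (length(keep) == 0L) stop("profile has no defined column", call. = FALSE)
  best_ix <- vapply(keep, function(j) argmax_first(profile$rho[, j]),
                    integer(1))
  best <- data.frame(
    duration = profile$durations[keep],
    best_step = profile$steps[best_ix],
    rho = profile$rho[cbind(best_ix, keep)]
  )
  boot_best <- NULL
  if (!is.null(profile$boot)) {
    boot_best <- matrix(NA_integer_, nrow = profile$n_boot,
                        ncol = length(keep),
                        dimnames = list(NULL,
                                        as.character(profile$durations[keep])))
    for (b in seq_len(profile$n_boot)) {
      for (jj in seq_along(keep)) {
        ix <- argmax_first(profile$boot[b, , keep[jj]])
        if (!is.na(ix)) boot_best[b, jj] <- profile$steps[ix]
      }
    }
  }
  list(best = best, boot_best = boot_best)
}

#' Explanatory power relative to the lower noise ceiling
#'
#' Converts the most predictive model step's rho at each duration into a
#' proportion of that duration's lower noise ceiling, then averages across
#' durations. Values above 1 are legal: the model can reach or surpass the
#' lower ceiling. Durations with a non-positive lower ceiling are excluded
#' with a warning. When the profile carries bootstrap replicates the
#' statistic is recomputed per replicate for a 95% percentile interval
#' (ceilings held at their point estimates).
#'
#' @param profile a [predictivity_profile][bootstrap_profile()].
#' @param ceilings a data frame from [noise_ceiling_table()] (columns
#'   `duration`, `lower`), or a numeric vector of lower ceilings named by
#'   duration.
#' @return list with `value`, `per_duration` (data frame), `ci_low`,
#'   `ci_high` (NA without bootstrap replicates).
#' @export
explanatory_power <- function(profile, ceilings) {
  stopifnot(inherits(profile, "predictivity_profile"))
  if (is.data.frame(ceilings)) {
    low <- stats::setNames(ceilings$lower, as.character(ceilings$duration))
  } else {
    low <- ceilings
  }
  durs <- as.character(profile$durations)
  if (!all(durs %in% names(low))) {
    stop("lower ceiling missing for some durations", call. = FALSE)
  }
  low <- low[durs]
  usable <- which(is.finite(low) & low > 0)
  if (length(usable) < length(durs)) {
    warning("excluding duration(s) with non-positive lower ceiling: ",
            paste(durs[setdiff(seq_along(durs), usable)], collapse = ", "))
  }
  if (length(usable) == 0L) stop("no usable duration", call. = FALSE)
  best_rho <- vapply(usable, function(j) {
    max(profile$rho[, j], na.rm = TRUE)
  }, numeric(1))
  per_duration <- data.frame(
    duration = profile$durations[usable],
    best_rho = best_rho,
    lower_ceiling = as.numeric(low[usable]),
    proportion = best_rho / as.numeric(low[usable])
  )
  value <- mean(per_duration$proportion)
  ci_low <- ci_high <- NA_real_
  if (!is.null(profile$boot)) {
    boot_ep <- vapply(seq_len(profile$n_boot), function(b) {
      props <- vapply(usable, function(j) {
        suppressWarnings(max(profile$boot[b, , j], na.rm = TRUE)) /
          as.numeric(low[j])
      }, numeric(1))
      mean(props[is.finite(props)])
    }, numeric(1))
    ci_low <- stats::quantile(boot_ep, 0.025, na.rm = TRUE, names = FALSE)
    ci_high <- stats::quantile(boot_ep, 0.975, na.rm = TRUE, names = FALSE)
  }
  list(value = value, per_duration = per_duration,
       ci_low = ci_low, ci_high = ci_high)
}
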