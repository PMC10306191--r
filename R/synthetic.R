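#' Synthetic-study configuration
#'
#' Bundles every knob of the synthetic RSVP study the package can generate:
#' toy image categories, trial structure and simulated observer panels. The
#' defaults mirror the reference behavioural design: streams of 6 images, a
#' quarter of trials without a target, targets never first or last, four
#' presentation durations (13/40/80/160 ms/image), 176 trials and a panel of
#' 36 observers.
#'
#' @param n_categories number of image categories in the bank (>= 2; must be
#'   at least `images_per_trial`).
#' @param image_shape integer vector, pixel dimensions of each image.
#' @param exemplars_per_category exemplars generated per category (>= 2, so
#'   every cue has a target and a distinct foil).
#' @param category_signal template contrast in `(0, 1]`: how far category
#'   templates spread around mid-grey.
#' @param noise_sd pixel noise added to each exemplar around its template.
#' @param n_trials number of RSVP trials.
#' @param p_target_absent fraction of trials without a target (default
#'   0.25); the absent count is stratified exactly as `round(n * p)`.
#' @param images_per_trial images per stream (>= 3; the target needs an
#'   interior slot).
#' @param durations_ms presentation-duration labels cycled over trials.
#' @param steps_grid model steps-per-image conditions to simulate.
#' @param n_subjects simulated observers.
#' @param subject_noise_sd standard deviation of per-subject bias on the
#'   logit scale (0 = identical subjects).
#' @param gain slope of the logistic mapping evidence to yes-probability.
#' @param seed master seed for every generator.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_categories = 200L,
                         image_shape = c(8L, 8L),
                         exemplars_per_category = 12L,
                         category_signal = 1,
                         noise_sd = 0.1,
                         n_trials = 176L,
                         p_target_absent = 0.25,
                         images_per_trial = 6L,
                         durations_ms = c(13L, 40L, 80L, 160L),
                         steps_grid = c(1L, 2L, 4L, 8L),
                         n_subjects = 36L,
                         subject_noise_sd = 0.5,
                         gain = 6,
                         seed = 1L) {
  stopifnot_scalar_number(n_categories, "n_categories", lower = 2,
                          integer = TRUE)
  stopifnot_scalar_number(p_target_absent, "p_target_absent", 0, 1)
  stopifnot_scalar_number(images_per_trial, "images_per_trial", lower = 3,
                          integer = TRUE)
  stopifnot_scalar_number(exemplars_per_category, "exemplars_per_category",
                          lower = 2, integer = TRUE)
  if (n_categories < images_per_trial) {
    stop("need at least `images_per_trial` categories", call. = FALSE)
  }
  structure(
    list(n_categories = as.integer(n_categories),
         image_shape = as.integer(image_shape),
         exemplars_per_category = as.integer(exemplars_per_category),
         category_signal = category_signal, noise_sd = noise_sd,
         n_trials = as.integer(n_trials),
         p_target_absent = p_target_absent,
         images_per_trial = as.integer(images_per_trial),
         durations_ms = durations_ms, steps_grid = as.integer(steps_grid),
         n_subjects = as.integer(n_subjects),
         subject_noise_sd = subject_noise_sd, gain = gain,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a labelled toy image bank
#'
#' Each category gets a fixed spatial template — pixel values drawn
#' uniformly in a band of width `category_signal` around mid-grey — and each
#' exemplar is the template plus i.i.d. Gaussian pixel noise, clipped to
#' `[0, 1]`. At zero noise all exemplars of a category are identical and
#' categories are linearly separable by nearest-template matching.
#'
#' @param config a [synth_config()].
#' @return object of class `image_bank`: list with `images` (list of
#'   matrices), `labels` (integer category per image), `templates` (list of
#'   matrices) and `shape`.
#' @export
generate_image_bank <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    npx <- prod(config$image_shape)
    half <- config$category_signal / 2
    templates <- lapply(seq_len(config$n_categories), function(cc) {
      matrix(stats::runif(npx, 0.5 - half, 0.5 + half),
             nrow = config$image_shape[1])
    })
    images <- list()
    labels <- integer(0)
    for (cc in seq_len(config$n_categories)) {
      for (e in seq_len(config$exemplars_per_category)) {
        img <- templates[[cc]] +
          matrix(stats::rnorm(npx, sd = config$noise_sd),
                 nrow = config$image_shape[1])
        images[[length(images) + 1L]] <- pmin(pmax(img, 0), 1)
        labels <- c(labels, cc)
      }
    }
    structure(list(images = images, labels = labels, templates = templates,
                   shape = config$image_shape),
              class = "image_bank")
  })
}

#' @export
print.image_bank <- function(x, ...) {
  cat("Image bank:", length(x$images), "images,",
      length(x$templates), "categories,",
      paste(x$shape, collapse = "x"), "px\n")
  invisible(x)
}

#' Generate an RSVP trial set
#'
#' Builds trials that obey the reference task structure: each trial is a
#' stream of `images_per_trial` images from distinct categories; exactly
#' `round(n_trials * p_target_absent)` trials contain no target (stratified,
#' not sampled); on target-present trials the target occupies a uniformly
#' chosen interior position (never first or last). Every trial's cue
#' category is unique while the bank permits; otherwise uniqueness is
#' relaxed with a warning. Each trial also carries a target and a distinct
#' foil exemplar of the cue category (the pair whose mean readout anchors
#' semantic-relevance ranking), and a presentation-duration label cycled
#' from `durations_ms`.
#'
#' @param config a [synth_config()].
#' @param image_bank an [generate_image_bank()] result.
#' @return object of class `rsvp_trials`: list with `trials` (one record per
#'   trial: `trial_id`, `cue_category`, `categories`, `bank_index`,
#'   `target_present`, `target_position`, `target_bank_index`,
#'   `foil_bank_index`, `duration_ms`) and `config`.
#' @export
generate_rsvp_trials <- function(config, image_bank) {
  stopifnot(inherits(config, "synth_config"),
            inherits(image_bank, "image_bank"))
  n_cats <- length(image_bank$templates)
  m <- config$images_per_trial
  if (n_cats < m) {
    stop("bank must hold at least `images_per_trial` categories",
         call. = FALSE)
  }
  n <- config$n_trials
  with_seed(config$seed + 1L, {
    if (n_cats >= n) {
      cues <- sample(n_cats, n)
    } else {
      warning("fewer categories than trials: cue uniqueness relaxed")
      cues <- sample(rep(seq_len(n_cats), length.out = n))
    }
    n_absent <- round(n * config$p_target_absent)
    absent <- rep(FALSE, n)
    if (n_absent > 0) absent[sample(n, n_absent)] <- TRUE
    durations <- sample(rep(config$durations_ms, length.out = n))
    pick_exemplar <- function(cc, exclude = integer(0)) {
      ix <- setdiff(which(image_bank$labels == cc), exclude)
      if (length(ix) == 1L) ix else sample(ix, 1L)
    }
    trials <- vector("list", n)
    for (i in seq_len(n)) {
      cue <- cues[i]
      target_ix <- pick_exemplar(cue)
      foil_ix <- pick_exemplar(cue, exclude = target_ix)
      if (absent[i]) {
        cats <- sample(setdiff(seq_len(n_cats), cue), m)
        pos <- NA_integer_
        bank_ix <- vapply(cats, pick_exemplar, integer(1))
      } else {
        others <- sample(setdiff(seq_len(n_cats), cue), m - 1L)
        pos <- sample(2:(m - 1L), 1L)
        cats <- append(others, cue, after = pos - 1L)
        bank_ix <- integer(m)
        for (j in seq_len(m)) {
          bank_ix[j] <- if (j == pos) target_ix else pick_exemplar(cats[j])
        }
      }
      trials[[i]] <- list(trial_id = i, cue_category = cue,
                          categories = cats, bank_index = bank_ix,
                          target_present = !absent[i],
                          target_position = pos,
                          target_bank_index = target_ix,
                          foil_bank_index = foil_ix,
                          duration_ms = durations[i])
    }
    structure(list(trials = trials, config = config), class = "rsvp_trials")
  })
}

#' @export
print.rsvp_trials <- function(x, ...) {
  present <- vapply(x$trials, `[[`, logical(1), "target_present")
  cat("RSVP trial set:", length(x$trials), "trials (",
      sum(!present), "target-absent ),",
      x$config$images_per_trial, "images/trial\n")
  invisible(x)
}

#' Audit an RSVP trial set against the task invariants
#'
#' Checks that targets only occupy interior positions, that the
#' target-absent count equals the stratified `round(n * p)`, that every
#' trial's categories are distinct, and that the cue appears in the stream
#' exactly on target-present trials.
#'
#' @param trials an [generate_rsvp_trials()] result.
#' @return invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_trials <- function(trials) {
  stopifnot(inherits(trials, "rsvp_trials"))
  cfg <- trials$config
  m <- cfg$images_per_trial
  n_absent <- 0L
  for (tr in trials$trials) {
    if (anyDuplicated(tr$categories)) {
      stop("trial ", tr$trial_id, ": duplicate categories", call. = FALSE)
    }
    if (tr$target_present) {
      if (is.na(tr$target_position) ||
          tr$target_position < 2L || tr$target_position > m - 1L) {
        stop("trial ", tr$trial_id, ": target not interior", call. = FALSE)
      }
      if (tr$categories[tr$target_position] != tr$cue_category) {
        stop("trial ", tr$trial_id, ": cue not at target position",
             call. = FALSE)
      }
    } else {
      n_absent <- n_absent + 1L
      if (tr$cue_category %in% tr$categories) {
        stop("trial ", tr$trial_id, ": cue present on absent trial",
             call. = FALSE)
      }
    }
  }
  expected_absent <- round(length(trials$trials) * cfg$p_target_absent)
  if (n_absent != expected_absent) {
    stop("target-absent count ", n_absent, " != stratified ",
         expected_absent, call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate an observer panel from latent trial evidence
#'
#' Subject s reports "target present" on trial i with probability
#' `plogis(gain * (evidence_i - center) + bias_s)`, where `bias_s` is a
#' per-subject offset drawn from `N(0, subject_noise_sd)`. With
#' `response = "bernoulli"` reports are sampled; with `"threshold"` a
#' subject answers yes deterministically whenever the probability exceeds
#' 0.5 — so zero subject noise makes all subjects identical. The natural
#' latent evidence is the model's own per-trial PPC, which enables
#' self-consistency analyses where the generating model should approach the
#' panel's noise ceiling.
#'
#' @param evidence numeric latent evidence per trial (finite).
#' @param duration per-trial duration label (length 1 recycled, or one per
#'   trial).
#' @param n_subjects panel size.
#' @param gain logistic slope.
#' @param subject_noise_sd per-subject bias standard deviation.
#' @param response `"bernoulli"` or `"threshold"`.
#' @param center evidence value mapped to probability 0.5 at zero bias
#'   (default: the mean of `evidence`).
#' @param seed RNG seed; the panel is deterministic given it.
#' @return an [observer_reports()] object.
#' @export
generate_observer_panel <- function(evidence, duration = 0L,
                                    n_subjects = 36L, gain = 6,
                                    subject_noise_sd = 0.5,
                                    response = c("bernoulli", "threshold"),
                                    center = NULL, seed = 1L) {
  response <- match.arg(response)
  if (any(!is.finite(evidence))) stop("evidence must be finite",
                                      call. = FALSE)
  n_trials <- length(evidence)
  duration <- rep_len(duration, n_trials)
  if (is.null(center)) center <- mean(evidence)
  with_seed(seed, {
    bias <- stats::rnorm(n_subjects, sd = subject_noise_sd)
    eta <- outer(bias, gain * (evidence - center), `+`)
    p <- stats::plogis(eta)
    R <- if (response == "threshold") {
      (p > 0.5) * 1
    } else {
      matrix(stats::rbinom(length(p), 1L, as.numeric(p)),
             nrow = n_subjects)
    }
    observer_reports(R, duration,
                     trial_ids = names(evidence) %||%
                       as.character(seq_len(n_trials)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
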