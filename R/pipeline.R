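#' Trial-level prototypes and PPC for a synthetic study
#'
#' For every trial, builds the cue-category prototype from the bank's
#' exemplars of that category (each processed in isolation; the readout at
#' the final model step is the exemplar's activation), ranks exemplars by
#' correlation with the mean target/foil readout, averages the top k, then
#' runs the trial's image stream sequentially at every steps-per-image
#' condition, correlates the readout with the prototype at every step, and
#' records the peak prototype correlation.
#'
#' @param network a built [rsvp_network][build_network()].
#' @param image_bank the bank the trials index into.
#' @param trials an [generate_rsvp_trials()] result.
#' @param steps_grid steps-per-image conditions (default from the trials'
#'   config).
#' @param k_prototype exemplars averaged into each prototype (capped at the
#'   per-category exemplar count).
#' @param exemplar_steps model steps an exemplar is presented for when its
#'   activation is recorded.
#' @return a [ppc_table()] with one row per trial x condition, plus
#'   attribute `duration_ms` (per-trial labels, aligned to trial ids).
#' @export
trial_ppc <- function(network, image_bank, trials, steps_grid = NULL,
                      k_prototype = 10L, exemplar_steps = 4L) {
  stopifnot(inherits(network, "rsvp_network"),
            inherits(trials, "rsvp_trials"))
  cfg <- trials$config
  if (is.null(steps_grid)) steps_grid <- cfg$steps_grid
  final_state <- function(bank_ix) {
    tr <- run_single_image(network, image_bank$images[[bank_ix]],
                           exemplar_steps)
    tr$values[nrow(tr$values), ]
  }
  proto_cache <- new.env(parent = emptyenv())
  prototype_for <- function(tr) {
    key <- as.character(tr$cue_category)
    if (!is.null(proto_cache[[key]])) return(proto_cache[[key]])
    ex_ix <- which(image_bank$labels == tr$cue_category)
    acts <- t(vapply(ex_ix, final_state,
                     numeric(network$config$n_categories)))
    ref <- (final_state(tr$target_bank_index) +
              final_state(tr$foil_bank_index)) / 2
    es <- exemplar_set(acts, ref, category_label = tr$cue_category)
    proto <- compute_prototype(es, min(k_prototype, nrow(acts)))
    proto_cache[[key]] <- proto
    proto
  }
  rows <- list()
  for (tr in trials$trials) {
    proto <- prototype_for(tr)
    imgs <- image_bank$images[tr$bank_index]
    for (n_steps in steps_grid) {
      sq <- make_sequence(imgs, n_steps)
      st <- strength_trace(run_sequential(network, sq), proto)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tr$trial_id, steps_per_image = n_steps,
        ppc = peak_prototype_correlation(st),
        target_present = tr$target_present
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- ppc_table(out$trial_id, out$steps_per_image, out$ppc,
                   out$target_present)
  attr(out, "duration_ms") <-
    stats::setNames(vapply(trials$trials, `[[`, numeric(1), "duration_ms"),
                    vapply(trials$trials, `[[`, numeric(1), "trial_id"))
  out
}

#' Sensitivity table over steps-per-image conditions
#'
#' @param ppc a [ppc_table()] spanning one or more conditions.
#' @param adaptation_kind label recorded in the output.
#' @return data frame with columns `adaptation_kind`, `steps_per_image`,
#'   `dprime`, `auc`, `n_present`, `n_absent`.
#' @export
dprime_table <- function(ppc, adaptation_kind = NA_character_) {
  steps <- sort(unique(ppc$steps_per_image))
  do.call(rbind, lapply(steps, function(s) {
    d <- model_dprime(ppc[ppc$steps_per_image == s, , drop = FALSE])
    data.frame(adaptation_kind = adaptation_kind, steps_per_image = s,
               dprime = d$dprime, auc = d$auc,
               n_present = d$n_present, n_absent = d$n_absent)
  }))
}

#' Run the full synthetic RSVP study
#'
#' End-to-end pipeline: image bank, trial set, seeded toy network with the
#' requested adaptation preset, per-trial prototypes and PPC across the
#' steps grid, d' per condition, a simulated observer panel whose latent
#' evidence is the model's own PPC (the condition used for a trial follows
#' its duration rank, giving the panel a built-in temporal correspondence),
#' the bootstrap predictivity profile, per-duration noise ceilings, temporal
#' correspondence and explanatory power.
#'
#' @param config a [synth_config()].
#' @param hidden_sizes network hidden-layer widths.
#' @param adaptation adaptation preset name or [adaptation_params()].
#' @param n_boot subject bootstraps for the predictivity profile.
#' @param k_prototype exemplars per prototype.
#' @param out_dir optional directory: tidy CSVs and a JSON run manifest are
#'   written there.
#' @return list of class `rsvp_run` with components `config`, `network`,
#'   `bank`, `trials`, `ppc`, `dprime`, `reports`, `profile`, `ceilings`,
#'   `temporal`, `explanatory_power`, `warnings`.
#' @export
run_rsvp_study <- function(config = synth_config(),
                           hidden_sizes = c(32L, 32L),
                           adaptation = "powerlaw",
                           n_boot = 200L,
                           k_prototype = 10L,
                           out_dir = NULL) {
  if (is.character(adaptation)) adaptation <- adaptation_preset(adaptation)
  warn <- character(0)
  note <- function(msg) warn <<- c(warn, msg)
  bank <- generate_image_bank(config)
  trials <- withCallingHandlers(
    generate_rsvp_trials(config, bank),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  net <- build_network(network_config(
    input_dim = prod(config$image_shape),
    hidden_sizes = hidden_sizes,
    n_categories = config$n_categories,
    lateral = TRUE, adaptation = adaptation, seed = config$seed
  ))
  calib <- bank$images[seq_len(min(32L, length(bank$images)))]
  net <- freeze_normalization(net, calib)
  ppc <- trial_ppc(net, bank, trials, config$steps_grid, k_prototype)
  dtab <- dprime_table(ppc, net$config$adaptation$kind)

  dur <- attr(ppc, "duration_ms")
  durs_sorted <- sort(unique(config$durations_ms))
  steps_sorted <- sort(unique(config$steps_grid))
  evidence <- vapply(names(dur), function(id) {
    j <- match(dur[[id]], durs_sorted)
    s <- steps_sorted[min(j, length(steps_sorted))]
    ppc$ppc[ppc$trial_id == as.numeric(id) & ppc$steps_per_image == s]
  }, numeric(1))
  reports <- generate_observer_panel(
    evidence, duration = as.numeric(dur),
    n_subjects = config$n_subjects, gain = config$gain,
    subject_noise_sd = config$subject_noise_sd,
    seed = config$seed + 2L
  )
  profile <- withCallingHandlers(
    bootstrap_profile(ppc, reports, n_boot = n_boot,
                      seed = config$seed + 3L),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  ceilings <- noise_ceiling_table(reports)
  temporal <- temporal_correspondence(profile)
  ep <- withCallingHandlers(
    explanatory_power(profile, ceilings),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  run <- structure(
    list(config = config, network = net, bank = bank, trials = trials,
         ppc = ppc, dprime = dtab, reports = reports, profile = profile,
         ceilings = ceilings, temporal = temporal,
         explanatory_power = ep, warnings = warn),
    class = "rsvp_run"
  )
  if (!is.null(out_dir)) write_rsvp_run(run, out_dir)
  run
}

#' @export
print.rsvp_run <- function(x, ...) {
  cat("Synthetic RSVP study (seed", x$config$seed, ")\n")
  cat("  trials   :", length(x$trials$trials), " subjects:",
      nrow(x$reports$reports), "\n")
  cat("  adaptation:", x$network$config$adaptation$kind, "\n")
  cat("  d' by steps/image:\n")
  print(x$dprime[, c("steps_per_image", "dprime", "auc")],
        row.names = FALSE)
  cat("  explanatory power:", format(round(x$explanatory_power$value, 3)),
      "\n")
  invisible(x)
}

#' Write tidy CSV outputs and a JSON manifest for a study run
#'
#' Emits `ppc.csv`, `dprime.csv`, `reports.csv` (subject, trial,
#' duration_ms, response), `profile.csv` (steps_per_image, duration, rho,
#' ci_low, ci_high), `ceilings.csv`, `temporal.csv`, and `manifest.json`
#' echoing the resolved configuration, seed and machine-parsable warning
#' counts.
#'
#' @param run an `rsvp_run`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_rsvp_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  ppc_out <- as.data.frame(run$ppc)
  ppc_out$duration_ms <-
    attr(run$ppc, "duration_ms")[as.character(ppc_out$trial_id)]
  w(ppc_out, "ppc.csv")
  w(run$dprime, "dprime.csv")
  w(reports_to_df(run$reports), "reports.csv")
  w(profile_to_df(run$profile), "profile.csv")
  w(run$ceilings, "ceilings.csv")
  w(run$temporal$best, "temporal.csv")
  manifest <- list(
    package = "rsvpnet",
    seed = run$config$seed,
    config = unclass(run$config),
    adaptation = unclass(run$network$config$adaptation),
    n_boot = run$profile$n_boot,
    explanatory_power = run$explanatory_power$value,
    n_warnings = length(run$warnings),
    warnings = run$warnings
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Tidy data frame of an observer panel
#'
#' @param reports an [observer_reports()].
#' @return data frame with columns `subject`, `trial`, `duration_ms`,
#'   `response`.
#' @export
reports_to_df <- function(reports) {
  n_s <- nrow(reports$reports)
  n_t <- ncol(reports$reports)
  data.frame(
    subject = rep(reports$subject_ids, times = n_t),
    trial = rep(reports$trial_ids, each = n_s),
    duration_ms = rep(reports$duration, each = n_s),
    response = as.integer(reports$reports)
  )
}

#' Rebuild an observer panel from its tidy data frame
#'
#' @param df data frame with columns `subject`, `trial`, `duration_ms`,
#'   `response`.
#' @return an [observer_reports()].
#' @export
reports_from_df <- function(df) {
  need <- c("subject", "trial", "duration_ms", "response")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("reports table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  subj <- unique(df$subject)
  trl <- unique(df$trial)
  R <- matrix(NA_real_, nrow = length(subj), ncol = length(trl))
  R[cbind(match(df$subject, subj), match(df$trial, trl))] <- df$response
  if (anyNA(R)) stop("incomplete subject x trial table", call. = FALSE)
  dur <- df$duration_ms[match(trl, df$trial)]
  observer_reports(R, dur, subject_ids = as.character(subj),
                   trial_ids = as.character(trl))
}

profile_to_df <- function(profile) {
  grid <- expand.grid(steps_per_image = profile$steps,
                      duration = profile$durations)
  grid$rho <- as.numeric(profile$rho)
  grid$ci_low <- as.numeric(profile$ci_low)
  grid$ci_high <- as.numeric(profile$ci_high)
  grid
}

parse_cli_args <- function(args) {
  opts <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        opts[[kv[1]]] <- paste(kv[-1], collapse = "=")
      } else {
        opts[[key]] <- args[[i + 1L]]
        i <- i + 1L
      }
    } else {
      positional <- c(positional, a)
    }
    i <- i + 1L
  }
  list(opts = opts, positional = positional)
}

cli_opt <- function(opts, name, default = NULL) {
  if (!is.null(opts[[name]])) opts[[name]] else default
}

#' Command-line entry point
#'
#' Thin shell interface over the pipeline functions; `inst/cli/rsvpnet.R`
#' wraps it for `Rscript`. Subcommands:
#' \describe{
#'   \item{synth}{generate the synthetic trial set and observer panel;
#'     writes `reports.csv` and a trial audit.}
#'   \item{simulate}{run the network over the synthetic trials; writes
#'     `ppc.csv`.}
#'   \item{analyze}{full study including d' tables, predictivity profile,
#'     ceilings, temporal correspondence and explanatory power.}
#'   \item{compare}{alias of analyze, kept for scripted workflows.}
#' }
#' Common options: `--seed`, `--out` (output directory), `--preset`
#' (`none` / `exponential` / `powerlaw`), `--trials`, `--subjects`,
#' `--boot`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status, invisibly (0 on success); a usage error signals a
#'   condition of class `rsvpnet_usage_error`.
#' @export
rsvp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rsvpnet <synth|simulate|analyze|compare>",
    "[--seed N] [--out DIR] [--preset NAME] [--trials N]",
    "[--subjects N] [--boot N]")
  fail <- function(msg) {
    stop(structure(class = c("rsvpnet_usage_error", "error", "condition"),
                   list(message = paste0(msg, "\n", usage), call = NULL)))
  }
  parsed <- parse_cli_args(args)
  cmd <- parsed$positional[1]
  if (is.na(cmd) || !cmd %in% c("synth", "simulate", "analyze", "compare")) {
    fail("missing or unknown subcommand")
  }
  o <- parsed$opts
  seed <- as.integer(cli_opt(o, "seed", 1L))
  out <- cli_opt(o, "out", "rsvpnet-out")
  preset <- cli_opt(o, "preset", "powerlaw")
  if (!preset %in% c("none", "exponential", "powerlaw")) {
    fail(paste("unknown preset:", preset))
  }
  cfg <- synth_config(
    n_trials = as.integer(cli_opt(o, "trials", 48L)),
    n_subjects = as.integer(cli_opt(o, "subjects", 12L)),
    n_categories = max(48L, as.integer(cli_opt(o, "trials", 48L))),
    seed = seed
  )
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (cmd == "synth") {
    bank <- generate_image_bank(cfg)
    trials <- generate_rsvp_trials(cfg, bank)
    validate_trials(trials)
    df <- do.call(rbind, lapply(trials$trials, function(tr) {
      data.frame(trial_id = tr$trial_id, cue_category = tr$cue_category,
                 target_present = tr$target_present,
                 target_position = tr$target_position,
                 duration_ms = tr$duration_ms)
    }))
    utils::write.csv(df, file.path(out, "trials.csv"), row.names = FALSE)
    message("wrote ", file.path(out, "trials.csv"))
  } else if (cmd == "simulate") {
    bank <- generate_image_bank(cfg)
    trials <- generate_rsvp_trials(cfg, bank)
    net <- build_network(network_config(prod(cfg$image_shape), c(32L, 32L),
                                        cfg$n_categories,
                                        adaptation = adaptation_preset(preset),
                                        seed = seed))
    net <- freeze_normalization(net, bank$images[1:32])
    ppc <- trial_ppc(net, bank, trials)
    utils::write.csv(as.data.frame(ppc), file.path(out, "ppc.csv"),
                     row.names = FALSE)
    message("wrote ", file.path(out, "ppc.csv"))
  } else {
    run <- run_rsvp_study(cfg, adaptation = preset,
                          n_boot = as.integer(cli_opt(o, "boot", 200L)),
                          out_dir = out)
    message("wrote study outputs to ", out,
            " (explanatory power ",
            format(round(run$explanatory_power$value, 3)), ")")
  }
  invisible(0L)
}
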