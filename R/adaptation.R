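#' Adaptation parameters for intrinsic suppression
#'
#' Activation-based intrinsic suppression subtracts a scaled, history-dependent
#' state from a rectified unit's drive. The state follows one or more leaky
#' integrators of the unit's own past activation:
#' `s_t = alpha * s_{t-1} + (1 - alpha) * a_{t-1}`.
#' With a single decay factor the mechanism is exponential adaptation; a sum
#' of several exponentials with different decay factors approximates power-law
#' adaptation, in which case the effective suppression is the sum over
#' channels, scaled by `beta`.
#'
#' @param kind one of `"none"`, `"exponential"`, `"powerlaw"`.
#' @param alphas numeric vector of decay factors, each in `[0, 1)`. Length 1
#'   for `"exponential"`, length >= 2 for `"powerlaw"`. Ignored for `"none"`.
#' @param beta suppression gain, dimensionless, >= 0.
#' @return an object of class `adaptation_params`.
#' @examples
#' adaptation_params("exponential", alphas = 0.96, beta = 0.7)
#' adaptation_preset("powerlaw")
#' @export
adaptation_params <- function(kind = c("none", "exponential", "powerlaw"),
                              alphas = numeric(), beta = 0) {
  kind <- match.arg(kind)
  stopifnot_scalar_number(beta, "beta", lower = 0)
  if (kind == "none") {
    alphas <- numeric()
    beta <- 0
  } else {
    if (!is.numeric(alphas) || length(alphas) < 1L ||
        any(!is.finite(alphas)) || any(alphas < 0) || any(alphas >= 1)) {
      stop("all `alphas` must be finite and strictly in [0, 1)", call. = FALSE)
    }
    if (kind == "exponential" && length(alphas) != 1L) {
      stop("exponential adaptation takes exactly one alpha", call. = FALSE)
    }
    if (kind == "powerlaw" && length(alphas) < 1L) {
      stop("powerlaw adaptation needs at least one alpha", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, alphas = as.numeric(alphas), beta = as.numeric(beta)),
    class = "adaptation_params"
  )
}

#' @export
print.adaptation_params <- function(x, ...) {
  cat("Adaptation parameters\n")
  cat("  kind :", x$kind, "\n")
  if (x$kind != "none") {
    cat("  alpha:", paste(format(x$alphas), collapse = ", "), "\n")
    cat("  beta :", format(x$beta), "\n")
  }
  invisible(x)
}

#' Named adaptation presets
#'
#' `"exponential"` uses alpha = 0.96 with suppression gain beta = 0.7.
#' `"powerlaw"` approximates power-law adaptation as a sum of two
#' exponentials, alphas = (0.96, 0.75), with a much lower gain beta = 0.15 to
#' accommodate the larger summed state. `"none"` disables suppression.
#'
#' @param name preset name: `"none"`, `"exponential"`, or `"powerlaw"`.
#' @return an [adaptation_params()] object.
#' @export
adaptation_preset <- function(name) {
  presets <- list(
    none        = adaptation_params("none"),
    exponential = adaptation_params("exponential", alphas = 0.96, beta = 0.7),
    powerlaw    = adaptation_params("powerlaw", alphas = c(0.96, 0.75),
                                    beta = 0.15)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown adaptation preset: ", paste(name, collapse = ", "),
         " (available: ", paste(names(presets), collapse = ", "), ")",
         call. = FALSE)
  }
  presets[[name]]
}

#' Initialize a suppression state
#'
#' One channel (row) per entry of `alphas`, one column per unit, all zeros.
#'
#' @param params [adaptation_params()].
#' @param n_units number of units in the layer the state wraps.
#' @return numeric matrix `length(alphas) x n_units` (0 x n_units for
#'   `kind = "none"`).
#' @export
adapt_state_init <- function(params, n_units) {
  stopifnot(inherits(params, "adaptation_params"))
  stopifnot_scalar_number(n_units, "n_units", lower = 1, integer = TRUE)
  matrix(0, nrow = length(params$alphas), ncol = n_units)
}

#' One suppression-state update
#'
#' Pure update: returns the new state, leaving the input untouched. Each
#' channel k integrates the previous activation independently:
#' `s_t^(k) = alpha_k * s_{t-1}^(k) + (1 - alpha_k) * a_{t-1}`.
#' With `kind = "exponential"` there is exactly one channel; `kind = "none"`
#' returns the (empty) state unchanged.
#'
#' @param state channel-by-unit matrix from [adapt_state_init()] or a previous
#'   update.
#' @param prev_activation numeric vector of unit activations at the previous
#'   step (length = number of units).
#' @param params [adaptation_params()].
#' @return updated state matrix of the same shape.
#' @export
adapt_step <- function(state, prev_activation, params) {
  stopifnot(inherits(params, "adaptation_params"))
  if (!is.matrix(state) || nrow(state) != length(params$alphas)) {
    stop("state must have one channel (row) per alpha", call. = FALSE)
  }
  if (params$kind == "none") return(state)
  if (ncol(state) != length(prev_activation)) {
    stop("state and prev_activation disagree on the number of units",
         call. = FALSE)
  }
  a <- as.numeric(prev_activation)
  out <- state
  for (k in seq_along(params$alphas)) {
    ak <- params$alphas[k]
    out[k, ] <- ak * state[k, ] + (1 - ak) * a
  }
  out
}

#' Summed suppression across channels
#'
#' The effective (raw, pre-beta) suppression a unit experiences: the sum of
#' its state over channels. Zero everywhere for `kind = "none"`.
#'
#' @param state channel-by-unit state matrix.
#' @return numeric vector, one value per unit.
#' @export
adapt_suppression <- function(state) {
  if (nrow(state) == 0L) return(numeric(ncol(state)))
  colSums(state)
}

#' Apply suppression and rectify
#'
#' Computes `a_t = relu(drive - beta * sum_k s_t^(k))`. The state is stored
#' pre-beta so the gain can be swept without re-simulating; with `beta = 0`
#' or `kind = "none"` this is exactly `relu(drive)`.
#'
#' @param drive numeric vector of pre-activation input (`b + W x_t`, plus any
#'   lateral term), one value per unit.
#' @param state channel-by-unit state matrix (same unit count as `drive`).
#' @param params [adaptation_params()].
#' @return numeric vector of rectified activations.
#' @export
apply_suppression <- function(drive, state, params) {
  stopifnot(inherits(params, "adaptation_params"))
  if (any(!is.finite(drive))) stop("drive must be finite", call. = FALSE)
  if (nrow(state) > 0L && ncol(state) != length(drive)) {
    stop("state and drive disagree on the number of units", call. = FALSE)
  }
  pmax(drive - params$beta * adapt_suppression(state), 0)
}

#' Closed-loop single-unit adaptation trace
#'
#' Simulates one rectified unit from zero suppression state. At each step the
#' activation is computed from the current state, then the state is updated
#' from that activation, so suppression at step t reflects activity strictly
#' before t. For constant drive x > 0 under exponential adaptation the trace
#' converges to the fixed point `a* = s* = x / (1 + beta)`.
#'
#' @param drive_series numeric vector of per-step drive (length >= 1).
#' @param params [adaptation_params()].
#' @return an object of class `unit_trace`: a list with equal-length numeric
#'   vectors `drive`, `suppression` (beta-scaled summed state in effect at
#'   each step) and `activation`.
#' @examples
#' tr <- simulate_unit(rep(1, 200), adaptation_preset("exponential"))
#' tail(tr$activation, 1)  # ~ 1 / 1.7
#' @export
simulate_unit <- function(drive_series, params) {
  stopifnot(inherits(params, "adaptation_params"))
  n <- length(drive_series)
  if (n < 1L) stop("drive_series must have length >= 1", call. = FALSE)
  state <- adapt_state_init(params, 1L)
  drive <- as.numeric(drive_series)
  supp <- numeric(n)
  act <- numeric(n)
  for (t in seq_len(n)) {
    supp[t] <- params$beta * adapt_suppression(state)
    act[t] <- apply_suppression(drive[t], state, params)
    state <- adapt_step(state, act[t], params)
  }
  structure(list(drive = drive, suppression = supp, activation = act),
            class = "unit_trace")
}

#' @export
print.unit_trace <- function(x, ...) {
  cat("Single-unit adaptation trace:", length(x$drive), "steps\n")
  cat("  terminal activation :", format(utils::tail(x$activation, 1)), "\n")
  cat("  terminal suppression:", format(utils::tail(x$suppression, 1)), "\n")
  invisible(x)
}
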