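#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded builders and generators do not disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

#' Midrank Spearman correlation
#'
#' Spearman's rho computed as the Pearson correlation of midranks. Ties get
#' average ranks; no continuity correction. Returns `NA` (the undefined
#' sentinel used throughout the package) when either input is constant.
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar rho in \[-1, 1\], or `NA_real_` if undefined.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y))
}
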