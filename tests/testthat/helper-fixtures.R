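# Shared fixtures: tiny random images and seeded toy networks.

toy_images <- function(n, seed = 1, dim = c(8, 8)) {
  set.seed(seed)
  replicate(n, matrix(runif(prod(dim)), nrow = dim[1]), simplify = FALSE)
}

toy_net <- function(adaptation = adaptation_preset("none"),
                    seed = 1L, lateral = TRUE,
                    hidden = c(16L, 16L), n_categories = 10L,
                    input_dim = 64L, calibrate = TRUE) {
  net <- build_network(network_config(
    input_dim = input_dim, hidden_sizes = hidden,
    n_categories = n_categories, lateral = lateral,
    adaptation = adaptation, seed = seed
  ))
  if (calibrate) {
    net <- freeze_normalization(net, toy_images(8, seed = seed + 500))
  }
  net
}

# Hand-rolled rank-then-Pearson Spearman, kept independent of the package's
# implementation for oracle checks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Textbook Pearson correlation via the covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
}
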