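panel <- function(R, duration = rep(1, ncol(R))) {
  observer_reports(R, duration)
}

test_that("report rates average yes-responses per trial", {
  R <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  rp <- panel(R)
  expect_equal(unname(report_rate(rp)), c(0.75, 0.75, 0))
  expect_equal(unname(report_rate(panel(matrix(1, 5, 2)))), c(1, 1))
  # invariant to subject ordering
  rp2 <- panel(R[c(3, 1, 4, 2), ])
  expect_equal(report_rate(rp), report_rate(rp2))
  expect_error(report_rate(rp, duration = 99), "no trials")
  expect_error(observer_reports(matrix(2, 2, 2), c(1, 1)), "binary")
})

test_that("trial predictivity is midrank Spearman with an NA sentinel", {
  ppc <- c(0.1, 0.3, 0.2, 0.9, 0.5, 0.6)
  expect_equal(trial_predictivity(ppc, plogis(ppc)), 1)
  expect_equal(trial_predictivity(ppc, -ppc), -1)
  set.seed(18)
  for (i in 1:5) {
    x <- rnorm(6); y <- sample(c(0.25, 0.5, 0.5, 0.75, 1, 0))
    expect_equal(trial_predictivity(x, y), oracle_spearman(x, y))
  }
  expect_true(is.na(trial_predictivity(ppc, rep(0.5, 6))))
  expect_error(trial_predictivity(c(1, 2), c(1, 2)), "3 trials")
  # rank property: monotone transforms of PPC leave rho unchanged
  y <- c(0, 0.25, 0.25, 0.5, 1, 0.75)
  r0 <- trial_predictivity(ppc, y)
  expect_equal(trial_predictivity(exp(ppc), y), r0)
  expect_equal(trial_predictivity(10 * ppc - 3, y), r0)
})

test_that("subject bootstrap is reproducible and degenerate when subjects agree", {
  set.seed(19)
  n_tr <- 12
  ppcs <- ppc_table(rep(1:n_tr, 2), rep(c(1, 2), each = n_tr),
                    rnorm(2 * n_tr), rep(c(TRUE, FALSE), n_tr))
  R <- matrix(rep(rbinom(n_tr, 1, 0.5), each = 4), nrow = 4)
  rp <- panel(R, duration = rep(c(13, 40), 6))
  prof <- bootstrap_profile(ppcs, rp, n_boot = 20, seed = 1)
  # identical subjects: every resample reproduces the same profile
  expect_equal(prof$ci_low, prof$rho)
  expect_equal(prof$ci_high, prof$rho)
  # bitwise reproducibility under the same seed
  prof2 <- bootstrap_profile(ppcs, rp, n_boot = 20, seed = 1)
  expect_identical(prof$boot, prof2$boot)
  # n_boot = 1: bounds equal that single resample
  prof1 <- bootstrap_profile(ppcs, rp, n_boot = 1, seed = 2)
  expect_equal(unname(prof1$ci_low), unname(prof1$boot[1, , ]))
  expect_warning(
    bootstrap_profile(ppcs, panel(R[1, , drop = FALSE],
                                  duration = rep(c(13, 40), 6)),
                      n_boot = 2, seed = 1),
    "single subject")
})

test_that("trial resampling is available behind a flag", {
  set.seed(33)
  n_tr <- 15
  ppcs <- ppc_table(1:n_tr, 1, rnorm(n_tr), rep(c(TRUE, FALSE, TRUE), 5))
  R <- matrix(rbinom(4 * n_tr, 1, 0.5), nrow = 4)
  rp <- panel(R)
  prof <- bootstrap_profile(ppcs, rp, n_boot = 10, seed = 4,
                            resample = "trials")
  # replicate b recomputes rho over the drawn trial multiset
  for (b in 1:10) {
    ix <- prof$boot_indices[b, ]
    want <- oracle_spearman(ppcs$ppc[ix], colMeans(R)[ix])
    expect_equal(prof$boot[b, 1, 1], want)
  }
  # subject resampling remains the default
  prof_s <- bootstrap_profile(ppcs, rp, n_boot = 10, seed = 4)
  expect_false(identical(prof$boot, prof_s$boot))
})

test_that("bootstrap replicates match an exhaustive-resample oracle", {
  set.seed(20)
  n_tr <- 9
  ppcs <- ppc_table(1:n_tr, 1, rnorm(n_tr), rep(c(TRUE, FALSE, TRUE), 3))
  R <- matrix(rbinom(3 * n_tr, 1, 0.5), nrow = 3)
  rp <- panel(R)
  prof <- bootstrap_profile(ppcs, rp, n_boot = 25, seed = 3)
  # every possible 3-subject resample, enumerated
  grid <- expand.grid(1:3, 1:3, 1:3)
  all_rhos <- apply(grid, 1, function(ix) {
    oracle_spearman(ppcs$ppc, colMeans(R[ix, , drop = FALSE]))
  })
  for (b in 1:25) {
    ix <- prof$boot_indices[b, ]
    want <- oracle_spearman(ppcs$ppc, colMeans(R[ix, , drop = FALSE]))
    expect_equal(prof$boot[b, 1, 1], want)
    expect_true(any(abs(all_rhos - prof$boot[b, 1, 1]) < 1e-12))
  }
})

test_that("noise ceilings are 1 for identical non-constant observers", {
  R <- matrix(rep(c(1, 0, 1, 1, 0, 0), each = 5), nrow = 5)
  nc <- noise_ceilings(panel(R))
  expect_equal(nc$upper, 1)
  expect_equal(nc$lower, 1)
  expect_error(noise_ceilings(panel(R[1, , drop = FALSE])), "2 subjects")
})

test_that("independent observers have ceilings near zero, lower below upper", {
  set.seed(21)
  R <- matrix(rbinom(60 * 200, 1, 0.5), nrow = 60)
  nc <- noise_ceilings(panel(R))
  expect_lt(abs(nc$lower), 3 / sqrt(200))
  # the upper ceiling keeps the focal subject in the average (small positive
  # bias ~ 1/sqrt(n_subjects)); lower must sit below it on average
  mean_gap <- mean(replicate(5, {
    Ri <- matrix(rbinom(8 * 80, 1, 0.5), nrow = 8)
    nci <- noise_ceilings(panel(Ri))
    nci$upper - nci$lower
  }))
  expect_gt(mean_gap, 0)
})

test_that("noise ceilings are computed per duration", {
  set.seed(22)
  R <- cbind(matrix(rep(rbinom(10, 1, 0.5), each = 4), nrow = 4),
             matrix(rbinom(40, 1, 0.5), nrow = 4))
  rp <- panel(R, duration = rep(c(13, 80), each = 10))
  tab <- noise_ceiling_table(rp)
  expect_equal(tab$duration, c(13, 80))
  expect_equal(tab$upper[1], 1)       # identical halves agree perfectly
  expect_lt(tab$upper[2], 1)
  single <- noise_ceilings(rp, 13)
  expect_equal(single$upper, tab$upper[1])
})

test_that("temporal correspondence takes the earliest best step", {
  rho <- matrix(c(0.1, 0.2, 0.3,
                  0.3, 0.3, 0.1), nrow = 3,
                dimnames = list(steps = 1:3, duration = c(13, 40)))
  prof <- structure(list(rho = rho, steps = c(1L, 2L, 4L),
                         durations = c(13, 40), boot = NULL, n_boot = 0L),
                    class = "predictivity_profile")
  tc <- temporal_correspondence(prof)
  expect_equal(tc$best$best_step, c(4L, 1L))   # increasing column; tie -> 1
  expect_equal(tc$best$rho, c(0.3, 0.3))
  # single available step
  prof1 <- structure(list(rho = rho[1, , drop = FALSE], steps = 2L,
                          durations = c(13, 40), boot = NULL, n_boot = 0L),
                     class = "predictivity_profile")
  expect_equal(temporal_correspondence(prof1)$best$best_step, c(2L, 2L))
})

test_that("explanatory power is the mean ceiling-normalized best rho", {
  rho <- matrix(c(0.3, 0.1, 0.2, 0.6), nrow = 2,
                dimnames = list(steps = 1:2, duration = c(13, 40)))
  prof <- structure(list(rho = rho, steps = c(1L, 2L),
                         durations = c(13, 40), boot = NULL, n_boot = 0L),
                    class = "predictivity_profile")
  ceil <- data.frame(duration = c(13, 40), lower = c(0.6, 0.6))
  ep <- explanatory_power(prof, ceil)
  expect_equal(ep$value, 0.75)          # (0.3/0.6 + 0.6/0.6) / 2
  # matching ceilings everywhere give exactly 1
  ceil2 <- data.frame(duration = c(13, 40), lower = c(0.3, 0.6))
  expect_equal(explanatory_power(prof, ceil2)$value, 1)
  # halved rho gives 0.5
  prof$rho <- rho / 2
  expect_equal(explanatory_power(prof, ceil2)$value, 0.5)
  # non-positive ceilings are excluded with a warning
  ceil3 <- data.frame(duration = c(13, 40), lower = c(-0.1, 0.6))
  expect_warning(ep3 <- explanatory_power(prof, ceil3), "non-positive")
  expect_equal(ep3$value, 0.3 / 0.6)
  expect_error(explanatory_power(prof, data.frame(duration = 13, lower = 1)),
               "missing")
})
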