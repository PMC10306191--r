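test_that("identically seeded builds are deterministic", {
  imgs <- toy_images(3, seed = 9)
  sq <- make_sequence(imgs, 3)
  t1 <- run_sequential(toy_net(seed = 5), sq)
  t2 <- run_sequential(toy_net(seed = 5), sq)
  expect_identical(t1$values, t2$values)
  t3 <- run_sequential(toy_net(seed = 6), sq)
  expect_false(identical(t1$values, t3$values))
})

test_that("zero-gain adaptation equals no adaptation bitwise", {
  imgs <- toy_images(4, seed = 2)
  sq <- make_sequence(imgs, 4)
  net0 <- toy_net(adaptation_params("none"), seed = 3)
  netb <- toy_net(adaptation_params("exponential", 0.96, 0), seed = 3)
  expect_identical(run_sequential(net0, sq)$values,
                   run_sequential(netb, sq)$values)
})

test_that("an identity single-layer net reproduces its input", {
  net <- build_network(network_config(4, 4, 4, lateral = FALSE,
                                      seed = 1))
  net$layers[[1]]$W <- diag(4)
  net$layers[[1]]$b <- rep(0, 4)
  net$W_out <- diag(4)
  x <- matrix(c(0.1, 0.9, 0.4, 0.7), 2)
  tr <- run_single_image(net, x, 1)
  expect_equal(tr$values[1, ], as.numeric(x))
})

test_that("sequence construction tiles steps without gaps", {
  sq <- make_sequence(toy_images(6), 4)
  expect_equal(sq$n_steps, 24)
  expect_equal(make_sequence(toy_images(1), 1)$n_steps, 1)
  sq3 <- make_sequence(toy_images(3), 2)
  expect_equal(sq3$step_to_image, c(1, 1, 2, 2, 3, 3))
  expect_equal(sq3$boundaries$first_step, c(1, 3, 5))
  expect_equal(sq3$boundaries$last_step, c(2, 4, 6))
  bad <- list(matrix(0, 2, 2), matrix(0, 3, 3))
  expect_error(make_sequence(bad, 2), "shape")
  expect_error(make_sequence(list(), 2), "non-empty")
})

test_that("single-image runs equal one-image sequential runs", {
  net <- toy_net(adaptation_preset("powerlaw"), seed = 4)
  img <- toy_images(1, seed = 13)[[1]]
  expect_identical(run_single_image(net, img, 5)$values,
                   run_sequential(net, make_sequence(list(img), 5))$values)
})

test_that("a stateless network is memoryless; recurrence carries history", {
  imgs <- toy_images(2, seed = 21)
  # no lateral weights, no adaptation: repeated frames give identical rows
  ff <- toy_net(lateral = FALSE, seed = 8)
  tr <- run_sequential(ff, make_sequence(imgs[1], 4))
  for (t in 2:4) expect_equal(tr$values[t, ], tr$values[1, ])
  # and the sequential run equals concatenated single-image runs
  seq_tr <- run_sequential(ff, make_sequence(imgs, 3))
  cat_tr <- rbind(run_single_image(ff, imgs[[1]], 3)$values,
                  run_single_image(ff, imgs[[2]], 3)$values)
  expect_equal(seq_tr$values, cat_tr)
  # with recurrence, image B's response differs when A preceded it
  rec <- toy_net(lateral = TRUE, seed = 8)
  with_A <- run_sequential(rec, make_sequence(imgs, 3))$values[4:6, ]
  fresh <- run_single_image(rec, imgs[[2]], 3)$values
  expect_false(isTRUE(all.equal(with_A, fresh)))
  # same for adaptation without recurrence
  ad <- toy_net(adaptation_preset("exponential"), lateral = FALSE, seed = 8)
  with_A2 <- run_sequential(ad, make_sequence(imgs, 3))$values[4:6, ]
  fresh2 <- run_single_image(ad, imgs[[2]], 3)$values
  expect_false(isTRUE(all.equal(with_A2, fresh2)))
})

test_that("the readout is linear: scaling weights scales outputs", {
  net <- toy_net(seed = 10)
  img <- toy_images(1, seed = 3)[[1]]
  y1 <- run_single_image(net, img, 4)$values
  net$W_out <- 2 * net$W_out
  y2 <- run_single_image(net, img, 4)$values
  expect_equal(y2, 2 * y1)
})

test_that("reset removes history: order independence of single-image runs", {
  net <- toy_net(adaptation_preset("exponential"), seed = 12)
  imgs <- toy_images(2, seed = 30)
  a_then_b <- run_single_image(net, imgs[[2]], 3)$values
  # run the other image first; fresh-state run of B must be unchanged
  invisible(run_single_image(net, imgs[[1]], 3))
  b_alone <- run_single_image(net, imgs[[2]], 3)$values
  expect_identical(a_then_b, b_alone)
})

test_that("trace export is tidy and conserves step count", {
  sq <- make_sequence(toy_images(3), 2)
  tr <- run_sequential(toy_net(), sq)
  expect_equal(nrow(tr$values), sq$n_steps)
  df <- as.data.frame(tr)
  expect_named(df, c("step", "image_index", "category", "activation"))
  expect_equal(nrow(df), sq$n_steps * 10)
  expect_equal(df$activation[df$step == 2 & df$category == 3],
               tr$values[2, 3])
})

test_that("shape mismatches and bad configs error early", {
  net <- toy_net()
  expect_error(run_sequential(net, make_sequence(toy_images(2, dim = c(4, 4)), 2)),
               "input")
  expect_error(network_config(64, integer(0), 5), "hidden layer")
  expect_error(network_config(64, 16, 1), "n_categories")
})
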