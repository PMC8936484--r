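make_smooth_reference <- function(n = 101) {
  t <- seq(0, 1, length.out = n)
  states <- cbind(S = 0.2 + 0.8 * t^2, I = 0.7 * exp(-t), P = 0.6 + 0.1 *
                    sin(2 * t))
  structure(list(times = t, states = states, nu = NA_real_, meta = list()),
            class = "eco_trajectory")
}

test_that("forward pass matches hand-computed values", {
  zero <- mlp_weights(rep(0, 10), rep(0, 10), matrix(0, 3, 10), rep(0, 3))
  expect_equal(unname(mlp_forward(zero, c(-1, 0, 2))),
               matrix(0, 3, 3))
  one_unit <- mlp_weights(1, 0, matrix(1, 1, 1), 0)
  expect_equal(mlp_forward(one_unit, 0)[1, 1], 0)
  expect_equal(mlp_forward(one_unit, 1)[1, 1], tanh(1))
  expect_equal(mlp_forward(one_unit, 1)[1, 1], 0.761594, tolerance = 1e-6)
})

test_that("weights flatten and restore losslessly in the documented order", {
  set.seed(3)
  w <- mlp_weights(rnorm(10), rnorm(10), matrix(rnorm(30), 3, 10), rnorm(3))
  v <- flatten_weights(w)
  expect_length(v, 53)
  expect_equal(unflatten_weights(v), w)
  # ordering: input weights first, output biases last
  expect_identical(v[1:10], w$input_weights)
  expect_identical(v[51:53], w$output_biases)
})

test_that("min-max normalization maps endpoints and round-trips", {
  m <- fit_normalization(list(c(0, 0.25, 1)))
  expect_equal(apply_normalization(m, 0.5), 0)
  expect_equal(apply_normalization(m, 1), 1)
  expect_equal(apply_normalization(m, 0), -1)
  set.seed(5)
  x <- matrix(runif(30, -3, 7), 10, 3)
  m2 <- fit_normalization(x)
  expect_equal(invert_normalization(m2, apply_normalization(m2, x)), x,
               tolerance = 1e-12)
  expect_error(fit_normalization(list(rep(2, 5))), "degenerate")
})

test_that("split sizes follow the round-half-away rule and cover all nodes", {
  sp <- split_indices(101, seed = 7)
  expect_length(sp$train_idx, 76)
  expect_length(sp$val_idx, 10)
  expect_length(sp$test_idx, 15)
  sp20 <- split_indices(20, seed = 7)
  expect_equal(lengths(sp20[c("train_idx", "val_idx", "test_idx")]),
               c(train_idx = 15L, val_idx = 2L, test_idx = 3L))
  for (seed in 1:20) {
    sp <- split_indices(101, seed = seed)
    all_idx <- c(sp$train_idx, sp$val_idx, sp$test_idx)
    expect_identical(sort(all_idx), 1:101)  # disjoint and exhaustive
  }
  expect_identical(split_indices(101, seed = 3), split_indices(101, seed = 3))
  expect_error(split_indices(101, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("splitting does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(split_indices(101, seed = 99))
  expect_identical(runif(1), a)
})

test_that("a constant-plus-linear target is fitted almost exactly", {
  t <- seq(0, 1, length.out = 50)
  states <- cbind(2 + t, 1 - 0.5 * t, 0.3 + 0.2 * t)
  ref <- structure(list(times = t, states = states, nu = NA_real_,
                        meta = list()), class = "eco_trajectory")
  # tanh units realize a linear map only in their small-weight regime, so
  # "almost exactly" here means well below the noise floor of real fits
  fit <- train_surrogate(ref, seed = 1)
  best <- fit$record$val_mse[fit$record$best_epoch + 1]
  expect_lt(best, 1e-5)
})

test_that("max_epochs = 0 returns the initial weights and a length-1 record", {
  ref <- make_smooth_reference()
  fit <- train_surrogate(ref, seed = 4, settings = scg_settings(max_epochs = 0))
  expect_length(fit$record$train_mse, 1)
  expect_equal(fit$record$best_epoch, 0L)
  expect_equal(flatten_weights(fit$weights),
               flatten_weights(init_weights_nw(seed = 4)))
})

test_that("returned weights reproduce the recorded best validation MSE", {
  ref <- make_smooth_reference()
  for (seed in c(0, 5, 9)) {
    fit <- train_surrogate(ref, seed = seed)
    rec <- fit$record
    tn <- apply_normalization(fit$norm$input, ref$times, channels = 1)
    Yn <- apply_normalization(fit$norm$output, ref$states)
    val_mse <- mean_squared_error(
      mlp_forward(fit$weights, tn[fit$split$val_idx]),
      Yn[fit$split$val_idx, ])
    expect_equal(val_mse, rec$val_mse[rec$best_epoch + 1], tolerance = 1e-12)
    expect_equal(rec$best_epoch, which.min(rec$val_mse) - 1L)
  }
})

test_that("training is bit-identical for a fixed seed", {
  ref <- make_smooth_reference()
  f1 <- train_surrogate(ref, seed = 8)
  f2 <- train_surrogate(ref, seed = 8)
  expect_identical(f1$record, f2$record)
  expect_identical(flatten_weights(f1$weights), flatten_weights(f2$weights))
})

test_that("a smooth 3-channel target reaches training MSE 1e-4 within 10 seeds", {
  ref <- make_smooth_reference()
  best <- min(sapply(0:9, function(s) {
    fit <- train_surrogate(ref, seed = s)
    fit$record$train_mse[fit$record$best_epoch + 1]
  }))
  expect_lt(best, 1e-4)
})

test_that("prediction denormalizes and flags extrapolation", {
  ref <- make_smooth_reference()
  fit <- train_surrogate(ref, seed = 2)
  pred <- predict_trajectory(fit, ref$times)
  expect_false(pred$meta$extrapolation)
  expect_equal(dim(pred$states), dim(ref$states))
  # zero network predicts the per-channel midpoint everywhere
  fit0 <- fit
  fit0$weights <- mlp_weights(rep(0, 10), rep(0, 10), matrix(0, 3, 10),
                              rep(0, 3))
  mid <- (fit$norm$output$min + fit$norm$output$max) / 2
  expect_equal(unname(predict_trajectory(fit0, c(0.2, 0.8))$states),
               matrix(mid, 2, 3, byrow = TRUE), tolerance = 1e-12)
  expect_true(predict_trajectory(fit, c(-0.5, 0.5))$meta$extrapolation)
})

test_that("surrogate JSON serialization round-trips predictions", {
  ref <- make_smooth_reference()
  fit <- train_surrogate(ref, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate_json(fit, path)
  back <- read_surrogate_json(path)
  expect_equal(predict_trajectory(back, ref$times)$states,
               predict_trajectory(fit, ref$times)$states, tolerance = 1e-12)
})
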