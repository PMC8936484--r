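#' Network weights of the 1 x 10 x 3 surrogate
#'
#' The surrogate is a single-hidden-layer feedforward network: one scalar
#' input (time), `n_hidden` tanh units and three linear outputs (one per
#' state channel). All parameters flatten to a single vector with the fixed
#' ordering: input weights (10), hidden biases (10), output weights
#' (3 x 10, row-major by output channel), output biases (3) - 53 values for
#' the default architecture.
#'
#' @param input_weights Numeric vector of hidden-layer input weights.
#' @param hidden_biases Numeric vector, same length.
#' @param output_weights Numeric matrix, `n_out` x `n_hidden`.
#' @param output_biases Numeric vector of length `n_out`.
#' @return An object of class `mlp_weights`.
#' @export
mlp_weights <- function(input_weights, hidden_biases, output_weights,
                        output_biases) {
  input_weights <- as.numeric(input_weights)
  hidden_biases <- as.numeric(hidden_biases)
  output_weights <- as.matrix(output_weights)
  output_biases <- as.numeric(output_biases)
  h <- length(input_weights)
  stopifnot(length(hidden_biases) == h, ncol(output_weights) == h,
            nrow(output_weights) == length(output_biases))
  vals <- c(input_weights, hidden_biases, as.numeric(t(output_weights)),
            output_biases)
  if (any(!is.finite(vals))) {
    stop("all network parameters must be finite", call. = FALSE)
  }
  structure(list(input_weights = input_weights,
                 hidden_biases = hidden_biases,
                 output_weights = output_weights,
                 output_biases = output_biases),
            class = "mlp_weights")
}

#' Flatten network weights to a parameter vector
#'
#' @param weights An [mlp_weights()] object.
#' @return Numeric vector in the documented ordering (input weights, hidden
#'   biases, output weights row-major, output biases).
#' @export
flatten_weights <- function(weights) {
  c(weights$input_weights, weights$hidden_biases,
    as.numeric(t(weights$output_weights)), weights$output_biases)
}

#' Restore network weights from a parameter vector
#'
#' @param w Numeric vector produced by [flatten_weights()].
#' @param n_hidden Number of hidden units (default 10).
#' @param n_out Number of output channels (default 3).
#' @return An [mlp_weights()] object.
#' @export
unflatten_weights <- function(w, n_hidden = 10L, n_out = 3L) {
  stopifnot(length(w) == 2L * n_hidden + n_out * n_hidden + n_out)
  iw <- w[seq_len(n_hidden)]
  hb <- w[n_hidden + seq_len(n_hidden)]
  ow <- matrix(w[2L * n_hidden + seq_len(n_out * n_hidden)],
               nrow = n_out, ncol = n_hidden, byrow = TRUE)
  ob <- w[2L * n_hidden + n_out * n_hidden + seq_len(n_out)]
  mlp_weights(iw, hb, ow, ob)
}

#' Forward pass of the surrogate network
#'
#' Computes, for each input \eqn{t} and output channel \eqn{k},
#' \deqn{y_k(t) = b_k + \sum_j v_{kj} \tanh(w_j t + c_j).}
#' Inputs and outputs are in normalized coordinates; see
#' [fit_normalization()].
#'
#' @param weights An [mlp_weights()] object.
#' @param t Numeric vector of (normalized) input values.
#' @return Numeric matrix, `length(t)` x `n_out`.
#' @export
#' @examples
#' w <- mlp_weights(1, 0, matrix(1, 1, 1), 0)
#' mlp_forward(w, 1)  # tanh(1)
mlp_forward <- function(weights, t) {
  if (any(!is.finite(t))) {
    stop("non-finite input passed to mlp_forward", call. = FALSE)
  }
  z <- tanh(outer(as.numeric(t), weights$input_weights) +
              matrix(weights$hidden_biases, nrow = length(t),
                     ncol = length(weights$hidden_biases), byrow = TRUE))
  sweep(z %*% t(weights$output_weights), 2L, weights$output_biases, "+")
}

#' Fit per-channel min-max normalization maps
#'
#' Each channel is mapped affinely so that its observed minimum goes to -1
#' and its maximum to +1 (the convention of MATLAB's `mapminmax`, which the
#' fitting-tool workflow is built on).
#'
#' @param values A list of numeric vectors (or a matrix, one channel per
#'   column).
#' @return An object of class `minmax_map` holding per-channel `min` and
#'   `max`.
#' @export
fit_normalization <- function(values) {
  if (is.matrix(values)) values <- lapply(seq_len(ncol(values)),
                                          function(j) values[, j])
  mins <- vapply(values, min, numeric(1))
  maxs <- vapply(values, max, numeric(1))
  if (any(maxs <= mins)) {
    stop("degenerate channel range: max must exceed min for every channel",
         call. = FALSE)
  }
  structure(list(min = mins, max = maxs), class = "minmax_map")
}

#' Apply a min-max normalization map
#'
#' @param map A `minmax_map` from [fit_normalization()].
#' @param x Numeric vector or matrix (one channel per column).
#' @param channels Which channels of the map to use (default all, in order).
#' @return Normalized values in `[-1, 1]` (for in-range inputs), same shape
#'   as `x`.
#' @export
apply_normalization <- function(map, x, channels = seq_along(map$min)) {
  lo <- map$min[channels]; hi <- map$max[channels]
  if (is.matrix(x)) {
    sweep(sweep(x, 2L, lo, "-"), 2L, hi - lo, "/") * 2 - 1
  } else {
    2 * (x - lo) / (hi - lo) - 1
  }
}

#' Invert a min-max normalization map
#'
#' @inheritParams apply_normalization
#' @param y Normalized values.
#' @return Values on the original scale.
#' @export
invert_normalization <- function(map, y, channels = seq_along(map$min)) {
  lo <- map$min[channels]; hi <- map$max[channels]
  if (is.matrix(y)) {
    sweep(sweep((y + 1) / 2, 2L, hi - lo, "*"), 2L, lo, "+")
  } else {
    (y + 1) / 2 * (hi - lo) + lo
  }
}

round_half_away <- function(x) floor(x + 0.5)

#' Seeded random train/validation/test split
#'
#' Partitions `1..n_points` into disjoint, exhaustive train / validation /
#' test index sets by a uniformly random permutation under the seed.
#' Validation and test sizes are `round(n * fraction)` with ties rounded
#' half away from zero; training absorbs the remainder, so 101 points under
#' the 75/10/15 rule give sizes 76/10/15.
#'
#' @param n_points Number of data points (>= 3).
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1
#'   (default `c(0.75, 0.10, 0.15)`).
#' @param seed Integer seed; fixed seed gives identical splits.
#' @return An object of class `data_split` with `train_idx`, `val_idx`,
#'   `test_idx` and `seed`.
#' @export
#' @examples
#' sp <- split_indices(101, seed = 1)
#' lengths(sp[c("train_idx", "val_idx", "test_idx")])
split_indices <- function(n_points, fractions = c(0.75, 0.10, 0.15),
                          seed = 0L) {
  stopifnot(n_points >= 3)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  n_val <- as.integer(round_half_away(n_points * fractions[2L]))
  n_test <- as.integer(round_half_away(n_points * fractions[3L]))
  n_train <- n_points - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L) {
    stop("split sizes degenerate for n_points = ", n_points, call. = FALSE)
  }
  perm <- with_local_seed(seed, sample.int(n_points))
  structure(list(train_idx = sort(perm[seq_len(n_train)]),
                 val_idx = sort(perm[n_train + seq_len(n_val)]),
                 test_idx = sort(perm[n_train + n_val + seq_len(n_test)]),
                 seed = as.integer(seed)),
            class = "data_split")
}

# Runs expr under a temporary RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Nguyen-Widrow initial weights for the surrogate
#'
#' Hidden-layer input weights have magnitude \eqn{0.7 H^{1/n_{in}}} with
#' random signs; hidden biases are spread uniformly over the active input
#' range, the standard Nguyen-Widrow recipe for fast tanh-layer coverage.
#' Output-layer weights and biases are uniform on \eqn{[-0.5, 0.5]}.
#'
#' @param n_hidden Hidden units (default 10).
#' @param n_out Output channels (default 3).
#' @param seed Integer seed.
#' @return An [mlp_weights()] object.
#' @export
init_weights_nw <- function(n_hidden = 10L, n_out = 3L, seed = 0L) {
  with_local_seed(seed, {
    beta <- 0.7 * n_hidden^(1)  # one input: H^(1/1)
    signs <- sample(c(-1, 1), n_hidden, replace = TRUE)
    iw <- beta * signs
    hb <- beta * seq(-1, 1, length.out = n_hidden) * signs
    ow <- matrix(stats::runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden)
    ob <- stats::runif(n_out, -0.5, 0.5)
    mlp_weights(iw, hb, ow, ob)
  })
}

# MSE objective and gradient of the network on (t, Y) pairs, both in
# normalized space; standard backprop, vectorized over the batch.
mlp_mse_objective <- function(t, Y, n_hidden, n_out) {
  n <- length(t)
  force(Y)
  function(w) {
    iw <- w[seq_len(n_hidden)]
    hb <- w[n_hidden + seq_len(n_hidden)]
    ow <- matrix(w[2L * n_hidden + seq_len(n_out * n_hidden)],
                 nrow = n_out, ncol = n_hidden, byrow = TRUE)
    ob <- w[2L * n_hidden + n_out * n_hidden + seq_len(n_out)]
    z <- outer(t, iw) + matrix(hb, n, n_hidden, byrow = TRUE)
    a <- tanh(z)                       # n x H
    pred <- a %*% t(ow) + matrix(ob, n, n_out, byrow = TRUE)
    resid <- pred - Y                  # n x K
    value <- sum(resid^2) / (n * n_out)
    scale <- 2 / (n * n_out)
    g_ow <- scale * t(resid) %*% a     # K x H
    g_ob <- scale * colSums(resid)
    back <- (resid %*% ow) * (1 - a^2) # n x H
    g_iw <- scale * as.numeric(crossprod(back, t))
    g_hb <- scale * colSums(back)
    list(value = value,
         gradient = c(g_iw, g_hb, as.numeric(t(g_ow)), g_ob))
  }
}

#' Train the neural surrogate on a reference trajectory
#'
#' The end-to-end fitting pipeline: (1) fit min-max normalization on the
#' full dataset (time input plus the three state channels); (2) split the
#' grid nodes 75/10/15 into train/validation/test under the seed; (3)
#' initialize a 1 x `n_hidden` x 3 tanh network by the Nguyen-Widrow rule;
#' (4) minimize the training-split MSE (in normalized space) with
#' [minimize_scg()], monitoring validation MSE after every epoch; (5) stop
#' early once validation MSE has failed to improve for `max_val_fail`
#' consecutive epochs (or on the optimizer's own criteria); (6) return the
#' weight snapshot of the best-validation epoch. Reported MSE values are in
#' normalized space, the convention of the MATLAB fitting tool this
#' workflow mirrors.
#'
#' @param reference An `eco_trajectory` (>= 3 nodes), e.g. from
#'   [reference_solution()].
#' @param seed Integer seed controlling the split and the initial weights.
#' @param settings An [scg_settings()] object.
#' @param max_val_fail Consecutive validation failures tolerated before
#'   stopping (default 6, the fitting-tool default).
#' @param n_hidden Hidden units (default 10).
#' @param fractions Split fractions (default `c(0.75, 0.10, 0.15)`).
#'
#' @return An object of class `surrogate_fit`: list with `weights`
#'   (best-epoch [mlp_weights()]), `norm` (input/output `minmax_map`s),
#'   `split` ([split_indices()] result), and `record`: per-epoch `train_mse`,
#'   `val_mse`, `test_mse`, `grad_norm` vectors (epoch 0 = initial weights),
#'   `best_epoch` (0-based, argmin of validation MSE), `stop_epoch`,
#'   `stop_reason`, and `final_grad_norm`.
#' @export
train_surrogate <- function(reference, seed = 0L, settings = scg_settings(),
                            max_val_fail = 6L, n_hidden = 10L,
                            fractions = c(0.75, 0.10, 0.15)) {
  times <- reference$times
  states <- reference$states
  n <- length(times)
  stopifnot(n >= 3L, nrow(states) == n)
  n_out <- ncol(states)

  norm_in <- fit_normalization(list(times))
  norm_out <- fit_normalization(states)
  tn <- apply_normalization(norm_in, times, channels = 1L)
  Yn <- apply_normalization(norm_out, states)

  split <- split_indices(n, fractions = fractions, seed = seed)
  obj_train <- mlp_mse_objective(tn[split$train_idx],
                                 Yn[split$train_idx, , drop = FALSE],
                                 n_hidden, n_out)
  obj_val <- mlp_mse_objective(tn[split$val_idx],
                               Yn[split$val_idx, , drop = FALSE],
                               n_hidden, n_out)
  obj_test <- mlp_mse_objective(tn[split$test_idx],
                                Yn[split$test_idx, , drop = FALSE],
                                n_hidden, n_out)

  w0 <- flatten_weights(init_weights_nw(n_hidden, n_out, seed = seed))

  env <- new.env(parent = emptyenv())
  env$train <- obj_train(w0)$value
  env$val <- obj_val(w0)$value
  env$test <- obj_test(w0)$value
  env$best_val <- env$val
  env$best_epoch <- 0L
  env$best_w <- w0
  env$fails <- 0L
  monitor <- function(iter, w, value, grad_norm) {
    v <- obj_val(w)$value
    env$train <- c(env$train, value)
    env$val <- c(env$val, v)
    env$test <- c(env$test, obj_test(w)$value)
    # strict comparison both ways: an epoch that leaves validation MSE
    # exactly at the best so far (e.g. a rejected optimizer step) neither
    # resets nor advances the failure count
    if (v < env$best_val) {
      env$best_val <- v
      env$best_epoch <- iter
      env$best_w <- w
      env$fails <- 0L
    } else if (v > env$best_val) {
      env$fails <- env$fails + 1L
    }
    env$fails >= max_val_fail
  }

  fit <- minimize_scg(obj_train, w0, settings, callback = monitor)
  record <- list(train_mse = env$train,
                 val_mse = env$val,
                 test_mse = env$test,
                 grad_norm = fit$trace$grad_norm_history,
                 best_epoch = env$best_epoch,
                 stop_epoch = fit$trace$iterations,
                 stop_reason = if (fit$trace$stop_reason ==
                                     "external-callback")
                   "validation-stop" else fit$trace$stop_reason,
                 final_grad_norm =
                   fit$trace$grad_norm_history[
                     length(fit$trace$grad_norm_history)])
  structure(list(weights = unflatten_weights(env$best_w, n_hidden, n_out),
                 norm = list(input = norm_in, output = norm_out),
                 split = split,
                 record = record,
                 n_hidden = n_hidden,
                 seed = as.integer(seed)),
            class = "surrogate_fit")
}

#' Evaluate a trained surrogate on a time grid
#'
#' Normalizes the input times, runs the forward pass and maps the outputs
#' back to physical units. Times outside the trained input range are
#' evaluated as-is and flagged as extrapolation in the returned `meta`.
#'
#' @param fit A `surrogate_fit` from [train_surrogate()] (or pass `weights`
#'   and `norm` explicitly).
#' @param times Numeric vector of evaluation times.
#' @return An `eco_trajectory` with the surrogate states, comparable
#'   node-wise with the reference.
#' @export
predict_trajectory <- function(fit, times) {
  norm <- fit$norm
  tn <- apply_normalization(norm$input, times, channels = 1L)
  Yn <- mlp_forward(fit$weights, tn)
  Y <- invert_normalization(norm$output, Yn)
  extrap <- any(times < norm$input$min[1L] - 1e-12) ||
    any(times > norm$input$max[1L] + 1e-12)
  if (ncol(Y) == 3L) colnames(Y) <- c("S", "I", "P")
  structure(list(times = as.numeric(times), states = Y, nu = NA_real_,
                 meta = list(source = "surrogate",
                             extrapolation = extrap)),
            class = "eco_trajectory")
}

#' Serialize a trained surrogate to JSON
#'
#' Writes weight arrays, normalization ranges, the split seed and a record
#' summary; [read_surrogate_json()] restores an equivalent fit object.
#'
#' @param fit A `surrogate_fit`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_surrogate_json <- function(fit, path) {
  obj <- list(n_hidden = fit$n_hidden,
              seed = fit$seed,
              input_weights = fit$weights$input_weights,
              hidden_biases = fit$weights$hidden_biases,
              output_weights = fit$weights$output_weights,
              output_biases = fit$weights$output_biases,
              norm_input = list(min = fit$norm$input$min,
                                max = fit$norm$input$max),
              norm_output = list(min = fit$norm$output$min,
                                 max = fit$norm$output$max),
              best_epoch = fit$record$best_epoch,
              stop_epoch = fit$record$stop_epoch,
              stop_reason = fit$record$stop_reason)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a surrogate from JSON
#'
#' @param path File written by [write_surrogate_json()].
#' @return A list usable by [predict_trajectory()] (`weights` + `norm`).
#' @export
read_surrogate_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(weights = mlp_weights(obj$input_weights, obj$hidden_biases,
                             obj$output_weights, obj$output_biases),
       norm = list(input = structure(list(min = obj$norm_input$min,
                                          max = obj$norm_input$max),
                                     class = "minmax_map"),
                   output = structure(list(min = obj$norm_output$min,
                                           max = obj$norm_output$max),
                                      class = "minmax_map")),
       n_hidden = obj$n_hidden, seed = obj$seed)
}
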