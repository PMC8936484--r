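#' Settings for the scaled conjugate gradient minimizer
#'
#' @param sigma0 Finite-difference scale for the Hessian-vector estimate
#'   (dimensionless, small; default `5e-5`).
#' @param lambda0 Initial Levenberg-style scale parameter (default `5e-7`).
#' @param max_epochs Iteration cap (default 1000).
#' @param grad_tol Stop when the Euclidean gradient norm falls below this
#'   (default `1e-6`).
#' @param obj_tol Stop when the decrease of the objective over an accepted
#'   step falls below this (default 0, disabled).
#'
#' @return An object of class `scg_settings`.
#' @export
scg_settings <- function(sigma0 = 5e-5, lambda0 = 5e-7, max_epochs = 1000L,
                         grad_tol = 1e-6, obj_tol = 0) {
  stopifnot(sigma0 > 0, lambda0 > 0, max_epochs >= 0,
            grad_tol >= 0, obj_tol >= 0)
  structure(list(sigma0 = sigma0, lambda0 = lambda0,
                 max_epochs = as.integer(max_epochs),
                 grad_tol = grad_tol, obj_tol = obj_tol),
            class = "scg_settings")
}

#' Minimize a differentiable objective by scaled conjugate gradient
#'
#' From-scratch implementation of Moller's scaled conjugate gradient (SCG).
#' Line searches are replaced by a one-sided finite-difference curvature
#' estimate along the search direction,
#' \eqn{s_k = (\nabla f(w_k + \sigma_k p_k) - \nabla f(w_k)) / \sigma_k}
#' with \eqn{\sigma_k = \sigma_0 / |p_k|}, regularized by a Levenberg-style
#' scale \eqn{\lambda} adapted from the comparison parameter \eqn{\Delta}
#' (raised when \eqn{\Delta < 0.25}, lowered when \eqn{\Delta > 0.75}).
#' A step is accepted only when \eqn{\Delta > 0}, so accepted objective
#' values never increase. The direction is restarted to steepest descent
#' every `d` iterations (d = dimension) and after a rejected step. The
#' algorithm is fully deterministic: identical inputs give identical traces.
#'
#' @param objective Function `w -> list(value = , gradient = )` returning
#'   the scalar objective and its gradient at `w`.
#' @param w0 Numeric start vector.
#' @param settings An [scg_settings()] object.
#' @param callback Optional observer called after each iteration as
#'   `callback(iter, w, value, grad_norm)`; returning `TRUE` stops the run
#'   with `stop_reason = "external-callback"`. This is how validation-based
#'   early stopping is injected; the optimizer itself knows nothing about
#'   data splits.
#'
#' @return A list with `w` (final iterate), and `trace`: a list with
#'   `objective_history`, `grad_norm_history` (one entry per iteration,
#'   including the start point) and `stop_reason` (one of
#'   `"gradient-tolerance"`, `"objective-tolerance"`, `"epoch-cap"`,
#'   `"external-callback"`, `"numerical-failure"`).
#' @references Moller, M. F. (1993). A scaled conjugate gradient algorithm
#'   for fast supervised learning. Neural Networks, 6(4), 525-533.
#' @export
#' @examples
#' quad <- function(w) list(value = sum(w^2), gradient = 2 * w)
#' fit <- minimize_scg(quad, c(1, 1), scg_settings())
#' fit$w
minimize_scg <- function(objective, w0, settings = scg_settings(),
                         callback = NULL) {
  stopifnot(inherits(settings, "scg_settings"))
  w <- as.numeric(w0)
  d <- length(w)
  ev <- objective(w)
  fw <- ev$value
  g <- as.numeric(ev$gradient)
  if (!is.finite(fw) || any(!is.finite(g))) {
    stop("objective or gradient non-finite at the start vector",
         call. = FALSE)
  }
  obj_hist <- fw
  grad_hist <- sqrt(sum(g^2))
  stop_reason <- "epoch-cap"

  r <- -g
  p <- r
  lambda <- settings$lambda0
  lambda_bar <- 0

  k <- 0L
  while (k < settings$max_epochs) {
    k <- k + 1L
    norm_r <- sqrt(sum(r^2))
    if (norm_r < settings$grad_tol) {
      stop_reason <- "gradient-tolerance"
      k <- k - 1L
      break
    }
    norm_p2 <- sum(p^2)
    norm_p <- sqrt(norm_p2)
    if (norm_p == 0) {
      stop_reason <- "gradient-tolerance"
      k <- k - 1L
      break
    }
    # curvature along p is re-estimated every iteration because the
    # direction changes on every path (conjugate update or restart)
    sigma_k <- settings$sigma0 / norm_p
    ev2 <- objective(w + sigma_k * p)
    s <- (as.numeric(ev2$gradient) - g) / sigma_k
    delta_k <- sum(p * s)
    # scale the curvature estimate
    delta_s <- delta_k + (lambda - lambda_bar) * norm_p2
    if (delta_s <= 0) {
      lambda_bar <- 2 * (lambda - delta_s / norm_p2)
      delta_s <- -delta_s + lambda * norm_p2
      lambda <- lambda_bar
    }
    mu_k <- sum(p * r)
    alpha <- mu_k / delta_s
    w_try <- w + alpha * p
    ev_try <- objective(w_try)
    f_try <- ev_try$value
    if (!is.finite(f_try)) {
      stop_reason <- "numerical-failure"
      break
    }
    Delta <- 2 * delta_s * (fw - f_try) / mu_k^2
    if (is.finite(Delta) && Delta > 0) {
      decrease <- fw - f_try
      w <- w_try
      fw <- f_try
      g <- as.numeric(ev_try$gradient)
      if (any(!is.finite(g))) {
        stop_reason <- "numerical-failure"
        break
      }
      r_new <- -g
      lambda_bar <- 0
      if (k %% d == 0L) {
        p <- r_new  # periodic restart to steepest descent
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu_k
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      obj_hist <- c(obj_hist, fw)
      grad_hist <- c(grad_hist, sqrt(sum(g^2)))
      if (!is.null(callback) &&
          isTRUE(callback(k, w, fw, grad_hist[length(grad_hist)]))) {
        stop_reason <- "external-callback"
        break
      }
      if (settings$obj_tol > 0 && decrease < settings$obj_tol) {
        stop_reason <- "objective-tolerance"
        break
      }
    } else {
      # rejected step: keep w, raise lambda, restart direction
      lambda_bar <- lambda
      p <- r
      obj_hist <- c(obj_hist, fw)
      grad_hist <- c(grad_hist, sqrt(sum(g^2)))
      if (!is.null(callback) &&
          isTRUE(callback(k, w, fw, grad_hist[length(grad_hist)]))) {
        stop_reason <- "external-callback"
        break
      }
    }
    if (is.finite(Delta) && Delta < 0.25) {
      lambda <- lambda + delta_s * (1 - Delta) / norm_p2
    }
  }
  if (stop_reason == "epoch-cap" && sqrt(sum(r^2)) < settings$grad_tol) {
    stop_reason <- "gradient-tolerance"
  }
  list(w = w,
       trace = list(objective_history = obj_hist,
                    grad_norm_history = grad_hist,
                    stop_reason = stop_reason,
                    iterations = k))
}

#' Write an optimization trace to CSV
#'
#' @param trace The `trace` component returned by [minimize_scg()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(iter = seq_along(trace$objective_history) - 1L,
                   objective = trace$objective_history,
                   grad_norm = trace$grad_norm_history)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
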