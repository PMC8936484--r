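#' Solver settings for the fractional predictor-corrector
#'
#' @param nu Fractional order of the Caputo derivative, in (0, 1].
#' @param h Step size (time units), positive.
#' @param t_end Horizon (time units); `t_end / h` must be a whole number of
#'   steps within rounding tolerance.
#' @param corrector_sweeps Number of corrector applications per step
#'   (default 1, the textbook predictor-corrector).
#'
#' @return An object of class `caputo_settings`.
#' @export
caputo_settings <- function(nu, h, t_end, corrector_sweeps = 1L) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu <= 0 || nu > 1) {
    stop("unsupported fractional order: nu must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(h) || h <= 0 || !is.finite(h)) {
    stop("step size h must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(t_end) || t_end <= 0 || !is.finite(t_end)) {
    stop("horizon t_end must be positive and finite", call. = FALSE)
  }
  n_steps <- t_end / h
  if (abs(n_steps - round(n_steps)) > 1e-8 * max(1, n_steps)) {
    stop("t_end / h must be a whole number of steps", call. = FALSE)
  }
  if (corrector_sweeps < 1L) {
    stop("corrector_sweeps must be at least 1", call. = FALSE)
  }
  structure(list(nu = as.numeric(nu), h = as.numeric(h),
                 t_end = as.numeric(t_end),
                 n_steps = as.integer(round(n_steps)),
                 corrector_sweeps = as.integer(corrector_sweeps)),
            class = "caputo_settings")
}

#' Predictor quadrature weights of the fractional rectangle rule
#'
#' For the step from node `n` to `n + 1`, the fractional Adams-Bashforth
#' predictor uses history weights
#' \deqn{b_j = \frac{h^\nu}{\nu}\left((n + 1 - j)^\nu - (n - j)^\nu\right),
#'   \quad j = 0, \dots, n,}
#' which telescope: \eqn{\sum_j b_j = (h^\nu/\nu)(n+1)^\nu}. At \eqn{\nu = 1}
#' every weight collapses to `h` (the classical rectangle rule).
#'
#' @param n Step index (0-based), nonnegative integer.
#' @param nu Fractional order in (0, 1].
#' @param h Step size.
#'
#' @return Numeric vector of `n + 1` strictly positive weights `b[0..n]`
#'   (1-indexed in R).
#' @export
predictor_weights <- function(n, nu, h) {
  stopifnot(n >= 0)
  if (nu <= 0 || nu > 1) {
    stop("unsupported fractional order: nu must lie in (0, 1]", call. = FALSE)
  }
  j <- 0:n
  (h^nu / nu) * ((n + 1 - j)^nu - (n - j)^nu)
}

#' Corrector quadrature weights of the fractional trapezoid rule
#'
#' For the step from node `n` to `n + 1`, the fractional Adams-Moulton
#' corrector uses weights \eqn{a_j = \frac{h^\nu}{\nu(\nu+1)} c_j} with
#' \deqn{c_0 = n^{\nu+1} - (n - \nu)(n + 1)^\nu,}
#' \deqn{c_j = (n - j + 2)^{\nu+1} + (n - j)^{\nu+1} - 2 (n - j + 1)^{\nu+1},
#'   \quad 1 \le j \le n,}
#' \deqn{c_{n+1} = 1.}
#' At \eqn{\nu = 1} this reduces to the composite trapezoid rule
#' (`h/2, h, ..., h, h/2`).
#'
#' @inheritParams predictor_weights
#' @return Numeric vector of `n + 2` nonnegative weights `a[0..n+1]`.
#' @export
corrector_weights <- function(n, nu, h) {
  stopifnot(n >= 0)
  if (nu <= 0 || nu > 1) {
    stop("unsupported fractional order: nu must lie in (0, 1]", call. = FALSE)
  }
  cc <- numeric(n + 2L)
  cc[1L] <- n^(nu + 1) - (n - nu) * (n + 1)^nu
  if (n >= 1L) {
    j <- 1:n
    cc[j + 1L] <- (n - j + 2)^(nu + 1) + (n - j)^(nu + 1) -
      2 * (n - j + 1)^(nu + 1)
  }
  cc[n + 2L] <- 1
  (h^nu / (nu * (nu + 1))) * cc
}

#' Solve a Caputo fractional system by Adams-Bashforth-Moulton
#'
#' Predictor-corrector scheme for \eqn{D^\nu y = f(t, y)} with classical
#' initial condition \eqn{y(0) = y_0} (Caputo convention) on the uniform
#' grid \eqn{t_j = jh}. Each step first predicts with the fractional
#' rectangle rule,
#' \deqn{y^P_{n+1} = y_0 + \frac{1}{\Gamma(\nu)} \sum_{j=0}^{n} b_j f(t_j, y_j),}
#' then applies the fractional trapezoid corrector `corrector_sweeps` times,
#' \deqn{y_{n+1} = y_0 + \frac{1}{\Gamma(\nu)}\left(\sum_{j=0}^{n} a_j
#'   f(t_j, y_j) + a_{n+1} f(t_{n+1}, y^*)\right),}
#' where \eqn{y^*} is the latest iterate. The full history is summed at
#' every step (no short-memory truncation), an O(N^2) cost that is
#' negligible at the grid sizes used here.
#'
#' @param rhs_fn Function `(t, y) -> dy` or `(y) -> dy` mapping a state
#'   vector to its derivative vector.
#' @param y0 Numeric initial state vector (any length).
#' @param settings A [caputo_settings()] object.
#'
#' @return An object of class `eco_trajectory`: a list with `times` (length
#'   N+1), `states` (an (N+1) x d matrix, first row exactly `y0`), `nu` and
#'   `meta` (settings echo).
#' @export
#' @examples
#' s <- caputo_settings(nu = 1, h = 0.01, t_end = 1)
#' tr <- solve_caputo_abm(function(t, y) -y, 1, s)
#' tail(tr$states[, 1], 1)  # ~ exp(-1)
solve_caputo_abm <- function(rhs_fn, y0, settings) {
  stopifnot(inherits(settings, "caputo_settings"))
  f <- if (length(formals(rhs_fn)) >= 2L) rhs_fn else function(t, y) rhs_fn(y)
  y0 <- as.numeric(y0)
  d <- length(y0)
  N <- settings$n_steps
  nu <- settings$nu
  h <- settings$h
  times <- (0:N) * h
  states <- matrix(NA_real_, nrow = N + 1L, ncol = d)
  fvals <- matrix(NA_real_, nrow = N + 1L, ncol = d)
  states[1L, ] <- y0
  f0 <- f(0, y0)
  if (any(!is.finite(f0))) {
    stop("right-hand side is non-finite at the initial state", call. = FALSE)
  }
  fvals[1L, ] <- f0
  inv_gamma <- 1 / gamma(nu)
  for (n in 0:(N - 1L)) {
    idx <- 1:(n + 1L)
    b <- predictor_weights(n, nu, h)
    hist_pred <- crossprod(fvals[idx, , drop = FALSE], b)[, 1L]
    y_pred <- y0 + inv_gamma * hist_pred
    a <- corrector_weights(n, nu, h)
    hist_corr <- crossprod(fvals[idx, , drop = FALSE], a[idx])[, 1L]
    y_new <- y_pred
    for (sweep in seq_len(settings$corrector_sweeps)) {
      f_new <- f(times[n + 2L], y_new)
      y_new <- y0 + inv_gamma * (hist_corr + a[n + 2L] * f_new)
    }
    if (any(!is.finite(y_new))) {
      stop("solution diverged (non-finite state) at step ", n + 1L,
           ", t = ", format(times[n + 2L]), call. = FALSE)
    }
    states[n + 2L, ] <- y_new
    fvals[n + 2L, ] <- f(times[n + 2L], y_new)
  }
  if (d == 3L && is.null(colnames(states))) {
    colnames(states) <- c("S", "I", "P")
  }
  structure(list(times = times, states = states, nu = nu,
                 meta = list(h = h, t_end = settings$t_end,
                             corrector_sweeps = settings$corrector_sweeps,
                             scheme = "caputo-abm")),
            class = "eco_trajectory")
}

#' Mittag-Leffler function (one-parameter, truncated series)
#'
#' Evaluates \eqn{E_\nu(z) = \sum_{k \ge 0} z^k / \Gamma(\nu k + 1)} by
#' direct series summation until the next term falls below `1e-15` relative
#' to the running sum, with a hard cap on the number of terms. Intended as
#' an independent validation oracle for the solver on linear relaxation
#' problems (\eqn{D^\nu y = -y} has solution \eqn{y_0 E_\nu(-t^\nu)}); the
#' truncated series is accurate for moderate arguments (|z| <= 5 is ample
#' at double precision).
#'
#' @param nu Order, positive.
#' @param z Real argument.
#' @param max_terms Term cap (default 1000).
#'
#' @return The value of \eqn{E_\nu(z)}.
#' @export
#' @examples
#' mittag_leffler(1, 1)      # e
#' mittag_leffler(0.5, -1)   # exp(1) * erfc(1)
mittag_leffler <- function(nu, z, max_terms = 1000L) {
  if (!is.numeric(nu) || nu <= 0) {
    stop("order nu must be positive", call. = FALSE)
  }
  total <- 0
  for (k in 0:(max_terms - 1L)) {
    term <- z^k / gamma(nu * k + 1)
    total <- total + term
    if (is.finite(total) && abs(term) <= 1e-15 * max(1, abs(total)) && k > 0L) {
      return(total)
    }
  }
  stop("Mittag-Leffler series did not converge within ", max_terms,
       " terms (argument too large for the truncated series)", call. = FALSE)
}

#' Reference trajectory of the infection prey-predator system
#'
#' Convenience wrapper: solves the eco-epidemic system with the
#' Adams-Bashforth-Moulton scheme on the study grid, `h = 0.01` over
#' `[0, 1]` (101 nodes). This is the trajectory the neural surrogate is
#' trained against.
#'
#' @param params An [eco_params()] object.
#' @param y0 An [eco_state()] initial state.
#' @param nu Fractional order in (0, 1].
#' @param h Step size (default 0.01).
#' @param t_end Horizon (default 1).
#'
#' @return An `eco_trajectory` (see [solve_caputo_abm()]).
#' @export
#' @examples
#' cfg <- eco_defaults()
#' tr <- reference_solution(cfg$params, cfg$init, nu = 0.5)
#' head(as.data.frame(tr))
reference_solution <- function(params, y0, nu, h = 0.01, t_end = 1) {
  settings <- caputo_settings(nu = nu, h = h, t_end = t_end)
  solve_caputo_abm(function(t, y) eco_rhs(y, params), as.numeric(y0),
                   settings)
}

#' @export
print.eco_trajectory <- function(x, ...) {
  cat("Trajectory: ", length(x$times), " nodes on [",
      format(x$times[1]), ", ", format(x$times[length(x$times)]),
      "], nu = ", format(x$nu), "\n", sep = "")
  utils::str(x$states)
  invisible(x)
}

#' @export
as.data.frame.eco_trajectory <- function(x, ...) {
  df <- as.data.frame(x$states)
  if (ncol(df) == 3L) names(df) <- c("S", "I", "P")
  cbind(t = x$times, df)
}

#' Write a trajectory to CSV
#'
#' Writes one row per grid node with header `t,S,I,P` (or `t,y1,...` for
#' non-model systems) at full double precision.
#'
#' @param trajectory An `eco_trajectory`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
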