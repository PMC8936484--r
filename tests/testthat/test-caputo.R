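# Classical rectangle-rule predictor / trapezoid corrector in cumulative
# (integral) form: y_{n+1} = y0 + h*(f0/2 + f1 + ... + fn + fhat_{n+1}/2)
# with the predictor y0 + h*(f0 + ... + fn). Written without any of the
# fractional weight machinery: oracle for the nu = 1 reduction of the
# solver, whose history is likewise anchored at y0.
classical_pc <- function(rhs_fn, y0, h, t_end) {
  N <- round(t_end / h)
  times <- (0:N) * h
  y <- matrix(NA_real_, N + 1L, length(y0))
  y[1L, ] <- y0
  fsum <- 0 * y0                      # f1 + ... + fn
  f0 <- rhs_fn(times[1L], y0)
  for (n in 0:(N - 1L)) {
    fn_all <- f0 + fsum
    yp <- y0 + h * fn_all
    fhat <- rhs_fn(times[n + 2L], yp)
    y[n + 2L, ] <- y0 + h * (f0 / 2 + fsum + fhat / 2)
    fsum <- fsum + rhs_fn(times[n + 2L], y[n + 2L, ])
  }
  list(times = times, states = y)
}

test_that("predictor weights follow the closed form and telescope", {
  # nu = 1: every weight is h (rectangle rule)
  expect_equal(predictor_weights(5, 1, 0.01), rep(0.01, 6))
  # direct evaluation of the last weight at nu = 0.5, h = 0.01
  b <- predictor_weights(7, 0.5, 0.01)
  expect_equal(b[8], 0.01^0.5 / 0.5)
  expect_equal(predictor_weights(0, 0.73, 0.02), 0.02^0.73 / 0.73)
  for (nu in c(0.3, 0.5, 0.7, 0.9, 1.0)) {
    for (n in c(0L, 1L, 17L, 1000L)) {
      b <- predictor_weights(n, nu, 0.01)
      expect_true(all(b > 0))
      expect_equal(sum(b), (0.01^nu / nu) * (n + 1)^nu, tolerance = 1e-12)
    }
  }
})

test_that("corrector weights reduce to the trapezoid rule at nu = 1", {
  a <- corrector_weights(6, 1, 0.05)
  expect_equal(a, c(0.025, rep(0.05, 6), 0.025))
  # c[n+1] = 1 term at nu = 0.5, n = 0, h = 1
  a0 <- corrector_weights(0, 0.5, 1)
  expect_equal(a0[2], 1 / (0.5 * 1.5))
  expect_true(all(corrector_weights(50, 0.7, 0.01) >= 0))
})

test_that("scheme is exact on constant right-hand sides", {
  # D^nu y = 1 has solution y0 + t^nu / Gamma(nu + 1)
  for (nu in c(0.3, 0.5, 0.7, 0.9, 1.0)) {
    s <- caputo_settings(nu, h = 0.02, t_end = 1)
    tr <- solve_caputo_abm(function(t, y) rep(1, length(y)), c(2, -1), s)
    exact <- 2 + tr$times^nu / gamma(nu + 1)
    expect_equal(tr$states[, 1], exact, tolerance = 1e-12)
    expect_equal(tr$states[, 2], exact - 3, tolerance = 1e-12)
  }
})

test_that("zero dynamics keep the state fixed", {
  s <- caputo_settings(0.5, 0.05, 1)
  tr <- solve_caputo_abm(function(t, y) 0 * y, c(1.5, 2.5, 3.5), s)
  expect_true(all(tr$states == rep(c(1.5, 2.5, 3.5), each = 21)))
  expect_identical(tr$states[1, ], c(S = 1.5, I = 2.5, P = 3.5))
})

test_that("nu = 1 solver matches the exponential decay oracle", {
  s <- caputo_settings(1, 0.01, 1)
  tr <- solve_caputo_abm(function(t, y) -y, 1, s)
  expect_equal(tr$states[101, 1], exp(-1), tolerance = 1e-4)
})

test_that("nu = 1 solution agrees node-wise with a classical
           predictor-corrector on the prey-predator system", {
  cfg <- eco_defaults()
  tr <- reference_solution(cfg$params, cfg$init, nu = 1)
  cl <- classical_pc(function(t, y) eco_rhs(y, cfg$params),
                     as.numeric(cfg$init), h = 0.01, t_end = 1)
  expect_equal(dim(tr$states), dim(cl$states))
  expect_lt(max(abs(tr$states - cl$states)), 1e-8)
})

test_that("Mittag-Leffler series matches closed forms", {
  expect_equal(mittag_leffler(1, 1), exp(1), tolerance = 1e-14)
  expect_equal(mittag_leffler(1, -2.5), exp(-2.5), tolerance = 1e-12)
  expect_equal(mittag_leffler(0.7, 0), 1)
  # E_{1/2}(-1) = e * erfc(1); erfc via the normal CDF
  erfc1 <- 2 * pnorm(-sqrt(2))
  expect_equal(mittag_leffler(0.5, -1), exp(1) * erfc1, tolerance = 1e-12)
  expect_equal(mittag_leffler(0.5, -1), 0.427584, tolerance = 1e-6)
  # E_2(z^2) = cosh(z)
  expect_equal(mittag_leffler(2, 4), cosh(2), tolerance = 1e-12)
})

test_that("fractional relaxation matches the Mittag-Leffler oracle and
           halving h never hurts", {
  for (nu in c(0.5, 0.7, 0.9)) {
    exact <- mittag_leffler(nu, -1)
    errs <- sapply(c(0.01, 0.005, 0.0025), function(h) {
      s <- caputo_settings(nu, h, 1)
      tr <- solve_caputo_abm(function(t, y) -y, 1, s)
      abs(tr$states[nrow(tr$states), 1] - exact)
    })
    expect_lt(errs[1], 5e-3)
    # memory monotonicity: halving h never increases the error at t = 1
    expect_true(all(diff(errs) <= 0))
    # empirical convergence order at least 1
    order <- log2(errs[1] / errs[2])
    expect_gte(order, 1)
  }
})

test_that("reference trajectory has the study grid and exact initial node", {
  cfg <- eco_defaults()
  tr <- reference_solution(cfg$params, cfg$init, nu = 0.5)
  expect_length(tr$times, 101)
  expect_equal(tr$times[101], 1.0)
  expect_identical(unname(tr$states[1, ]), c(0.2, 0.7, 0.6))
  expect_true(all(diff(tr$times) > 0))
})

test_that("invalid orders and divergence are reported", {
  expect_error(predictor_weights(3, 1.2, 0.01), "unsupported")
  expect_error(corrector_weights(3, 0, 0.01), "unsupported")
  expect_error(caputo_settings(1.5, 0.01, 1), "unsupported")
  expect_error(caputo_settings(0.5, 0.013, 1), "whole number")
  s <- caputo_settings(1, 0.1, 2)
  expect_error(solve_caputo_abm(function(t, y) y^2, 5, s),
               "diverged.*step", perl = TRUE)
})

test_that("trajectory CSV export round-trips at full precision", {
  cfg <- eco_defaults()
  tr <- reference_solution(cfg$params, cfg$init, nu = 0.7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_named(back, c("t", "S", "I", "P"))
  expect_equal(nrow(back), 101)
  expect_equal(back$S, unname(tr$states[, 1]), tolerance = 1e-15)
})
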