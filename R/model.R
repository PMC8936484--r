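#' Parameters of the eco-epidemic prey-predator model
#'
#' Constructs and validates the seven rate constants of the infection-based
#' prey-predator system with hunting cooperation. All rates must be finite
#' and nonnegative; negative rates have no ecological meaning here.
#'
#' @param delta Infection transmission rate among prey (per unit prey density
#'   per time).
#' @param r Prey reproduction rate (per time). Both susceptible and infected
#'   prey reproduce susceptible offspring; the infection is not transmitted
#'   vertically.
#' @param mu Natural prey death rate (per time).
#' @param a Hunting-cooperation coefficient (per predator density): predation
#'   pressure grows with predator density through the \eqn{(aP + \lambda)P}
#'   functional response.
#' @param lam Baseline predation rate (per predator density per time).
#' @param e Conversion rate of consumed prey into predator biomass
#'   (dimensionless fraction).
#' @param m Predator death rate (per time).
#'
#' @return An object of class `eco_params`: a named list of the seven rates.
#' @seealso [eco_state()], [eco_rhs()], [eco_defaults()]
#' @export
#' @examples
#' eco_params(delta = 0.5, r = 1.5, mu = 0.5, a = 0.5, lam = 0.5,
#'            e = 0.5, m = 0.5)
eco_params <- function(delta, r, mu, a, lam, e, m) {
  p <- list(delta = delta, r = r, mu = mu, a = a, lam = lam, e = e, m = m)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite numeric value",
           call. = FALSE)
    }
    if (v < 0) {
      stop("parameter '", nm, "' must be nonnegative (rates only)",
           call. = FALSE)
    }
  }
  structure(lapply(p, as.numeric), class = "eco_params")
}

#' Initial state of the prey-predator system
#'
#' @param i1 Initial susceptible prey density.
#' @param i2 Initial infected prey density.
#' @param i3 Initial predator density.
#'
#' @return An object of class `eco_state`: a named numeric vector
#'   `c(S = i1, I = i2, P = i3)`.
#' @export
#' @examples
#' eco_state(0.2, 0.7, 0.6)
eco_state <- function(i1, i2, i3) {
  v <- c(S = i1, I = i2, P = i3)
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v))) {
    stop("initial state components must be finite numeric values",
         call. = FALSE)
  }
  if (any(v < 0)) {
    stop("initial densities must be nonnegative", call. = FALSE)
  }
  structure(as.numeric(v), names = c("S", "I", "P"), class = "eco_state")
}

#' Right-hand side of the eco-epidemic prey-predator system
#'
#' Evaluates the three coupled rate equations at a given state. Writing
#' \eqn{S} for susceptible prey, \eqn{I} for infected prey and \eqn{P} for
#' predators:
#' \deqn{f_S = -\delta I S + r (I + S) - \mu S - (aP + \lambda) S P}
#' \deqn{f_I = -(\lambda + aP) I P + \delta S I - \mu I}
#' \deqn{f_P = (I + S)\, e\, (aP + \lambda) P - m P}
#' The \eqn{(aP + \lambda)P} factor is the hunting-cooperation functional
#' response. State components may be negative (the solver never clamps);
#' only finiteness is enforced.
#'
#' @param state Numeric length-3 vector `(S, I, P)` (an [eco_state()] or any
#'   finite numeric vector).
#' @param params An [eco_params()] object (or an equivalently named list).
#'
#' @return Named numeric vector of the three derivatives `(S, I, P)`.
#' @export
#' @examples
#' p <- eco_defaults()$params
#' eco_rhs(eco_state(0.2, 0.7, 0.6), p)
eco_rhs <- function(state, params) {
  if (!is.numeric(state) || length(state) != 3L) {
    stop("state must be a numeric vector of length 3", call. = FALSE)
  }
  if (any(!is.finite(state))) {
    stop("non-finite state component passed to eco_rhs", call. = FALSE)
  }
  S <- state[[1L]]; I <- state[[2L]]; P <- state[[3L]]
  hunt <- params$a * P + params$lam
  c(S = -params$delta * I * S + params$r * (I + S) - params$mu * S -
      hunt * S * P,
    I = -hunt * I * P + params$delta * S * I - params$mu * I,
    P = (I + S) * params$e * hunt * P - params$m * P)
}

#' Reference configuration of the infection prey-predator system
#'
#' The literature parameterization used throughout: all rates equal to 0.5
#' except the prey reproduction rate \eqn{r = 1.5}; initial densities
#' \eqn{(0.2, 0.7, 0.6)}; and the three fractional orders
#' \eqn{\nu \in \{0.5, 0.7, 0.9\}} that define study cases 1-3.
#'
#' @return A list with components `params` ([eco_params()]), `init`
#'   ([eco_state()]) and `orders` (numeric vector `c(0.5, 0.7, 0.9)`).
#' @export
#' @examples
#' cfg <- eco_defaults()
#' cfg$orders
eco_defaults <- function() {
  list(params = eco_params(delta = 0.5, r = 1.5, mu = 0.5, a = 0.5,
                           lam = 0.5, e = 0.5, m = 0.5),
       init = eco_state(0.2, 0.7, 0.6),
       orders = c(0.5, 0.7, 0.9))
}

#' @export
print.eco_params <- function(x, ...) {
  cat("Eco-epidemic prey-predator parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.eco_state <- function(x, ...) {
  cat("State (S = susceptible prey, I = infected prey, P = predator):\n")
  print(unclass(x))
  invisible(x)
}

#' Read a model configuration from a JSON file
#'
#' Expected keys: `delta`, `r`, `mu`, `a`, `lam`, `e`, `m` (rates), `i1`,
#' `i2`, `i3` (initial densities) and optionally `nu` (fractional order).
#' Missing keys fall back to [eco_defaults()]; unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @return A list with `params`, `init` and `nu` (`NULL` when absent).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("delta", "r", "mu", "a", "lam", "e", "m", "i1", "i2", "i3", "nu")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  defaults <- eco_defaults()
  base <- c(unclass(defaults$params),
            list(i1 = defaults$init[["S"]], i2 = defaults$init[["I"]],
                 i3 = defaults$init[["P"]]))
  for (nm in intersect(names(cfg), names(base))) base[[nm]] <- cfg[[nm]]
  list(params = do.call(eco_params, base[c("delta", "r", "mu", "a", "lam",
                                           "e", "m")]),
       init = eco_state(base$i1, base$i2, base$i3),
       nu = if ("nu" %in% names(cfg)) as.numeric(cfg$nu) else NULL)
}
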