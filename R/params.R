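#' Model registry
#'
#' The package's trial-level IGT models share one contract: a parameter table
#' with bounds, a likelihood step and a simulation step over latent deck
#' expectancies (and, for VPP, perseverance strengths). The registry maps
#' model names to that contract so further models (e.g. the
#' outcome-representation learning model) can be plugged in via
#' [register_igt_model()].
#'
#' @return A named list of model definitions. Each definition has `name`,
#'   `params` (tibble: `param`, `lower`, `upper`, `bounded`), and an integer
#'   `id` used by the compiled likelihood.
#' @export
model_registry <- function() .igtrl_registry$models

.igtrl_registry <- new.env(parent = emptyenv())

param_table <- function(param, lower, upper) {
  tibble::tibble(param = param, lower = lower, upper = upper,
                 bounded = is.finite(upper))
}

local({
  pvl <- param_table(
    c("A", "alpha", "cons", "lambda"),
    lower = c(0, 0, 0, 0), upper = c(1, 2, 5, 5)
  )
  vpp <- param_table(
    c("A", "alpha", "cons", "lambda", "epP", "epN", "K", "w"),
    lower = c(0, 0, 0, 0, -Inf, -Inf, 0, 0),
    upper = c(1, 2, 5, 5, Inf, Inf, 1, 1)
  )
  .igtrl_registry$models <- list(
    pvl_delta = list(name = "pvl_delta", params = pvl, id = 1L),
    pvl_decay = list(name = "pvl_decay", params = pvl, id = 2L),
    vpp       = list(name = "vpp", params = vpp, id = 3L)
  )
})

#' @rdname model_registry
#' @param name Model name.
#' @export
get_model <- function(name) {
  m <- .igtrl_registry$models[[name]]
  if (is.null(m)) {
    abort(paste0("Unknown model '", name, "'. Registered: ",
                 paste(names(.igtrl_registry$models), collapse = ", ")))
  }
  m
}

#' @rdname model_registry
#' @param definition A list with `name`, `params` (as above), and function
#'   fields `loglik(trials, params, outcome_scale)` and
#'   `simulate(params, schedule, seed, ...)` for models without a compiled
#'   core.
#' @export
register_igt_model <- function(name, definition) {
  stopifnot(is.character(name), length(name) == 1)
  definition$name <- name
  .igtrl_registry$models[[name]] <- definition
  invisible(definition)
}

check_params <- function(params, model) {
  m <- get_model(model)
  pt <- m$params
  miss <- setdiff(pt$param, names(params))
  if (length(miss)) {
    abort(paste0("Missing parameter(s) for ", model, ": ",
                 paste(miss, collapse = ", ")))
  }
  v <- unlist(params[pt$param])
  bad <- v < pt$lower | v > pt$upper | !is.finite(v) & pt$bounded
  if (any(bad)) {
    abort(paste0("Parameter(s) out of bounds for ", model, ": ",
                 paste(sprintf("%s=%g", pt$param[bad], v[bad]), collapse = ", ")))
  }
  setNames(as.numeric(v), pt$param)
}

#' Construct validated model parameters
#'
#' Constructors for the parameter vectors of the three built-in models.
#' Bounds follow the model definitions: learning/decay rate `A`, perseverance
#' decay `K` and RL weight `w` in \[0, 1\]; outcome sensitivity `alpha` in
#' (0, 2); response consistency `cons` in \[0, 5\]; loss aversion `lambda` in
#' \[0, 5\]; gain/loss perseverance impacts `epP`, `epN` unbounded.
#' Out-of-bound values are rejected.
#'
#' @param A Learning rate (delta rule) or decay rate (decay rule), \[0, 1\].
#' @param alpha Outcome-sensitivity shape of the prospect utility, (0, 2).
#' @param cons Response consistency; softmax sensitivity is `3^cons - 1`.
#' @param lambda Loss aversion multiplier, \[0, 5\].
#' @param epP,epN Perseverance impacts of gains / losses (real-valued).
#' @param K Perseverance decay rate, \[0, 1\].
#' @param w Reinforcement-learning weight mixing expectancy and
#'   perseverance, \[0, 1\].
#' @return A named numeric vector with class `igt_params` and attribute
#'   `model`.
#' @export
vpp_params <- function(A, alpha, cons, lambda, epP = 0, epN = 0, K = 0, w = 1) {
  p <- check_params(
    list(A = A, alpha = alpha, cons = cons, lambda = lambda,
         epP = epP, epN = epN, K = K, w = w), "vpp")
  structure(p, model = "vpp", class = "igt_params")
}

#' @rdname vpp_params
#' @export
pvl_delta_params <- function(A, alpha, cons, lambda) {
  p <- check_params(list(A = A, alpha = alpha, cons = cons, lambda = lambda),
                    "pvl_delta")
  structure(p, model = "pvl_delta", class = "igt_params")
}

#' @rdname vpp_params
#' @export
pvl_decay_params <- function(A, alpha, cons, lambda) {
  p <- check_params(list(A = A, alpha = alpha, cons = cons, lambda = lambda),
                    "pvl_decay")
  structure(p, model = "pvl_decay", class = "igt_params")
}

#' @export
print.igt_params <- function(x, ...) {
  cat("<igt_params:", attr(x, "model"), ">\n")
  print(unclass(x))
  invisible(x)
}

# ---- probit transforms between the natural and unconstrained scales -------
# Bounded parameters map through upper * pnorm(z); unbounded ones are
# identity. Used by the MAP optimiser and the hierarchical sampler.

to_unconstrained <- function(values, model) {
  pt <- get_model(model)$params
  z <- numeric(nrow(pt))
  for (i in seq_len(nrow(pt))) {
    v <- values[[pt$param[i]]]
    z[i] <- if (pt$bounded[i]) {
      qnorm(pmin(pmax(v / pt$upper[i], 1e-12), 1 - 1e-12))
    } else v
  }
  setNames(z, pt$param)
}

to_natural <- function(z, model) {
  pt <- get_model(model)$params
  v <- numeric(nrow(pt))
  for (i in seq_len(nrow(pt))) {
    v[i] <- if (pt$bounded[i]) pt$upper[i] * pnorm(z[[i]]) else z[[i]]
  }
  setNames(v, pt$param)
}
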