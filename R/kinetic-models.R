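#' Pharmacokinetic parameter set
#'
#' Bundles the parameters of the drug uptake / cellular response rate
#' equations. The uptake state `Nb` (bound drug) obeys
#' \deqn{dN_b/dt = (N_{recp} - N_b)\,K_{up}\,D}
#' and the response state `Nr` obeys
#' \deqn{dN_r/dt = (N_{resp} - N_r)\,K_{resp}\,N_b.}
#' The capacities `Nrecp` and `Nresp` act as saturation ceilings; `D` is the
#' (constant, dimensionless) drug dose. Because only the product `Kup * D`
#' enters the uptake equation, `Kup` and `D` are jointly identifiable: `D` is
#' treated as a known constant and never fitted.
#'
#' @param Kup uptake rate constant (1/h per unit dose), >= 0.
#' @param Kresp response rate constant (1/h per unit bound drug), >= 0.
#' @param Nrecp receptor/binding capacity (arbitrary concentration units), >= 0.
#' @param Nresp response capacity (arbitrary concentration units), >= 0.
#' @param D drug dose (dimensionless, constant over time), >= 0.
#'
#' @return An object of class `kinetic_params`: a named numeric vector with
#'   elements `Kup`, `Kresp`, `Nrecp`, `Nresp`, `D`.
#' @export
#' @examples
#' kinetic_params(Kup = 0.25, Kresp = 0.05)
kinetic_params <- function(Kup = 0.25, Kresp = 0.05, Nrecp = 1, Nresp = 1,
                           D = 1) {
  p <- c(Kup = Kup, Kresp = Kresp, Nrecp = Nrecp, Nresp = Nresp, D = D)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  need <- c("Kup", "Kresp", "Nrecp", "Nresp", "D")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0L) {
    stop("invalid kinetic parameters: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- p[need]
  if (any(!is.finite(p))) {
    stop("invalid kinetic parameters: non-finite value in [",
         paste(names(p)[!is.finite(p)], collapse = ", "), "]", call. = FALSE)
  }
  if (any(p < 0)) {
    stop("invalid kinetic parameters: negative value in [",
         paste(names(p)[p < 0], collapse = ", "), "]", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

# symbols permitted inside user-declared rate expressions
.rate_expr_allowed_calls <- c("+", "-", "*", "/", "^", "(", "exp", "log",
                              "sqrt", "pmax", "pmin")

check_rate_expr <- function(e, allowed_names) {
  if (is.numeric(e) || is.integer(e)) return(invisible(TRUE))
  if (is.name(e)) {
    if (!as.character(e) %in% allowed_names) {
      stop("rate expression uses unknown symbol '", as.character(e),
           "'; allowed: ", paste(allowed_names, collapse = ", "),
           call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    if (!fn %in% .rate_expr_allowed_calls) {
      stop("rate expression uses disallowed function '", fn, "'",
           call. = FALSE)
    }
    for (i in seq_along(e)[-1L]) check_rate_expr(e[[i]], allowed_names)
    return(invisible(TRUE))
  }
  stop("unsupported construct in rate expression", call. = FALSE)
}

#' Kinetic model definition
#'
#' Retrieves a built-in pharmacokinetic ODE model by name. Two models ship
#' with the package:
#' \describe{
#'   \item{`"uptake"`}{one state `Nb` (bound drug), parameters
#'     `Kup`, `Nrecp`, `D`; saturating first-order uptake.}
#'   \item{`"uptake_response"`}{two states `Nb`, `Nr`; the response `Nr` is
#'     driven by the accumulated bound drug, parameters `Kup`, `Kresp`,
#'     `Nrecp`, `Nresp`, `D`.}
#' }
#' Arbitrary systems can be declared with [custom_kinetic_model()].
#'
#' @param name `"uptake"` or `"uptake_response"`.
#' @param initial_state state values at t = 0; defaults to all zero
#'   (no pre-bound drug, no pre-existing response).
#' @param component_map which resolved component (column of C) each state
#'   constrains; defaults to states in order, occupying the lowest indices.
#'
#' @return An object of class `kinetic_model`, a list with elements `name`,
#'   `n_states`, `state_names`, `rhs`, `param_names`, `initial_state` and
#'   `component_map`.
#' @export
#' @examples
#' m <- kinetic_model("uptake_response")
#' m$param_names
kinetic_model <- function(name = c("uptake", "uptake_response"),
                          initial_state = NULL, component_map = NULL) {
  name <- match.arg(name)
  if (name == "uptake") {
    m <- new_kinetic_model(
      name = "uptake", state_names = "Nb",
      rhs = function(t, state, p) {
        list((p[["Nrecp"]] - state[[1L]]) * p[["Kup"]] * p[["D"]])
      },
      param_names = c("Kup", "Nrecp", "D"),
      initial_state = initial_state, component_map = component_map)
  } else {
    m <- new_kinetic_model(
      name = "uptake_response", state_names = c("Nb", "Nr"),
      rhs = function(t, state, p) {
        dNb <- (p[["Nrecp"]] - state[[1L]]) * p[["Kup"]] * p[["D"]]
        dNr <- (p[["Nresp"]] - state[[2L]]) * p[["Kresp"]] * state[[1L]]
        list(c(dNb, dNr))
      },
      param_names = c("Kup", "Kresp", "Nrecp", "Nresp", "D"),
      initial_state = initial_state, component_map = component_map)
  }
  m
}

new_kinetic_model <- function(name, state_names, rhs, param_names,
                              initial_state = NULL, component_map = NULL,
                              capacity_for_state = NULL) {
  n_states <- length(state_names)
  if (is.null(initial_state)) initial_state <- rep(0, n_states)
  if (is.null(component_map)) component_map <- seq_len(n_states)
  if (length(initial_state) != n_states) {
    stop("initial_state must have one value per state (", n_states, ")",
         call. = FALSE)
  }
  if (anyDuplicated(component_map) > 0L) {
    stop("component_map indices must be distinct", call. = FALSE)
  }
  structure(
    list(name = name, n_states = n_states, state_names = state_names,
         rhs = rhs, param_names = param_names,
         initial_state = as.numeric(initial_state),
         component_map = as.integer(component_map)),
    class = "kinetic_model")
}

#' Declare a kinetic model from rate expressions
#'
#' Builds a [kinetic_model()] from textual rate expressions, one per state.
#' Expressions are parsed and checked against a whitelist of symbols (state
#' names, parameter names, `t`) and arithmetic functions; they are never
#' executed as arbitrary code. This is the hook through which configuration
#' files can declare systems other than the built-in ones.
#'
#' @param name model identifier.
#' @param state_names character vector of state names.
#' @param rates character vector of rate expressions (`d<state>/dt`), one per
#'   state, e.g. `"(Nrecp - Nb) * Kup * D"`.
#' @param param_names character vector of parameter names the expressions may
#'   reference.
#' @param initial_state,component_map see [kinetic_model()].
#'
#' @return A `kinetic_model`.
#' @export
#' @examples
#' m <- custom_kinetic_model(
#'   "uptake_decl", "Nb", "(Nrecp - Nb) * Kup * D",
#'   param_names = c("Kup", "Nrecp", "D"))
custom_kinetic_model <- function(name, state_names, rates, param_names,
                                 initial_state = NULL, component_map = NULL) {
  if (length(rates) != length(state_names)) {
    stop("need exactly one rate expression per state", call. = FALSE)
  }
  allowed <- c(state_names, param_names, "t")
  exprs <- lapply(rates, function(r) {
    e <- str2lang(r)
    check_rate_expr(e, allowed)
    e
  })
  rhs <- function(t, state, p) {
    env <- new.env(parent = baseenv())
    for (i in seq_along(state_names)) assign(state_names[i], state[[i]], env)
    for (nm in param_names) assign(nm, p[[nm]], env)
    assign("t", t, env)
    list(vapply(exprs, eval, numeric(1L), envir = env))
  }
  new_kinetic_model(name, state_names, rhs, param_names,
                    initial_state = initial_state,
                    component_map = component_map)
}

#' Integrate a kinetic model on a time grid
#'
#' Solves the model's ODE system with an adaptive explicit Runge-Kutta pair
#' (`deSolve::ode`, method `"ode45"`, rtol 1e-8, atol 1e-10; the systems are
#' non-stiff in the relevant parameter ranges) and returns the state
#' trajectories at exactly the requested times.
#'
#' @param model a [kinetic_model()].
#' @param params a [kinetic_params()] (or named vector covering
#'   `model$param_names`).
#' @param times hour grid, strictly increasing, `times[1] >= 0`. The initial
#'   state is anchored at t = 0; if `times[1] > 0` the solver integrates from 0
#'   and reports only the requested grid.
#'
#' @return An object of class `concentration_profiles`: list with `times`,
#'   `values` (time x state matrix) and `state_names`. Trajectories are
#'   clamped to zero within solver tolerance (1e-8) to absorb round-off.
#' @export
#' @examples
#' pr <- solve_kinetics(kinetic_model("uptake"),
#'                      kinetic_params(Kup = 0.25), seq(0, 72, 0.5))
#' max(pr$values[, "Nb"]) # bounded by Nrecp = 1
solve_kinetics <- function(model, params, times) {
  stopifnot(inherits(model, "kinetic_model"))
  p <- validate_kinetic_params_for(model, params)
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1L] < 0) stop("times must start at or after 0", call. = FALSE)

  solve_times <- times
  prepended <- FALSE
  if (times[1L] > 0) {
    solve_times <- c(0, times)
    prepended <- TRUE
  }
  y0 <- stats::setNames(model$initial_state, model$state_names)
  sol <- tryCatch(
    deSolve::ode(y = y0, times = solve_times,
                 func = function(t, y, parms) model$rhs(t, y, parms),
                 parms = p, method = "ode45", rtol = 1e-8, atol = 1e-10),
    error = function(e) e, warning = function(w) w)
  if (inherits(sol, "condition") || nrow(sol) < length(solve_times) ||
      anyNA(sol)) {
    stop("ODE integration failed for model '", model$name, "' at parameters [",
         paste(sprintf("%s=%g", names(p), p), collapse = ", "), "]",
         call. = FALSE)
  }
  values <- unname(sol[, -1L, drop = FALSE])
  if (prepended) values <- values[-1L, , drop = FALSE]
  colnames(values) <- model$state_names
  # absorb integrator round-off at the non-negativity boundary
  tiny_neg <- values < 0 & values > -1e-8
  values[tiny_neg] <- 0
  if (any(values < 0)) {
    stop("ODE solution went negative beyond tolerance for model '",
         model$name, "'", call. = FALSE)
  }
  structure(list(times = times, values = values,
                 state_names = model$state_names),
            class = "concentration_profiles")
}

# Accept a full kinetic_params or any named vector covering the model's
# parameter names; always validated for finiteness/non-negativity.
validate_kinetic_params_for <- function(model, params) {
  p <- unclass(params)
  missing <- setdiff(model$param_names, names(p))
  if (length(missing) > 0L) {
    stop("invalid kinetic parameters: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- p[model$param_names]
  if (any(!is.finite(p))) {
    stop("invalid kinetic parameters: non-finite value in [",
         paste(names(p)[!is.finite(p)], collapse = ", "), "]", call. = FALSE)
  }
  if (any(p < 0)) {
    stop("invalid kinetic parameters: negative value in [",
         paste(names(p)[p < 0], collapse = ", "), "]", call. = FALSE)
  }
  p
}

#' Closed-form saturating uptake
#'
#' Analytic solution of the uptake equation for constant dose and
#' `Nb(0) = 0`: `Nb(t) = Nrecp * (1 - exp(-Kup * D * t))`. Serves as an
#' independent oracle for [solve_kinetics()].
#'
#' @inheritParams solve_kinetics
#' @return A `concentration_profiles` with the single state `Nb`.
#' @export
#' @examples
#' closed_form_uptake(kinetic_params(Kup = 0.25), c(0, 4))$values
closed_form_uptake <- function(params, times) {
  p <- validate_kinetic_params_for(kinetic_model("uptake"), params)
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1L] < 0) stop("times must start at or after 0", call. = FALSE)
  nb <- p[["Nrecp"]] * (1 - exp(-p[["Kup"]] * p[["D"]] * times))
  values <- matrix(nb, ncol = 1L, dimnames = list(NULL, "Nb"))
  structure(list(times = times, values = values, state_names = "Nb"),
            class = "concentration_profiles")
}

#' @export
print.concentration_profiles <- function(x, ...) {
  cat("Concentration profiles:", length(x$times), "time points,",
      length(x$state_names), "state(s):",
      paste(x$state_names, collapse = ", "), "\n")
  cat("  t in [", x$times[1L], ",", x$times[length(x$times)], "] h\n")
  invisible(x)
}
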