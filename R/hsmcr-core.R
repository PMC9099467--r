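#' Constraint configuration for the hard-and-soft ALS
#'
#' @param n_components number of bilinear components I (>= 1).
#' @param nonneg_conc logical, per-component non-negativity on concentration
#'   profiles (recycled; default all TRUE).
#' @param nonneg_spec logical, per-component non-negativity on spectra.
#'   Default: TRUE everywhere except the first kinetically constrained
#'   component — the drug-binding component's resolved spectrum must be able
#'   to carry negative nucleic-acid features (drug intercalation *reduces*
#'   those bands), so clamping it would bias the fit. Set explicitly to
#'   enforce either reading.
#' @param kinetic optional hard-constraint link: a list with `model` (a
#'   [kinetic_model()]), `k0` (initial constants) and optionally `components`
#'   (columns the model states constrain; default the model's
#'   `component_map`, i.e. the lowest indices in state order).
#' @param max_iter iteration cap (default 200).
#' @param patience consecutive small-change iterations required to declare
#'   convergence (default 20).
#' @param rel_tol relative fitting-error change below which an iteration
#'   counts as "no change" (default 0.01, i.e. 1\%).
#' @return An object of class `constraint_config`.
#' @export
constraint_config <- function(n_components, nonneg_conc = TRUE,
                              nonneg_spec = NULL, kinetic = NULL,
                              max_iter = 200L, patience = 20L,
                              rel_tol = 0.01) {
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  if (rel_tol <= 0) stop("rel_tol must be > 0", call. = FALSE)
  nonneg_conc <- rep_len(as.logical(nonneg_conc), n_components)
  if (!is.null(kinetic)) {
    stopifnot(is.list(kinetic), inherits(kinetic$model, "kinetic_model"))
    if (is.null(kinetic$components)) {
      kinetic$components <- kinetic$model$component_map
    }
    kinetic$components <- as.integer(kinetic$components)
    if (length(kinetic$components) != kinetic$model$n_states ||
        anyDuplicated(kinetic$components) > 0L ||
        any(kinetic$components < 1L) ||
        any(kinetic$components > n_components)) {
      stop("kinetic component indices must be distinct and within 1..",
           n_components, call. = FALSE)
    }
    validate_kinetic_params_for(kinetic$model, kinetic$k0)
  }
  if (is.null(nonneg_spec)) {
    nonneg_spec <- rep(TRUE, n_components)
    if (!is.null(kinetic)) nonneg_spec[kinetic$components[1L]] <- FALSE
  } else {
    nonneg_spec <- rep_len(as.logical(nonneg_spec), n_components)
  }
  structure(list(n_components = n_components, nonneg_conc = nonneg_conc,
                 nonneg_spec = nonneg_spec, kinetic = kinetic,
                 max_iter = as.integer(max_iter),
                 patience = as.integer(patience), rel_tol = rel_tol),
            class = "constraint_config")
}

#' Residual fitting error of the bilinear reconstruction
#'
#' @param D data matrix.
#' @param C,S factor matrices.
#' @return list with `ssr` (sum of squared residuals, the quantity the
#'   convergence rule watches) and `lof_pct`
#'   (`100 * sqrt(ssr / sum(D^2))`, the conventional \%LOF for logging).
#' @export
lack_of_fit <- function(D, C, S) {
  R <- D - C %*% S
  ssr <- sum(R * R)
  list(ssr = ssr, lof_pct = 100 * sqrt(ssr / sum(D * D)))
}

#' Convergence decision for the ALS loop
#'
#' Stops with `"stop_patience"` when the fitting error (SSR) has increased or
#' decreased by less than `rel_tol` (relative) for `patience` consecutive
#' iteration pairs, and with `"stop_max_iter"` when `max_iter` iterations
#' have run. A zero fitting error is a perfect fit and converges immediately.
#'
#' @param lof_history numeric vector of per-iteration SSR values, non-empty.
#' @param rel_tol,patience,max_iter see [constraint_config()].
#' @return `"continue"`, `"stop_patience"` or `"stop_max_iter"`.
#' @export
check_convergence <- function(lof_history, rel_tol = 0.01, patience = 20L,
                              max_iter = 200L) {
  n <- length(lof_history)
  stopifnot(n >= 1L)
  if (lof_history[n] == 0) return("stop_patience")
  if (n >= patience + 1L) {
    prev <- lof_history[-n][(n - patience):(n - 1L)]
    curr <- lof_history[(n - patience + 1L):n]
    rel <- ifelse(prev == 0, 0, abs(curr - prev) / prev)
    if (all(rel < rel_tol)) return("stop_patience")
  }
  if (n >= max_iter) return("stop_max_iter")
  "continue"
}

#' Refit kinetic constants to soft concentration profiles
#'
#' Nonlinear least squares of the ODE trajectories against the kinetically
#' constrained columns of the soft (ALS-estimated) concentration matrix,
#' warm-started from the previous iteration's constants. All rate and
#' capacity parameters are bounded below by zero; the dose `D` is a known
#' constant and is held fixed. Solved by bounded Levenberg-Marquardt
#' (`minpack.lm::nls.lm`). Optimizer failure is downgraded to a warning and
#' the best iterate is returned, so the enclosing ALS loop never aborts.
#'
#' @param C_soft N x I soft concentration matrix.
#' @param model a [kinetic_model()].
#' @param k_prev previous constants (warm start).
#' @param times hour grid.
#' @param components columns of `C_soft` the model states constrain
#'   (state order); default `model$component_map`.
#' @return list with `k` (updated full parameter vector), `C_model`
#'   (N x n_states fitted trajectories) and `ssr` (residual at `k`).
#' @export
fit_kinetic_constants <- function(C_soft, model, k_prev, times,
                                  components = model$component_map) {
  p_prev <- validate_kinetic_params_for(model, k_prev)
  free <- setdiff(model$param_names, "D")
  target <- C_soft[, components, drop = FALSE]
  resid_fn <- function(par) {
    p <- p_prev
    p[free] <- par
    sol <- tryCatch(solve_kinetics(model, p, times), error = function(e) NULL)
    if (is.null(sol)) return(rep(1e6, length(target)))
    as.numeric(sol$values - target)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmax(p_prev[free], 0), lower = rep(0, length(free)),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("kinetic refit failed (", conditionMessage(fit),
            "); keeping previous constants", call. = FALSE)
    k_new <- p_prev
  } else {
    if (fit$info == 0 || fit$info == 9) {
      warning("kinetic refit did not converge (", fit$message,
              "); using best iterate", call. = FALSE)
    }
    k_new <- p_prev
    k_new[free] <- fit$par
  }
  sol <- solve_kinetics(model, k_new, times)
  list(k = k_new, C_model = sol$values,
       ssr = sum((sol$values - target)^2))
}

#' Impose the hard kinetic constraint
#'
#' Replaces the kinetically constrained columns of the soft concentration
#' matrix by the fitted ODE trajectories; all other columns pass through
#' unchanged. With no kinetic link this is the identity.
#'
#' @param C_soft N x I soft concentration matrix.
#' @param C_model N x n_states fitted trajectories (or NULL for no link).
#' @param components target columns (state order).
#' @return N x I hard concentration matrix.
#' @export
apply_kinetic_constraint <- function(C_soft, C_model, components = NULL) {
  if (is.null(C_model)) return(C_soft)
  if (is.null(components)) components <- seq_len(ncol(C_model))
  C_hard <- C_soft
  C_hard[, components] <- C_model
  C_hard
}

#' Hard-and-soft MCR-ALS
#'
#' Alternating constrained least squares on the bilinear model `D = C S`
#' (C: N x I concentration profiles, S: I x J pure spectra) with, when a
#' kinetic link is configured, a nonlinear refit of the ODE rate constants at
#' every iteration and replacement of the linked concentration columns by the
#' fitted trajectories. Iterations run: S step (constrained spectra) ->
#' C step (constrained concentrations) -> kinetic refit -> hard substitution,
#' with the fitting error recorded after each full pass. The loop is
#' deterministic given its inputs: there is no internal randomness.
#'
#' Two caveats the iteration history makes visible: (i) with soft constraints
#' only, the error is non-increasing (each half step solves its least-squares
#' problem exactly); with the hard substitution it may transiently rise —
#' that is the price of forcing model consistency; (ii) because the data are
#' normalized and C columns / S rows are never rescaled internally, capacity
#' parameters (`Nrecp`, `Nresp`) absorb the arbitrary intensity scale and are
#' recovered only up to a factor, while the rate constants (`Kup`, `Kresp`)
#' are scale-free.
#'
#' @param ds a [spectra_dataset()].
#' @param config a [constraint_config()].
#' @param normalize normalize rows to the phenylalanine band first
#'   (default TRUE); set FALSE if `ds` is already normalized.
#' @param norm_spec a [normalization_spec()].
#' @param verbose print one line per iteration (iteration, SSR, \%LOF,
#'   current constants).
#' @return An object of class `mcr_result`: list with `C` (N x I), `S`
#'   (I x J), `k_final`, `k_history` (iteration x parameter), `lof_history`
#'   (SSR per iteration), `lof_pct_history`, `n_iter`, `converged`,
#'   `stop_reason` (`"patience"` or `"max_iter"`), `times`, `wavenumbers`,
#'   `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(config = simulation_config(noise_fraction = 0))
#' cfg <- constraint_config(3, kinetic = list(
#'   model = kinetic_model("uptake_response"), k0 = kinetic_params()))
#' fit <- run_mcr_als(sim$dataset, cfg, verbose = FALSE)
#' fit$k_final[c("Kup", "Kresp")]
run_mcr_als <- function(ds, config, normalize = TRUE,
                        norm_spec = normalization_spec(), verbose = FALSE) {
  stopifnot(inherits(ds, "spectra_dataset"),
            inherits(config, "constraint_config"))
  if (normalize) ds <- normalize_dataset(ds, norm_spec)
  D <- ds$intensities
  times <- ds$times
  N <- nrow(D)
  kin <- config$kinetic
  if (!is.null(kin)) {
    n_free <- length(setdiff(kin$model$param_names, "D"))
    if (N < 2L * n_free) {
      warning("only ", N, " time points for ", n_free, " kinetic parameters; ",
              "rate constants are unlikely to be identifiable", call. = FALSE)
    }
    C <- initial_concentrations(kin$model, kin$k0, times,
                                config$n_components, kin$components)
    k <- validate_kinetic_params_for(kin$model, kin$k0)
  } else {
    C <- matrix(1, N, config$n_components)
    # a constant start is rank-1: perturb deterministically so the first
    # S step sees a full-rank C
    if (config$n_components > 1L) {
      for (j in 2:config$n_components) {
        C[, j] <- seq(0, 1, length.out = N)^(j - 1L)
      }
    }
    k <- NULL
  }

  lof_history <- numeric(0)
  lof_pct_history <- numeric(0)
  k_history <- NULL
  I <- config$n_components
  J <- ncol(D)
  # components whose profile and spectrum both collapse to zero are frozen
  # there and excluded from subsequent solves (kinetically linked components
  # are exempt: the hard substitution always restores their profile)
  alive <- rep(TRUE, I)
  kin_cols <- if (is.null(kin)) integer(0) else kin$components
  mark_dead <- function(idx) {
    idx <- setdiff(idx, kin_cols)
    new_dead <- idx[alive[idx]]
    if (length(new_dead) > 0L) {
      warning("component(s) ", paste(new_dead, collapse = ", "),
              " collapsed to zero; frozen at zero, run continues",
              call. = FALSE)
      alive[new_dead] <<- FALSE
    }
  }
  S <- NULL
  repeat {
    use_s <- alive & apply(abs(C), 2L, max) > 0
    if (!any(use_s)) {
      stop("all components collapsed to zero; nothing left to fit",
           call. = FALSE)
    }
    S <- matrix(0, I, J)
    S[use_s, ] <- nnls_rows(D, C[, use_s, drop = FALSE],
                            config$nonneg_spec[use_s])
    mark_dead(which(apply(abs(S), 1L, max) == 0))
    use_c <- alive & apply(abs(S), 1L, max) > 0
    C_soft <- matrix(0, nrow(D), I)
    C_soft[, use_c] <- nnls_cols(D, S[use_c, , drop = FALSE],
                                 config$nonneg_conc[use_c])
    mark_dead(which(apply(abs(C_soft), 2L, max) == 0))

    if (!is.null(kin)) {
      kfit <- fit_kinetic_constants(C_soft, kin$model, k, times,
                                    kin$components)
      k <- kfit$k
      C_hard <- apply_kinetic_constraint(C_soft, kfit$C_model, kin$components)
      k_history <- rbind(k_history, k)
    } else {
      C_hard <- C_soft
    }

    lof <- lack_of_fit(D, C_hard, S)
    lof_history <- c(lof_history, lof$ssr)
    lof_pct_history <- c(lof_pct_history, lof$lof_pct)
    it <- length(lof_history)
    if (verbose) {
      cat(sprintf("iter %3d  SSR %.6e  LOF %6.3f%%", it, lof$ssr,
                  lof$lof_pct))
      if (!is.null(k)) {
        cat("  ", paste(sprintf("%s=%.4g", names(k), k), collapse = " "))
      }
      cat("\n")
    }
    C <- C_hard
    decision <- check_convergence(lof_history, config$rel_tol,
                                  config$patience, config$max_iter)
    if (decision != "continue") break
  }

  if (!is.null(k_history)) {
    rownames(k_history) <- NULL
    colnames(k_history) <- names(k)
  }
  structure(
    list(C = C, S = S, k_final = k, k_history = k_history,
         lof_history = lof_history, lof_pct_history = lof_pct_history,
         n_iter = length(lof_history),
         converged = decision == "stop_patience",
         stop_reason = sub("^stop_", "", decision),
         times = times, wavenumbers = ds$wavenumbers, config = config),
    class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat("Hard-and-soft MCR-ALS fit: ", ncol(x$C), " components, ",
      x$n_iter, " iterations (", x$stop_reason, ")\n", sep = "")
  cat("  final LOF: ", format(x$lof_pct_history[x$n_iter], digits = 4),
      "%  (SSR ", format(x$lof_history[x$n_iter], digits = 4), ")\n",
      sep = "")
  if (!is.null(x$k_final)) {
    cat("  kinetic constants:\n")
    print(signif(x$k_final, 4))
  }
  invisible(x)
}
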