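#' Phenylalanine-band normalization window
#'
#' Window definition for the internal-intensity reference: the band is
#' integrated over 988-1023 1/cm above a straight baseline fitted jointly to
#' all grid points falling in the 986-990 and 1021-1025 1/cm anchor windows.
#'
#' @param band_lo,band_hi integration window bounds (1/cm).
#' @param base_lo,base_hi length-2 vectors: the low- and high-side baseline
#'   anchor windows (1/cm).
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(band_lo = 988, band_hi = 1023,
                               base_lo = c(986, 990), base_hi = c(1021, 1025)) {
  if (band_hi <= band_lo) stop("band window is empty", call. = FALSE)
  for (w in list(base_lo, base_hi)) {
    if (length(w) != 2L || w[2L] < w[1L]) {
      stop("baseline anchor windows must be length-2 increasing", call. = FALSE)
    }
  }
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 base_lo = base_lo, base_hi = base_hi),
            class = "normalization_spec")
}

# closed-interval membership with exact-comparison guard
in_window <- function(w, lo, hi, tol = 1e-9) w >= lo - tol & w <= hi + tol

trapezoid <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

#' Baseline-corrected phenylalanine band area
#'
#' Integrates a spectrum over the band window above a linear baseline.
#' The baseline is the least-squares straight line through every grid point
#' lying in either anchor window (robust on coarse grids where each window
#' holds several points); the integral is a trapezoid on the native grid, no
#' resampling.
#'
#' @param spectrum numeric vector (a.u.).
#' @param wavenumbers matching axis (1/cm), strictly increasing.
#' @param spec a [normalization_spec()].
#' @return band area (a.u. * 1/cm), strictly positive.
#' @export
phenylalanine_area <- function(spectrum, wavenumbers,
                               spec = normalization_spec()) {
  stopifnot(length(spectrum) == length(wavenumbers))
  anchor <- in_window(wavenumbers, spec$base_lo[1L], spec$base_lo[2L]) |
    in_window(wavenumbers, spec$base_hi[1L], spec$base_hi[2L])
  if (!any(in_window(wavenumbers, spec$base_lo[1L], spec$base_lo[2L])) ||
      !any(in_window(wavenumbers, spec$base_hi[1L], spec$base_hi[2L]))) {
    stop("each baseline anchor window must contain at least one grid point",
         call. = FALSE)
  }
  band <- in_window(wavenumbers, spec$band_lo, spec$band_hi)
  if (sum(band) < 2L) {
    stop("band window must contain at least two grid points", call. = FALSE)
  }
  xa <- wavenumbers[anchor]
  ya <- spectrum[anchor]
  if (length(unique(xa)) == 1L) {
    base_at <- function(x) rep(mean(ya), length(x))
  } else {
    fit <- stats::lm.fit(cbind(1, xa), ya)$coefficients
    base_at <- function(x) fit[1L] + fit[2L] * x
  }
  xb <- wavenumbers[band]
  area <- trapezoid(xb, spectrum[band] - base_at(xb))
  # degenerate means no band above round-off at the spectrum's own scale
  tiny <- 1e-10 * max(diff(range(xb)) * max(abs(spectrum[band])), 1e-300)
  if (!is.finite(area) || area <= tiny) {
    stop("degenerate phenylalanine band: baseline-corrected area is ",
         signif(area, 4), " (no reference band in this spectrum)",
         call. = FALSE)
  }
  area
}

#' Normalize every spectrum to its phenylalanine band area
#'
#' Divides each row of the dataset by its own baseline-corrected band area,
#' making the phenylalanine band the internal intensity reference. The
#' operation is idempotent and invariant to per-row rescaling.
#'
#' @param ds a [spectra_dataset()].
#' @param spec a [normalization_spec()].
#' @return a new `spectra_dataset` whose per-row band areas are all 1.
#' @export
normalize_dataset <- function(ds, spec = normalization_spec()) {
  stopifnot(inherits(ds, "spectra_dataset"))
  areas <- vapply(seq_len(nrow(ds$intensities)), function(i) {
    tryCatch(phenylalanine_area(ds$intensities[i, ], ds$wavenumbers, spec),
             error = function(e) {
               stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
             })
  }, numeric(1L))
  spectra_dataset(ds$intensities / areas, ds$times, ds$wavenumbers, ds$meta)
}

#' Singular-value rank diagnostics
#'
#' Returns the full singular spectrum of the data matrix together with
#' explained-variance fractions. No rank is auto-selected: the user picks the
#' smallest number of components explaining the meaningful variance, leaving
#' pure-noise components out.
#'
#' @param ds a [spectra_dataset()] or a plain matrix.
#' @return An object of class `rank_estimate`: list with `singular_values`,
#'   `variance_fraction`, `cumulative_variance`, and `n_above(threshold)`
#'   counting singular values above `threshold * sv[1]`.
#' @export
#' @examples
#' sim <- simulate_dataset(config = simulation_config(noise_fraction = 0))
#' estimate_rank(sim$dataset)$n_above(1e-10) # 3 components
estimate_rank <- function(ds) {
  m <- if (inherits(ds, "spectra_dataset")) ds$intensities else as.matrix(ds)
  sv <- svd(m, nu = 0, nv = 0)$d
  vf <- sv^2 / sum(sv^2)
  structure(list(singular_values = sv, variance_fraction = vf,
                 cumulative_variance = cumsum(vf),
                 n_above = function(threshold = 1e-10)
                   sum(sv > threshold * sv[1L])),
            class = "rank_estimate")
}

#' @export
print.rank_estimate <- function(x, n = 8L, ...) {
  k <- min(n, length(x$singular_values))
  cat("Singular spectrum (first", k, "values):\n")
  print(data.frame(sv = signif(x$singular_values[seq_len(k)], 5),
                   var_pct = round(100 * x$variance_fraction[seq_len(k)], 3),
                   cum_pct = round(100 * x$cumulative_variance[seq_len(k)], 3)))
  invisible(x)
}

#' Initial concentration estimates from the kinetic model
#'
#' Builds the C0 matrix that starts the ALS iterations: kinetically
#' constrained columns are the ODE solution at the initial constants `k0`;
#' unconstrained columns start as a constant 1 profile (the least-informative
#' choice consistent with a time-invariant background component).
#'
#' @param model a [kinetic_model()].
#' @param k0 initial kinetic constants ([kinetic_params()] or named vector).
#' @param times hour grid of the dataset.
#' @param n_components total component count I.
#' @param constrained_indices which columns the model states occupy (in state
#'   order); default `model$component_map`.
#' @return N x I matrix.
#' @export
initial_concentrations <- function(model, k0, times, n_components,
                                   constrained_indices = model$component_map) {
  constrained_indices <- as.integer(constrained_indices)
  if (length(constrained_indices) != model$n_states) {
    stop("need one constrained column per model state", call. = FALSE)
  }
  if (anyDuplicated(constrained_indices) > 0L ||
      any(constrained_indices < 1L) || any(constrained_indices > n_components)) {
    stop("constrained_indices must be distinct and within 1..n_components",
         call. = FALSE)
  }
  C0 <- matrix(1, nrow = length(times), ncol = n_components)
  sol <- solve_kinetics(model, k0, times)
  C0[, constrained_indices] <- sol$values
  C0
}
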