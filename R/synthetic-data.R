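#' Sum of Gaussian bands on a wavenumber axis
#'
#' Pure component spectra are synthesized as sums of Gaussian bands declared
#' by centre, full width at half maximum and height. Negative heights yield
#' subtractive features.
#'
#' @param wavenumbers spectral axis (1/cm).
#' @param bands data.frame with columns `center` (1/cm), `fwhm` (1/cm),
#'   `height` (a.u.).
#' @return numeric vector, same length as `wavenumbers`.
#' @export
gaussian_bands <- function(wavenumbers, bands) {
  stopifnot(all(c("center", "fwhm", "height") %in% names(bands)))
  out <- numeric(length(wavenumbers))
  for (i in seq_len(nrow(bands))) {
    sigma2 <- (bands$fwhm[i] / (2 * sqrt(2 * log(2))))^2
    out <- out + bands$height[i] *
      exp(-(wavenumbers - bands$center[i])^2 / (2 * sigma2))
  }
  out
}

#' Pure component library for the simulator
#'
#' @param wavenumbers strictly increasing axis (1/cm).
#' @param cell_spectrum baseline cell profile (a.u., >= 0).
#' @param binding_signature drug-plus-binding profile; negative entries encode
#'   the subtractive nucleic-acid features.
#' @param response_signature cellular-response profile (a.u.).
#' @return An object of class `component_library`; the element
#'   `subtractive_channels` flags the channels where the binding signature is
#'   negative.
#' @export
component_library <- function(wavenumbers, cell_spectrum, binding_signature,
                              response_signature) {
  wavenumbers <- as.numeric(wavenumbers)
  J <- length(wavenumbers)
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  }
  for (nm in c("cell_spectrum", "binding_signature", "response_signature")) {
    v <- get(nm)
    if (length(v) != J) stop(nm, " must match the wavenumber axis", call. = FALSE)
  }
  if (any(cell_spectrum < 0)) {
    stop("cell_spectrum must be non-negative", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers,
                 cell_spectrum = as.numeric(cell_spectrum),
                 binding_signature = as.numeric(binding_signature),
                 response_signature = as.numeric(response_signature),
                 subtractive_channels = binding_signature < 0),
            class = "component_library")
}

# band tables for the default library ------------------------------------

.cell_bands <- function() data.frame(
  center = c(621, 645, 785, 811, 852, 938, 1005, 1033, 1095, 1126, 1250,
             1340, 1450, 1578, 1660),
  fwhm   = c(12, 12, 14, 12, 14, 16, 8, 12, 18, 14, 30, 22, 20, 16, 35),
  height = c(0.10, 0.08, 0.45, 0.35, 0.20, 0.15, 1.00, 0.25, 0.30, 0.20,
             0.35, 0.30, 0.55, 0.25, 0.70))

.binding_bands <- function() data.frame(
  center = c(440, 460, 1211, 785, 811),
  fwhm   = c(10, 10, 12, 14, 12),
  height = c(0.50, 0.60, 0.40, -0.30, -0.22))

.response_bands <- function() data.frame(
  center = c(1450, 1680),
  fwhm   = c(18, 24),
  height = c(0.50, 0.15))

#' Default component library
#'
#' Emulates the spectral players of a doxorubicin-inoculated lung cell:
#' a constant cell background (with the phenylalanine reference band at
#' 1005 1/cm and nucleic-acid bands at 785/811 1/cm), a drug-binding
#' signature with the doxorubicin bands at 440, 460 and 1211 1/cm plus
#' *negative* features at the nucleic-acid bands (drug intercalation reduces
#' their intensity), and a slower cellular-response signature dominated by
#' the protein band near 1450 1/cm.
#'
#' @param wn_lo,wn_hi,wn_step wavenumber grid (1/cm); default 400-1800 at
#'   2 1/cm.
#' @return A [component_library()].
#' @export
#' @examples
#' lib <- default_library()
#' lib$wavenumbers[which.max(lib$binding_signature)] # 460 1/cm region
default_library <- function(wn_lo = 400, wn_hi = 1800, wn_step = 2) {
  wn <- seq(wn_lo, wn_hi, by = wn_step)
  component_library(
    wavenumbers = wn,
    cell_spectrum = gaussian_bands(wn, .cell_bands()),
    binding_signature = gaussian_bands(wn, .binding_bands()),
    response_signature = gaussian_bands(wn, .response_bands()))
}

#' Simulation configuration
#'
#' Defaults reproduce the reference simulation: a 0-72 h course sampled every
#' 0.5 h (145 spectra) with 1\% additive uniform noise, uptake and response
#' dynamics from [kinetic_params()] defaults.
#'
#' @param params a [kinetic_params()]; the generating ("true") constants.
#' @param t_start,t_end,t_step time grid (h); `t_step > 0`.
#' @param noise_fraction additive uniform noise amplitude as a fraction of the
#'   maximum intensity of the noiseless matrix (default 0.01).
#' @param seed RNG seed for the noise draw.
#' @param amplitudes named vector `c(binding=, response=)` scaling how much
#'   each unit of Nb / Nr contributes spectrally (a.u.).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params = kinetic_params(),
                              t_start = 0, t_end = 72, t_step = 0.5,
                              noise_fraction = 0.01, seed = 1L,
                              amplitudes = c(binding = 0.35, response = 0.25)) {
  if (t_step <= 0) stop("t_step must be > 0", call. = FALSE)
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  if (noise_fraction < 0) stop("noise_fraction must be >= 0", call. = FALSE)
  if (!all(c("binding", "response") %in% names(amplitudes))) {
    stop("amplitudes must name 'binding' and 'response'", call. = FALSE)
  }
  validate_kinetic_params(unclass(params))
  structure(list(params = params, t_start = t_start, t_end = t_end,
                 t_step = t_step, noise_fraction = noise_fraction,
                 seed = as.integer(seed), amplitudes = amplitudes),
            class = "simulation_config")
}

simulation_time_grid <- function(config) {
  n <- floor((config$t_end - config$t_start) / config$t_step + 1e-9)
  config$t_start + config$t_step * (0:n)
}

# evaluate thunk under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Additive uniform noise
#'
#' Adds uniform noise on `[0, noise_fraction * max(m))` to every entry,
#' mirroring a uniform random-number draw scaled to a stated percentage of
#' the maximum intensity. Reproducible under `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param m numeric matrix.
#' @param noise_fraction >= 0; 0 returns `m` unchanged.
#' @param seed RNG seed.
#' @return matrix of the same shape.
#' @export
add_noise <- function(m, noise_fraction, seed = 1L) {
  if (noise_fraction < 0) stop("noise_fraction must be >= 0", call. = FALSE)
  if (noise_fraction == 0) return(m)
  amp <- noise_fraction * max(m)
  noise <- with_seed(seed, matrix(stats::runif(length(m), 0, amp),
                                  nrow = nrow(m)))
  m + noise
}

#' Simulate a time-resolved Raman dataset
#'
#' Builds each spectrum as
#' `cell_spectrum + a_b * Nb(t) * binding_signature + a_r * Nr(t) * response_signature`
#' where Nb/Nr come from integrating the uptake+response model at the
#' configured constants, and the binding signature carries negative entries
#' at the nucleic-acid bands so drug binding *subtracts* intensity there.
#' Uniform noise is added last. The bilinear ground truth is returned
#' alongside: the noiseless matrix equals `C_true %*% S_true` exactly.
#'
#' @param library a [component_library()]; default [default_library()].
#' @param config a [simulation_config()].
#' @return An object of class `hs_simulation`: list with `dataset` (a
#'   [spectra_dataset()]), `C_true` (N x 3: binding, response, cell),
#'   `S_true` (3 x J), `profiles` (the ODE solution) and `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(config = simulation_config(noise_fraction = 0))
#' nrow(sim$dataset$intensities) # 145
simulate_dataset <- function(library = default_library(),
                             config = simulation_config()) {
  stopifnot(inherits(library, "component_library"),
            inherits(config, "simulation_config"))
  times <- simulation_time_grid(config)
  profiles <- solve_kinetics(kinetic_model("uptake_response"), config$params,
                             times)
  a <- config$amplitudes
  C_true <- cbind(binding = a[["binding"]] * profiles$values[, "Nb"],
                  response = a[["response"]] * profiles$values[, "Nr"],
                  cell = rep(1, length(times)))
  S_true <- rbind(binding = library$binding_signature,
                  response = library$response_signature,
                  cell = library$cell_spectrum)
  D0 <- C_true %*% S_true
  n_neg <- sum(D0 < -1e-12)
  if (n_neg > 0L) {
    warning("amplitude/noise settings drove ", n_neg,
            " intensities negative; clipped to 0", call. = FALSE)
    D0[D0 < 0] <- 0
  }
  D <- add_noise(D0, config$noise_fraction, config$seed)
  ds <- spectra_dataset(D, times, library$wavenumbers,
                        meta = list(source = "hsmcr simulator"))
  structure(list(dataset = ds, C_true = C_true, S_true = S_true,
                 profiles = profiles, config = config),
            class = "hs_simulation")
}

#' @export
print.hs_simulation <- function(x, ...) {
  cat("Simulated dataset (", nrow(x$C_true), " spectra, 3 components, ",
      100 * x$config$noise_fraction, "% noise, seed ", x$config$seed, ")\n",
      sep = "")
  print(x$dataset)
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the dataset as wide CSV (`dataset.csv`), the bilinear ground truth
#' (`C_true.csv`, `S_true.csv`) and a JSON sidecar (`simulation.json`)
#' holding the full configuration, seed included, for exact re-generation.
#'
#' @param sim an `hs_simulation`.
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "hs_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dataset = file.path(dir, "dataset.csv"),
             C_true = file.path(dir, "C_true.csv"),
             S_true = file.path(dir, "S_true.csv"),
             config = file.path(dir, "simulation.json"))
  write_spectra_csv(sim$dataset, paths[["dataset"]])
  ct <- data.frame(time_h = sim$dataset$times, sim$C_true, check.names = FALSE)
  utils::write.csv(format_num_df(ct), paths[["C_true"]], row.names = FALSE,
                   quote = FALSE)
  st <- data.frame(wavenumber = sim$dataset$wavenumbers, t(sim$S_true),
                   check.names = FALSE)
  utils::write.csv(format_num_df(st), paths[["S_true"]], row.names = FALSE,
                   quote = FALSE)
  cfg <- sim$config
  jsonlite::write_json(
    list(params = as.list(unclass(cfg$params)), t_start = cfg$t_start,
         t_end = cfg$t_end, t_step = cfg$t_step,
         noise_fraction = cfg$noise_fraction, seed = cfg$seed,
         amplitudes = as.list(cfg$amplitudes)),
    paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
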