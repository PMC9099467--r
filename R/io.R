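# CSV readers/writers and run reports. Numeric output is written with 15
# significant digits, locale-independent, so a write/read round trip
# reproduces matrices to better than 1e-12 relative.

format_num <- function(x) formatC(x, digits = 15, format = "g", flag = "-")

format_num_df <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) trimws(format_num(col)) else col
  })
  df
}

#' Read a wide-format spectral time course from CSV
#'
#' Expected layout: first column `time_h`, remaining column headers numeric
#' wavenumbers (1/cm), one row per spectrum. Wavenumber columns are reordered
#' ascending if needed (with a warning).
#'
#' @param path CSV file.
#' @return A [spectra_dataset()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("format error: ragged row ", bad, " in ", path, " (", nf[bad],
         " fields, expected ", nf[1L], ")", call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time_h") {
    stop("format error: first column must be 'time_h', found '",
         names(df)[1L], "'", call. = FALSE)
  }
  wn_names <- names(df)[-1L]
  wn <- suppressWarnings(as.numeric(wn_names))
  if (anyNA(wn)) {
    stop("format error: non-numeric wavenumber header '",
         wn_names[which(is.na(wn))[1L]], "'", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (is.unsorted(wn, strictly = TRUE)) {
    warning("wavenumber columns were not ascending; reordered", call. = FALSE)
    ord <- order(wn)
    wn <- wn[ord]
    m <- m[, ord, drop = FALSE]
  }
  spectra_dataset(m, df$time_h, wn, meta = list(source = path))
}

#' Write a spectral dataset to wide CSV
#'
#' @param ds a [spectra_dataset()].
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectra_dataset"))
  df <- data.frame(time_h = ds$times, ds$intensities, check.names = FALSE)
  names(df) <- c("time_h", format_num(ds$wavenumbers))
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# stable polynomial hash over a serialized object, for run provenance
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write an MCR fit to disk
#'
#' Emits `C.csv` (time_h x component), `S.csv` (wavenumber x component),
#' `k_history.csv` (iteration x parameter, when a kinetic link ran) and
#' `report.json` (config hash, stop reason, iteration count, final SSR and
#' \%LOF, final constants).
#'
#' @param result an `mcr_result` from [run_mcr_als()].
#' @param outdir output directory, created if absent.
#' @return invisibly, named vector of paths written.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "mcr_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  comp <- paste0("component_", seq_len(ncol(result$C)))
  paths <- c(C = file.path(outdir, "C.csv"), S = file.path(outdir, "S.csv"),
             report = file.path(outdir, "report.json"))

  cdf <- data.frame(time_h = result$times, result$C, check.names = FALSE)
  names(cdf) <- c("time_h", comp)
  utils::write.csv(format_num_df(cdf), paths[["C"]], row.names = FALSE,
                   quote = FALSE)

  sdf <- data.frame(wavenumber = result$wavenumbers, t(result$S),
                    check.names = FALSE)
  names(sdf) <- c("wavenumber", comp)
  utils::write.csv(format_num_df(sdf), paths[["S"]], row.names = FALSE,
                   quote = FALSE)

  if (!is.null(result$k_history)) {
    paths[["k_history"]] <- file.path(outdir, "k_history.csv")
    kdf <- data.frame(iteration = seq_len(nrow(result$k_history)),
                      result$k_history, check.names = FALSE)
    utils::write.csv(format_num_df(kdf), paths[["k_history"]],
                     row.names = FALSE, quote = FALSE)
  }

  report <- list(
    config_hash = config_hash(result$config),
    n_components = ncol(result$C),
    stop_reason = result$stop_reason,
    converged = result$converged,
    n_iter = result$n_iter,
    final_ssr = result$lof_history[result$n_iter],
    final_lof_pct = result$lof_pct_history[result$n_iter],
    k_final = if (is.null(result$k_final)) NULL
              else as.list(result$k_final),
    param_names = if (is.null(result$k_final)) NULL
                  else names(result$k_final))
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read a run configuration file (YAML or JSON)
#'
#' The two formats share one schema; the parser is chosen by file extension
#' (`.json` vs anything else = YAML).
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Build a constraint configuration from a parsed config list
#'
#' Schema: `n_components`; optional `nonneg_conc` / `nonneg_spec` (logical
#' vectors); optional `kinetic` with `model` (a built-in name, or a list with
#' `name`, `states`, `rates`, `params` declaring a custom system),
#' `k0` (named list) and `components`; optional `max_iter`, `patience`,
#' `rel_tol`.
#'
#' @param cfg named list, e.g. from [read_run_config()].
#' @return A [constraint_config()].
#' @export
constraint_config_from_list <- function(cfg) {
  kinetic <- NULL
  if (!is.null(cfg$kinetic)) {
    mspec <- cfg$kinetic$model
    model <- if (is.character(mspec)) {
      kinetic_model(mspec)
    } else {
      custom_kinetic_model(mspec$name, unlist(mspec$states),
                           unlist(mspec$rates), unlist(mspec$params),
                           initial_state = mspec$initial_state,
                           component_map = mspec$component_map)
    }
    k0 <- unlist(cfg$kinetic$k0)
    kinetic <- list(model = model, k0 = k0,
                    components = cfg$kinetic$components)
  }
  constraint_config(
    n_components = cfg$n_components,
    nonneg_conc = if (is.null(cfg$nonneg_conc)) TRUE else unlist(cfg$nonneg_conc),
    nonneg_spec = if (is.null(cfg$nonneg_spec)) NULL else unlist(cfg$nonneg_spec),
    kinetic = kinetic,
    max_iter = if (is.null(cfg$max_iter)) 200L else cfg$max_iter,
    patience = if (is.null(cfg$patience)) 20L else cfg$patience,
    rel_tol = if (is.null(cfg$rel_tol)) 0.01 else cfg$rel_tol)
}
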