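#' Time-course spectral dataset
#'
#' Container for a wide-format time-resolved spectral matrix: N spectra
#' (rows, one per inoculation time) by J wavenumber channels (columns).
#'
#' @param intensities N x J numeric matrix of intensities (a.u.).
#' @param times length-N vector of acquisition times (h), non-decreasing.
#' @param wavenumbers length-J vector of Raman shifts (1/cm), strictly
#'   increasing.
#' @param meta free-form named list of labels (cell line, compartment, ...).
#'
#' @return An object of class `spectra_dataset`.
#' @export
#' @examples
#' ds <- spectra_dataset(matrix(1, 3, 4), times = c(0, 1, 2),
#'                       wavenumbers = c(400, 500, 600, 700))
spectra_dataset <- function(intensities, times, wavenumbers, meta = list()) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  times <- as.numeric(times)
  wavenumbers <- as.numeric(wavenumbers)
  if (nrow(intensities) < 2L || ncol(intensities) < 2L) {
    stop("dataset needs at least 2 spectra and 2 spectral variables",
         call. = FALSE)
  }
  if (length(times) != nrow(intensities)) {
    stop("length(times) must equal nrow(intensities)", call. = FALSE)
  }
  if (length(wavenumbers) != ncol(intensities)) {
    stop("length(wavenumbers) must equal ncol(intensities)", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities contain NaN/Inf", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) < 0)) {
    stop("times must be finite and non-decreasing", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be finite and strictly increasing", call. = FALSE)
  }
  dimnames(intensities) <- NULL
  structure(list(intensities = intensities, times = times,
                 wavenumbers = wavenumbers, meta = meta),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("Spectral time course:", nrow(x$intensities), "spectra x",
      ncol(x$intensities), "wavenumber channels\n")
  cat("  t:", x$times[1L], "-", x$times[length(x$times)], "h;  wavenumbers:",
      x$wavenumbers[1L], "-", x$wavenumbers[length(x$wavenumbers)], "1/cm\n")
  if (length(x$meta) > 0L) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$intensities)
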