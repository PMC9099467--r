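# Active-set least squares with per-variable non-negativity flags.
#
# Lawson-Hanson NNLS generalised so that only flagged variables are
# constrained: unflagged variables live permanently in the passive set.
# Smallest-index (Bland-style) entering choice prevents cycling; a
# 3 x problem-size cap on outer iterations is a hard stop.

ls_coef <- function(A, b) {
  co <- qr.coef(qr(A), b)
  co[is.na(co)] <- 0
  co
}

# min ||A x - b||^2  s.t.  x[nonneg] >= 0
active_set_ls <- function(A, b, nonneg) {
  n <- ncol(A)
  x <- numeric(n)
  P <- !nonneg                       # free variables start (and stay) passive
  if (any(P)) x[P] <- ls_coef(A[, P, drop = FALSE], b)
  tol_w <- 1e-10 * (1 + max(abs(crossprod(A, b))))
  cap <- max(10L, 3L * n)
  for (outer in seq_len(cap)) {
    w <- crossprod(A, b - A %*% x)
    cand <- which(!P & w > tol_w)
    if (length(cand) == 0L) break
    P[min(cand)] <- TRUE             # Bland-style entering rule
    repeat {
      z <- numeric(n)
      z[P] <- ls_coef(A[, P, drop = FALSE], b)
      bad <- which(P & nonneg & z < 0)
      if (length(bad) == 0L) {
        x <- z
        break
      }
      alpha <- min(x[bad] / (x[bad] - z[bad]))
      x <- x + alpha * (z - x)
      leave <- P & nonneg & x <= 1e-12
      x[leave] <- 0
      P[leave] <- FALSE
    }
  }
  x
}

# Multi right-hand-side wrapper: unconstrained QR solve first, the active-set
# routine only on columns whose flagged entries come out negative.
constrained_ls <- function(A, B, nonneg) {
  B <- as.matrix(B)
  qa <- qr(A)
  X <- qr.coef(qa, B)
  X[is.na(X)] <- 0
  X <- matrix(X, ncol = ncol(B))
  if (!any(nonneg)) return(X)
  viol <- which(apply(X[nonneg, , drop = FALSE] < 0, 2L, any))
  for (j in viol) X[, j] <- active_set_ls(A, B[, j], nonneg)
  X
}

check_full_rank <- function(M, what) {
  if (qr(M)$rank < ncol(M)) {
    stop("ill-conditioned ", what, ": rank ", qr(M)$rank, " < ", ncol(M),
         " columns (condition number ", format(kappa(M), digits = 3), ")",
         call. = FALSE)
  }
}

#' Constrained spectral estimation (S step)
#'
#' For each wavenumber channel j solves
#' `min || D[, j] - C s ||^2` subject to `s[i] >= 0` for flagged components;
#' unflagged components are unconstrained. Exact active-set minimisation, not
#' clipping of the unconstrained solution.
#'
#' @param D N x J data matrix.
#' @param C N x I concentration matrix, full column rank.
#' @param nonneg_flags logical length I (recycled if length 1).
#' @return I x J spectra matrix.
#' @export
nnls_rows <- function(D, C, nonneg_flags = TRUE) {
  C <- as.matrix(C)
  D <- as.matrix(D)
  stopifnot(nrow(D) == nrow(C))
  nonneg <- rep_len(as.logical(nonneg_flags), ncol(C))
  check_full_rank(C, "concentration matrix")
  constrained_ls(C, D, nonneg)
}

#' Constrained concentration estimation (C step)
#'
#' Mirror of [nnls_rows()]: for each time point i solves
#' `min || D[i, ] - t(S) c ||^2` subject to non-negativity on flagged
#' components.
#'
#' @param D N x J data matrix.
#' @param S I x J spectra matrix, full row rank.
#' @param nonneg_flags logical length I (recycled if length 1).
#' @return N x I concentration matrix.
#' @export
nnls_cols <- function(D, S, nonneg_flags = TRUE) {
  S <- as.matrix(S)
  D <- as.matrix(D)
  stopifnot(ncol(D) == ncol(S))
  nonneg <- rep_len(as.logical(nonneg_flags), nrow(S))
  check_full_rank(t(S), "spectra matrix")
  t(constrained_ls(t(S), t(D), nonneg))
}
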