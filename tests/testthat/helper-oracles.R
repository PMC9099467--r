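# Independent oracles and small fixture builders shared across test files.

# Global minimizer of min ||A x - b||^2 s.t. x[nonneg] >= 0 by enumerating
# every clamp pattern of the flagged variables: solve the unconstrained LS on
# the complement, keep feasible candidates, return the feasible minimum.
enum_constrained_ls <- function(A, b, nonneg) {
  n <- ncol(A)
  flagged <- which(nonneg)
  best_x <- NULL
  best_ssr <- Inf
  for (mask in 0:(2^length(flagged) - 1L)) {
    clamped <- flagged[bitwAnd(mask, 2^(seq_along(flagged) - 1L)) > 0]
    free <- setdiff(seq_len(n), clamped)
    x <- numeric(n)
    if (length(free) > 0L) {
      co <- qr.coef(qr(A[, free, drop = FALSE]), b)
      co[is.na(co)] <- 0
      x[free] <- co
    }
    if (any(x[flagged] < -1e-12)) next
    ssr <- sum((A %*% x - b)^2)
    if (ssr < best_ssr - 1e-12) {
      best_ssr <- ssr
      best_x <- x
    }
  }
  list(x = best_x, ssr = best_ssr)
}

# indices of interior local maxima; a band centred between two grid points
# makes a two-point plateau, so equality is allowed on one side
local_maxima <- function(y) {
  n <- length(y)
  mid <- y[2:(n - 1L)]
  left <- y[1:(n - 2L)]
  right <- y[3:n]
  which((mid > left & mid >= right) | (mid >= left & mid > right)) + 1L
}

# does `y` have a local maximum within +/- tol_wn of `center` on axis `wn`?
has_peak_near <- function(y, wn, center, tol_wn = 5) {
  idx <- local_maxima(y)
  any(abs(wn[idx] - center) <= tol_wn)
}

# small random bilinear instance for ALS property tests
random_bilinear <- function(N = 12L, J = 8L, I = 2L, noise_sd = 0.05) {
  C <- matrix(stats::runif(N * I, 0, 1), N, I)
  S <- matrix(stats::runif(I * J, 0, 1), I, J)
  D <- C %*% S + matrix(stats::rnorm(N * J, sd = noise_sd), N, J)
  list(D = D, C = C, S = S)
}

# fast, reduced-size simulation used where full-scale runs are not the point
small_sim_config <- function(...) {
  simulation_config(t_end = 36, t_step = 1.5, ...)
}
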