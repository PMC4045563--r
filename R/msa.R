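#' Structure function K_q(d) of a 1D signal
#'
#' Computes the normalized q-th order moment of the signal increments at lag
#' `d`,
#' \deqn{K_q(d) = \frac{\langle |S(t+d) - S(t)|^q \rangle}{\langle |S(t)|^q \rangle},}
#' where the numerator averages over the `T - d` valid start points and the
#' denominator over all `T` samples. The ratio is invariant under rescaling
#' of the signal by any nonzero constant, since both moments pick up the same
#' factor `|c|^q`.
#'
#' @param signal numeric vector, the signal S(t) sampled at unit intervals.
#' @param q positive real moment order.
#' @param d positive integer lag, `d <= length(signal) - 1`.
#' @return a single nonnegative number, K_q(d).
#' @examples
#' structure_function(c(1, 2, 3, 4, 5), q = 1, d = 2) # 2/3
#' @seealso [structure_function_table()], [estimate_hurst()]
#' @export
structure_function <- function(signal, q, d) {
  signal <- validate_signal(signal)
  stopifnot(is.numeric(q), length(q) == 1L, q > 0)
  d <- validate_lag(d, length(signal))
  n <- length(signal)
  denom <- mean(abs(signal)^q)
  if (denom == 0) {
    stop("degenerate signal: all values are zero, K_q(d) undefined",
         call. = FALSE)
  }
  num <- mean(abs(signal[(1L + d):n] - signal[1L:(n - d)])^q)
  num / denom
}

#' Structure-function table over a grid of moment orders and lags
#'
#' Evaluates K_q(d) for every `q` in `q_values` and every lag `d = 1, ...,
#' d_max`. Increments at each lag are computed once and reused across moment
#' orders.
#'
#' @param signal numeric vector of length at least `d_max + 2`.
#' @param q_values positive moment orders (default `1:6`).
#' @param d_max maximum lag (default `19`).
#' @return an object of class `"sf_table"`: a list with elements `q_values`,
#'   `d_values` and the matrix `K` (rows = q, columns = d).
#' @export
structure_function_table <- function(signal, q_values = 1:6, d_max = 19L) {
  signal <- validate_signal(signal)
  stopifnot(is.numeric(q_values), length(q_values) >= 1L, all(q_values > 0))
  d_max <- as.integer(d_max)
  n <- length(signal)
  if (d_max < 1L) stop("d_max must be a positive integer", call. = FALSE)
  if (n < d_max + 2L) {
    stop(sprintf("signal too short: length %d < d_max + 2 = %d",
                 n, d_max + 2L), call. = FALSE)
  }
  denom <- vapply(q_values, function(q) mean(abs(signal)^q), numeric(1))
  if (any(denom == 0)) {
    stop("degenerate signal: all values are zero, K_q(d) undefined",
         call. = FALSE)
  }
  K <- matrix(NA_real_, nrow = length(q_values), ncol = d_max,
              dimnames = list(q = as.character(q_values),
                              d = as.character(seq_len(d_max))))
  for (d in seq_len(d_max)) {
    incr <- abs(signal[(1L + d):n] - signal[1L:(n - d)])
    for (i in seq_along(q_values)) {
      K[i, d] <- mean(incr^q_values[i]) / denom[i]
    }
  }
  structure(list(q_values = as.numeric(q_values),
                 d_values = seq_len(d_max),
                 K = K),
            class = "sf_table")
}

#' @export
print.sf_table <- function(x, ...) {
  cat(sprintf("Structure-function table: %d moment orders x %d lags\n",
              length(x$q_values), length(x$d_values)))
  print(signif(x$K, 4))
  invisible(x)
}

#' @export
as.data.frame.sf_table <- function(x, ...) {
  data.frame(q = rep(x$q_values, times = length(x$d_values)),
             d = rep(x$d_values, each = length(x$q_values)),
             K = as.vector(x$K))
}

#' Generalized Hurst spectrum from a structure-function table
#'
#' For each moment order q, fits an ordinary least-squares regression of
#' `log K_q(d)` on `log d` over all tabulated lags and sets
#' `H(q) = slope / q`, following the scaling law `K_q(d) proportional to
#' d^(q H(q))`. `H(2)` is the classic Hurst exponent; a flat spectrum
#' (H(q) constant in q) indicates a monofractal signal.
#'
#' Any zero entry K_q(d) makes the logarithm undefined and aborts estimation
#' with an error naming the offending (q, d) pair; lags are never silently
#' dropped, since that would change the regression support invisibly.
#'
#' @param table an `"sf_table"` from [structure_function_table()].
#' @return an object of class `"hurst_spectrum"`: list with `q_values`, `H`,
#'   `slope` (= q * H(q)), `intercept` and `r_squared` per moment order.
#' @examples
#' tab <- structure_function_table(cumsum(rnorm(4096)), q_values = 1:6)
#' estimate_hurst(tab)
#' @export
estimate_hurst <- function(table) {
  stopifnot(inherits(table, "sf_table"))
  if (length(table$d_values) < 2L) {
    stop("insufficient lags: at least 2 distinct d required for regression",
         call. = FALSE)
  }
  zero <- which(table$K == 0, arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    stop(sprintf(
      "degenerate signal: K_q(d) = 0 at q = %s, d = %d; log-log fit undefined",
      format(table$q_values[zero[1, 1]]), table$d_values[zero[1, 2]]),
      call. = FALSE)
  }
  x <- log(table$d_values)
  nq <- length(table$q_values)
  slope <- intercept <- r2 <- numeric(nq)
  for (i in seq_len(nq)) {
    y <- log(table$K[i, ])
    xc <- x - mean(x)
    slope[i] <- sum(xc * y) / sum(xc^2)
    intercept[i] <- mean(y) - slope[i] * mean(x)
    ss_res <- sum((y - intercept[i] - slope[i] * x)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2[i] <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  }
  structure(list(q_values = table$q_values,
                 H = slope / table$q_values,
                 slope = slope,
                 intercept = intercept,
                 r_squared = r2),
            class = "hurst_spectrum")
}

#' @export
print.hurst_spectrum <- function(x, ...) {
  cat("Generalized Hurst spectrum H(q):\n")
  print(data.frame(q = x$q_values, H = round(x$H, 4),
                   slope = round(x$slope, 4),
                   r_squared = round(x$r_squared, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.hurst_spectrum <- function(x, ...) {
  data.frame(q = x$q_values, H = x$H, slope = x$slope,
             r_squared = x$r_squared)
}

#' Hurst spectrum of a signal in one call
#'
#' Convenience wrapper: [structure_function_table()] followed by
#' [estimate_hurst()].
#'
#' @inheritParams structure_function_table
#' @return a `"hurst_spectrum"` object.
#' @export
hurst_spectrum <- function(signal, q_values = 1:6, d_max = 19L) {
  estimate_hurst(structure_function_table(signal, q_values, d_max))
}

validate_signal <- function(signal) {
  if (inherits(signal, "grayscale_image")) {
    stop("expected a 1D signal; use concatenate_rows() on images first",
         call. = FALSE)
  }
  signal <- as.numeric(signal)
  if (length(signal) < 2L) {
    stop("signal must contain at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(signal))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  signal
}

validate_lag <- function(d, n) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != as.integer(d)) {
    stop("lag d must be a positive integer", call. = FALSE)
  }
  d <- as.integer(d)
  if (d >= n) {
    stop(sprintf("invalid lag: d = %d must be < signal length %d", d, n),
         call. = FALSE)
  }
  d
}
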