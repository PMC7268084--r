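# Butterworth bandpass design via the analog prototype -> bandpass
# transform -> bilinear mapping, matching the classical DSP construction
# (an order-N prototype yields 2N poles, i.e. coefficient vectors of
# length 2N+1).

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Butterworth bandpass filter coefficients
#'
#' Designs a digital Butterworth bandpass filter (prototype order `order`,
#' so `2 * order` poles) via the bilinear transform with frequency
#' pre-warping.
#'
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs sampling frequency in Hz.
#' @param order analog prototype order (default 4).
#' @return List with numerator `b` and denominator `a` (length
#'   `2 * order + 1`, `a[1] == 1`).
#' @export
butter_bandpass <- function(low, high, fs, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("butter_bandpass: need 0 < low < high < Nyquist (", fs / 2, " Hz)")
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  s_poles <- c()
  for (p in proto) {
    bp <- bw * p
    disc <- sqrt(bp^2 / 4 - w0^2 + 0i)
    s_poles <- c(s_poles, bp / 2 + disc, bp / 2 - disc)
  }
  gain <- bw^order
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  z_zeros <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  k_d <- gain * Re(fs2^order / prod(fs2 - s_poles))
  b <- Re(poly_from_roots(z_zeros)) * k_d
  a <- Re(poly_from_roots(z_poles))
  list(b = b, a = a / a[1])
}

#' Zero-phase filtering
#'
#' Forward-backward application of an IIR filter with odd-symmetric edge
#' padding and steady-state initial conditions, yielding zero phase
#' distortion and squared magnitude response.
#'
#' @param b,a filter coefficients as from [butter_bandpass()].
#' @param x numeric vector or a matrix with time along rows.
#' @return Filtered vector/matrix of the same shape.
#' @export
filtfilt <- function(b, a, x) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  padlen <- 3L * (n - 1L)
  if (is.matrix(x)) return(cpp_filtfilt_mat(b, a, x, padlen))
  as.vector(cpp_filtfilt_mat(b, a, matrix(x, ncol = 1), padlen))
}

# Remove per-column linear trend (intercept + slope).
detrend_linear <- function(x) {
  one_col <- !is.matrix(x)
  if (one_col) x <- matrix(x, ncol = 1)
  t_idx <- seq_len(nrow(x))
  X <- cbind(1, t_idx - mean(t_idx))
  res <- x - X %*% solve(crossprod(X), crossprod(X, x))
  if (one_col) as.vector(res) else res
}
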