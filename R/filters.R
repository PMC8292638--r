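# IIR filter design and zero-phase filtering.
#
# No filter-design package ships with this stack, so the standard digital
# Butterworth construction (analog prototype -> band transform -> bilinear
# transform) is implemented here, together with steady-state initial
# conditions and forward-backward (zero-phase) application.  All filtering in
# the oscillation pipeline goes through these routines.

# polynomial coefficients (highest power first) from complex roots
poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, rt * p)
  p
}

#' Design a digital Butterworth filter
#'
#' Computes transfer-function coefficients for a lowpass, highpass, or
#' bandpass Butterworth filter via the bilinear transform, matching the usual
#' engineering convention (cutoffs as fractions of the Nyquist frequency).
#'
#' @param n Filter order (a bandpass doubles the final order).
#' @param w Cutoff, as a fraction of Nyquist in (0, 1); length 2 for
#'   `type = "pass"`.
#' @param type `"low"`, `"high"`, or `"pass"`.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @examples
#' bf <- butter_design(3, 80 / 500, "low")  # 80 Hz lowpass at fs = 1000
#' @export
butter_design <- function(n, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (type == "pass" && length(w) != 2L)
    stop("bandpass design needs two cutoffs")
  if (any(w <= 0) || any(w >= 1))
    stop("cutoffs must lie strictly inside (0, 1) as fractions of Nyquist")
  fs <- 2
  warped <- 2 * fs * tan(pi * w / fs)

  # analog lowpass prototype, cutoff 1 rad/s
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  gain <- 1

  if (type == "low") {
    wo <- warped
    p <- wo * p
    gain <- gain * wo^n
  } else if (type == "high") {
    wo <- warped
    p <- wo / p
    z <- rep(0 + 0i, n)
    # prototype has no zeros; Butterworth denominator constant term is 1
  } else {
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    p <- p * bw / 2
    p <- c(p + sqrt(p^2 - wo^2), p - sqrt(p^2 - wo^2))
    z <- rep(0 + 0i, n)
    gain <- gain * bw^n
  }

  # bilinear transform
  fs2 <- 2 * fs
  degree <- length(p) - length(z)
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, degree))
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))

  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a / a[1])
}

# steady-state initial state of the direct-form-II-transposed filter for a
# unit-step input (scipy's lfilter_zi construction)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1L) return(numeric(0))
  comp <- rbind(-a[-1] / a[1],
                cbind(diag(1, n - 2), rep(0, n - 2)))
  iminusa <- diag(n - 1) - t(comp)
  bvec <- b[-1] - a[-1] * b[1]
  solve(iminusa, bvec)
}

# causal IIR filter with initial state, vectorized through stats::filter:
# total response = zero-state response + zero-input response of the state
lfilter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v[nb:length(xp)])
  if (length(a) > 1L) {
    y <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  } else {
    y <- v
  }
  if (!is.null(zi) && length(zi)) {
    e <- c(zi, rep(0, length(x) - length(zi)))[seq_along(x)]
    if (length(a) > 1L) {
      yzi <- as.numeric(stats::filter(e, -a[-1], method = "recursive"))
    } else {
      yzi <- e
    }
    y <- y + yzi
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forward and backward with odd-reflection edge padding
#' and steady-state initial conditions, so that the output has no phase lag
#' and oscillation peaks are not displaced.
#'
#' @param b,a Transfer-function coefficients, e.g. from [butter_design()].
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  nfact <- 3L * max(length(a), length(b))
  if (n <= nfact)
    stop("signal too short for the filter's edge transient (need > ",
         nfact, " samples)")
  ext <- c(2 * x[1] - x[(nfact + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - nfact)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1):(nfact + n)]
}

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal whose modulus is the amplitude
#' envelope; squared modulus is the instantaneous band power used for the
#' gamma features.
#'
#' @param x Numeric signal (any length).
#' @return Complex vector, same length as `x`.
#' @export
analytic_signal <- function(x) {
  n0 <- length(x)
  # mixed-radix FFTs degrade on lengths with large prime factors; pad by odd
  # reflection to the next 5-smooth length and truncate afterwards
  m <- stats::nextn(n0, c(2, 3, 5))
  if (m > n0) {
    extra <- m - n0
    if (extra <= n0 - 1) {
      x <- c(x, 2 * x[n0] - x[(n0 - 1):(n0 - extra)])
    } else {
      x <- c(x, rep(x[n0], extra))
    }
  }
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(stats::fft(x) * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Decimate a signal by an integer factor
#'
#' Anti-alias lowpass (zero-phase Butterworth, cutoff at 0.8 of the output
#' Nyquist) followed by subsampling.  Plain subsampling is selectable for
#' signals known to be band-limited already.
#'
#' @param x Numeric signal.
#' @param factor Integer decimation factor (e.g. 30 for 30 kHz to 1 kHz).
#' @param antialias Apply the anti-alias filter first (default `TRUE`).
#' @return Decimated signal of length `ceiling(length(x) / factor)`.
#' @export
decimate_signal <- function(x, factor, antialias = TRUE) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(x)
  if (antialias) {
    bf <- butter_design(3, 0.8 / factor, "low")
    x <- zero_phase_filter(bf$b, bf$a, x)
  }
  x[seq(1L, length(x), by = factor)]
}
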