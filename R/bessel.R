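#' Causal Bessel low-pass filter
#'
#' Digital equivalent of the analog n-pole Bessel filter used in
#' electrophysiology acquisition chains.  The analog prototype poles are the
#' roots of the reverse Bessel polynomial, renormalized so the −3 dB point
#' sits at the cutoff (magnitude normalization); the digital filter follows by
#' prewarped bilinear transform ([signal::bilinear()]) and is applied causally.
#' DC gain is normalized to exactly 1.
#'
#' @param samples input series (pA).
#' @param rate sampling rate of `samples` (Hz).
#' @param cutoff −3 dB cutoff (Hz); must satisfy `0 < cutoff < rate/2`.
#' @param order number of poles (>= 1).
#' @return filtered series, same length as the input.
#' @examples
#' y <- bessel_lowpass(rep(1, 200), 5000, 1000, 4)
#' tail(y, 1)  # ~1: unity DC gain
#' @export
bessel_lowpass <- function(samples, rate, cutoff, order = 4) {
  stopifnot(is.numeric(samples))
  ba <- bessel_design(rate, cutoff, order)
  y <- iir_df2t(ba$b, ba$a, as.numeric(samples))
  if (!all(is.finite(y))) stop("filter output not finite", call. = FALSE)
  y
}

# Digital (b, a) coefficients; cached per (rate, cutoff, order).
bessel_design <- local({
  cache <- new.env(parent = emptyenv())
  function(rate, cutoff, order) {
    if (!is.numeric(rate) || !is.numeric(cutoff) || cutoff <= 0 ||
        cutoff >= rate / 2)
      stop("need 0 < cutoff < rate/2", call. = FALSE)
    order <- as.integer(order)
    if (is.na(order) || order < 1L || order > 12L)
      stop("order must be an integer in 1..12", call. = FALSE)
    key <- paste(rate, cutoff, order, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- bessel_prototype_poles(order)
    wc <- 2 * rate * tan(pi * cutoff / rate)       # prewarped analog cutoff
    ps <- p * wc
    zd <- signal::bilinear(Sz = numeric(0), Sp = ps, Sg = Re(prod(-ps)),
                           T = 1 / rate)
    b <- Re(zd$gain * signal::poly(zd$zero))
    a <- Re(signal::poly(zd$pole))
    b <- b * (sum(a) / sum(b))                      # DC gain exactly 1
    cache[[key]] <- list(b = b, a = a)
    cache[[key]]
  }
})

# Poles of the magnitude-normalized analog Bessel prototype (−3 dB at 1 rad/s).
bessel_prototype_poles <- function(order) {
  n <- order
  # reverse Bessel polynomial, ascending coefficients
  co <- vapply(0:n, function(k)
    factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k)),
    numeric(1))
  p <- polyroot(co)
  # scale so |H(j w)|^2 = 1/2 at w = 1
  mag2 <- function(w) {
    s <- complex(real = 0, imaginary = w)
    abs(co[1] / sum(co * s^(0:n)))^2
  }
  w3 <- uniroot(function(w) vapply(w, mag2, numeric(1)) - 0.5,
                c(1e-3, 10 * n), tol = 1e-13)$root
  p / w3
}
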