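# Internal 2-D FFT wrappers around the compiled kernels, plus a guard that
# drops the imaginary residue of a real-signal round trip only after checking
# it is numerically negligible.

.fft2 <- function(x) {
  if (is.complex(x)) .fft2_cpx_cpp(x, FALSE) else .fft2_real_cpp(x)
}

.ifft2 <- function(x) {
  if (!is.complex(x)) x <- x + 0i
  .fft2_cpx_cpp(x, TRUE)
}

# inverse transform expected to be real; assert residue and return Re
.ifft2_real <- function(x, tol = 1e-8) {
  y <- .ifft2(x)
  scale <- max(1, max(abs(Re(y))))
  if (max(abs(Im(y))) > tol * scale)
    stop("internal error: imaginary residue ", max(abs(Im(y))),
         " exceeds tolerance in a real inverse FFT")
  Re(y)
}

# gaussian low-pass via FFT (periodic boundary); used by the phantom
# generator for band-limited textures
.gauss_smooth <- function(x, sigma) {
  n1 <- nrow(x); n2 <- ncol(x)
  w1 <- .fft_freqs(n1); w2 <- .fft_freqs(n2)
  g <- exp(-outer(w1^2, rep(1, n2)) * sigma^2 / 2 -
             outer(rep(1, n1), w2^2) * sigma^2 / 2)
  .ifft2_real(.fft2(x) * g, tol = 1e-6)
}

# angular frequencies of an n-point DFT grid, in [-pi, pi)
.fft_freqs <- function(n) {
  k <- 0:(n - 1L)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  2 * pi * k / n
}
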