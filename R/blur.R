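# FFT-based periodic Gaussian convolution.
#
# Used both as the diffraction PSF on expected photon rates and as the exact
# propagator of the 2-D diffusion equation (a Gaussian of variance 2*D*dt).
# Periodic boundaries make the convolution mass-conserving to rounding error,
# which the diffusion renderer relies on; callers keep features away from the
# field edge.
gaussian_blur <- function(field, sigma_px) {
  if (sigma_px <= 0) return(field)
  nr <- nrow(field); nc <- ncol(field)
  kr <- gauss_kernel_1d(nr, sigma_px)
  kc <- gauss_kernel_1d(nc, sigma_px)
  K <- outer(kr, kc)
  Re(fft(fft(field) * fft(K), inverse = TRUE)) / (nr * nc)
}

# Periodic 1-D Gaussian kernel of length n centred on index 1, summing to 1.
gauss_kernel_1d <- function(n, sigma) {
  x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}
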