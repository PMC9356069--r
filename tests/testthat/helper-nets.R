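# small network for structural/semantic circuit tests (fast to build and run)
small_circuit_params <- function(...) {
  circuit_params(n_side = 15, N_I = 60, K_EE = 40, K_IE = 40, K_EI = 12,
                 K_II = 12, ...)
}

# spectral (FFT) evaluation of the Riesz operator of any order on a periodic
# grid: the independent oracle for the fractional-centered-difference route
spectral_riesz <- function(f, order, spacing) {
  n <- length(f)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * 2 * pi / (n * spacing)
  mult <- abs(k)^order
  mult[1] <- 0
  Re(stats::fft(stats::fft(f) * mult, inverse = TRUE)) / n
}
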