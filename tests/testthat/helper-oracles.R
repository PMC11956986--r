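# Independent oracles used across the suite. None of these call the package's
# spectral code: the Dirichlet-kernel oracle evaluates the DFT of a sinusoid
# mixture as an explicit geometric sum.

# Closed-form single-sided amplitude spectrum of sum_j A_j sin(2 pi f_j t + phi_j)
# sampled at fs for N samples. Returns the first floor(N/2)+1 bins.
dirichlet_spectrum <- function(A, f, phi, fs, N) {
  nb <- floor(N / 2) + 1L
  geo <- function(delta) {
    # sum_{n=0}^{N-1} exp(1i * delta * n), stable at delta ~ 0
    if (abs(delta %% (2 * pi)) < 1e-13 || abs(delta %% (2 * pi) - 2 * pi) < 1e-13)
      return(complex(real = N, imaginary = 0))
    (1 - exp(1i * delta * N)) / (1 - exp(1i * delta))
  }
  amps <- numeric(nb)
  for (k in seq_len(nb)) {
    wk <- 2 * pi * (k - 1) / N
    X <- 0 + 0i
    for (j in seq_along(A)) {
      th <- 2 * pi * f[j] / fs
      X <- X + A[j] / (2i) *
        (exp(1i * phi[j]) * geo(th - wk) - exp(-1i * phi[j]) * geo(-th - wk))
    }
    sc <- if (k == 1 || (N %% 2 == 0 && k == nb)) 1 else 2
    amps[k] <- sc * Mod(X) / N
  }
  amps
}

# Neighbor-bin subtraction + 3-bin target estimate applied to a raw amplitude
# vector, written long-hand (loops, no package code).
oracle_target <- function(amps, delta_f, f0, offsets = c(-4, -3, 3, 4)) {
  nb <- length(amps)
  corr <- numeric(nb)
  for (k in seq_len(nb)) {
    nbrs <- k + offsets
    nbrs <- nbrs[nbrs >= 1 & nbrs <= nb]
    corr[k] <- amps[k] - mean(amps[nbrs])
  }
  k <- round(f0 / delta_f) + 1L
  mean(corr[(k - 1):(k + 1)])
}

# Oracle SSEP estimates for a noiseless multi-sine epoch (the 1..33 s window
# of a signal starting at stimulus onset), for each target frequency.
oracle_ssep <- function(A, f, phi, fs, target_freqs,
                        start_offset_s = 1, length_s = 32) {
  N <- round(length_s * fs)
  # epoching shifts each component's phase by 2 pi f t0
  phi_ep <- phi + 2 * pi * f * start_offset_s
  amps <- dirichlet_spectrum(A, f, phi_ep, fs, N)
  vapply(target_freqs, function(f0) oracle_target(amps, fs / N, f0),
         numeric(1))
}

# Small helper: subjects x conditions matrix from a tidy ssep table
ssep_wide <- function(ssep, f0) {
  sub <- ssep[ssep$frequency_hz == f0, ]
  wide <- stats::reshape(sub[, c("subject_id", "condition", "amplitude_uv")],
                         idvar = "subject_id", timevar = "condition",
                         direction = "wide")
  m <- as.matrix(wide[, -1])
  colnames(m) <- sub("amplitude_uv\\.", "", colnames(m))
  m
}
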