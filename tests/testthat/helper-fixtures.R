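# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

# default-scale phantom + noisy bSSFP PC180 acquisition, cached
fix_bssfp <- function(seed = 1L, snr = 20) {
  key <- paste0("bssfp_", seed, "_", snr)
  if (is.null(.fix[[key]])) {
    ph <- make_phantom(c(64L, 48L), seed = seed)
    par <- paradigm()
    acq <- acquisition_config("bssfp", phase_cycling = 180)
    clean <- simulate_timeseries(ph, par, acq)
    kfull <- to_kspace(clean, noise_sd = noise_sd_for_snr(clean, snr),
                       seed = 100L + seed)
    .fix[[key]] <- list(phantom = ph, paradigm = par, acq = acq,
                        clean = clean, kfull = kfull,
                        truth = from_kspace(kfull))
  }
  .fix[[key]]
}

# random complex array
rcarr <- function(dims, seed = 1L) {
  n <- prod(dims)
  ktfmri:::with_seed(seed, array(complex(real = stats::rnorm(n),
                                         imaginary = stats::rnorm(n)), dims))
}

# 1D sparse-spectrum toy: time series of length T with a 2-sparse temporal
# spectrum, observed at `ns` random time points (as a 1 x 1 x T k-t problem)
toy_sparse_instance <- function(Tn = 16L, ns = 8L, k = 2L) {
  Phi <- ktfmri:::dft_matrix(Tn)
  supp <- sample(Tn, k)
  coef <- complex(modulus = stats::runif(k, 0.5, 2),
                  argument = stats::runif(k, 0, 2 * pi))
  x <- rep(0 + 0i, Tn); x[supp] <- coef
  v <- as.vector(Conj(t(Phi)) %*% x)
  samp <- sort(sample(Tn, ns))
  lines <- matrix(FALSE, 1L, Tn); lines[1L, samp] <- TRUE
  y <- array(0 + 0i, c(1L, 1L, Tn)); y[1L, 1L, samp] <- v[samp]
  list(x = x, v = v, samp = samp,
       kspace = kspace_series(y, mask = ktfmri:::new_sampling_mask(lines, "R", 2L)))
}

# Exhaustive minimum-l1 oracle for the toy: the l1 optimum of an 8 x 16
# underdetermined system lies at a basic solution, and every invertible
# 8-support system containing a sparser exact solution reproduces it, so
# the minimum over all C(16,8) square subsystem solutions is the l1 vertex.
l1_oracle <- function(v, samp, Tn = 16L) {
  Phi <- ktfmri:::dft_matrix(Tn)
  A <- Conj(t(Phi))[samp, ]
  supports <- utils::combn(Tn, length(samp))
  best <- NULL; bsol <- NULL; bl1 <- Inf
  for (j in seq_len(ncol(supports))) {
    J <- supports[, j]
    sol <- tryCatch(solve(A[, J], v[samp]), error = function(e) NULL)
    if (is.null(sol)) next
    l1 <- sum(Mod(sol))
    if (l1 < bl1 - 1e-12) { bl1 <- l1; best <- J; bsol <- sol }
  }
  xo <- rep(0 + 0i, Tn); xo[best] <- bsol
  xo
}

# dense matrix of the forward operator restricted to one readout position
dense_forward_matrix <- function(mask, transform) {
  n <- mask$n_pe * mask$n_frames
  cols <- lapply(seq_len(n), function(j) {
    e <- array(0 + 0i, c(1L, mask$n_pe, mask$n_frames)); e[j] <- 1
    as.vector(forward_model(e, mask, transform))
  })
  do.call(cbind, cols)
}
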