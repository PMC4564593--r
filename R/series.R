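# Containers for 2D+time image data and k-space measurements.

#' Complex spatiotemporal image series
#'
#' @param frames complex array `(n_ro, n_pe, T)`.
#' @param paradigm optional [paradigm()]; when supplied its total frame count
#'   must equal `T`.
#' @param provenance one of `"ground_truth"`, `"reconstruction"`,
#'   `"zero_filled"`.
#' @param acq optional [acquisition_config()] carried as metadata.
#' @return object of class `image_series`.
#' @export
image_series <- function(frames,
                         paradigm = NULL,
                         provenance = c("ground_truth", "reconstruction", "zero_filled"),
                         acq = NULL) {
  provenance <- match.arg(provenance)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 3D array (n_ro x n_pe x T)")
  if (!is.complex(frames)) frames <- frames + 0i
  if (!is.null(paradigm) && paradigm$total != dim(frames)[3L])
    stop("paradigm total (", paradigm$total, ") does not match frame count (",
         dim(frames)[3L], ")")
  structure(list(frames = frames, paradigm = paradigm,
                 provenance = provenance, acq = acq),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_series %d x %d x %d frames, %s>\n", d[1L], d[2L], d[3L],
              x$provenance))
  invisible(x)
}

#' @export
dim.image_series <- function(x) dim(x$frames)

#' Simulate a noiseless block-design fMRI time series from a phantom
#'
#' Frames `1..n_pre` and the post-stimulus block carry the steady-state
#' baseline signal; during stimulation the signal inside the activation mask
#' is scaled by `1 + activation_amplitude` (a multiplicative BOLD-like
#' amplitude change). With `ramp = TRUE` the first stimulation frame and the
#' first post frame carry half the amplitude (1-frame linear onset/offset).
#'
#' @param phantom a [make_phantom()] phantom.
#' @param paradigm a [paradigm()].
#' @param acq an [acquisition_config()].
#' @param ramp logical; 1-frame linear onset/offset (default FALSE:
#'   rectangular response).
#' @return a noiseless `ground_truth` [image_series()].
#' @export
simulate_timeseries <- function(phantom, paradigm, acq, ramp = FALSE) {
  stopifnot(inherits(paradigm, "paradigm"))
  base <- steady_state_signal(phantom, acq)
  nt <- paradigm$total
  w <- numeric(nt)
  stim <- paradigm$n_pre + seq_len(paradigm$n_stim)
  w[stim] <- 1
  if (ramp) {
    w[stim[1L]] <- 0.5
    if (max(stim) < nt) w[max(stim) + 1L] <- 0.5
  }
  amp <- phantom$activation_amplitude
  frames <- vapply(seq_len(nt),
                   function(t) base * (1 + w[t] * amp),
                   matrix(0 + 0i, nrow(base), ncol(base)))
  image_series(frames, paradigm = paradigm, provenance = "ground_truth", acq = acq)
}

#' Complex k-space measurements with an optional sampling mask
#'
#' @param data complex array `(n_ro, n_pe, T)` in the centred k-space layout
#'   (DC at `(n_ro/2, n_pe/2)`, see [ky_index()]).
#' @param mask `NULL` for fully sampled data, or a [sampling_mask()]; with a
#'   mask attached all unsampled entries must be exactly zero.
#' @param paradigm optional [paradigm()] metadata.
#' @return object of class `kspace_series` with a `center_index` field.
#' @export
kspace_series <- function(data, mask = NULL, paradigm = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (n_ro x n_pe x T)")
  if (!is.complex(data)) data <- data + 0i
  d <- dim(data)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "sampling_mask"))
    if (mask$n_pe != d[2L] || mask$n_frames != d[3L])
      stop("mask dimensions (", mask$n_pe, " x ", mask$n_frames,
           ") do not match data (", d[2L], " x ", d[3L], ")")
  }
  structure(list(data = data, mask = mask,
                 center_index = c(d[1L] %/% 2L, d[2L] %/% 2L),
                 paradigm = paradigm),
            class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_series %d x %d x %d, %s>\n", d[1L], d[2L], d[3L],
              if (is.null(x$mask)) "fully sampled" else
                paste0("mask ", x$mask$pattern, " (D = ", x$mask$D, ")")))
  invisible(x)
}

#' Transform an image series to k-space, optionally adding measurement noise
#'
#' Per-frame unitary 2D DFT with DC at the declared centre index, plus
#' independent complex Gaussian noise of standard deviation `noise_sd` per
#' real/imaginary channel added in k-space.
#'
#' @param series an [image_series()].
#' @param noise_sd nonnegative noise standard deviation (a.u.).
#' @param seed RNG seed for the noise stream.
#' @return a fully sampled [kspace_series()].
#' @export
to_kspace <- function(series, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(series, "image_series"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  k <- fft2_frames(series$frames)
  if (noise_sd > 0) {
    n <- length(k)
    k <- k + with_seed(seed, complex(real = stats::rnorm(n, sd = noise_sd),
                                     imaginary = stats::rnorm(n, sd = noise_sd)))
  }
  kspace_series(k, mask = NULL, paradigm = series$paradigm)
}

#' Inverse-transform k-space measurements to images
#'
#' Zero-filled (adjoint) reconstruction: unitary inverse 2D DFT of every
#' frame, with unsampled entries left at zero. Used both as the ground-truth
#' reconstruction of fully sampled data and as the non-CS control for the
#' centre-block mask.
#'
#' @param kspace a [kspace_series()].
#' @return an [image_series()] with provenance `"zero_filled"` (or
#'   `"ground_truth"` if the data are fully sampled).
#' @export
from_kspace <- function(kspace) {
  stopifnot(inherits(kspace, "kspace_series"))
  img <- fft2_frames(kspace$data, inverse = TRUE)
  image_series(img, paradigm = kspace$paradigm,
               provenance = if (is.null(kspace$mask)) "ground_truth" else "zero_filled")
}

#' Noise level that yields a requested baseline-image SNR
#'
#' The k-space DFT is unitary, so complex noise of per-channel standard
#' deviation `sd` in k-space appears with the same per-channel `sd` in the
#' image; the baseline-image SNR is taken as mean magnitude over the object
#' support divided by `sd`.
#'
#' @param series a noiseless [image_series()].
#' @param snr target SNR (e.g. 20).
#' @return the `noise_sd` to pass to [to_kspace()].
#' @export
noise_sd_for_snr <- function(series, snr) {
  stopifnot(inherits(series, "image_series"), snr > 0)
  m <- Mod(series$frames[, , 1L])
  mean(m[m > 0.01 * max(m)]) / snr
}

#' Export the magnitude of an image series as NIfTI-1
#'
#' @param series an [image_series()].
#' @param path output file path (`.nii` / `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_series_nifti <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  RNifti::writeNifti(Mod(series$frames), path)
  invisible(path)
}
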