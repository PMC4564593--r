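# Acquisition description and steady-state signal models.

#' Block-design stimulation paradigm
#'
#' @param n_pre,n_stim,n_post frame counts of the pre-stimulus baseline,
#'   stimulation and post-stimulus blocks; each at least 1. The default is
#'   the 48-frame bSSFP paradigm (16/8/24); spoiled-GRE studies use the
#'   halved paradigm `paradigm(8, 4, 12)`.
#' @return object of class `paradigm` with a `total` frame count.
#' @export
paradigm <- function(n_pre = 16L, n_stim = 8L, n_post = 24L) {
  n <- as.integer(c(n_pre, n_stim, n_post))
  if (any(is.na(n)) || any(n < 1L)) stop("all paradigm block counts must be >= 1")
  structure(list(n_pre = n[1L], n_stim = n[2L], n_post = n[3L], total = sum(n)),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("<paradigm pre/stim/post = %d/%d/%d (T = %d)>\n",
              x$n_pre, x$n_stim, x$n_post, x$total))
  invisible(x)
}

#' Acquisition configuration for the synthetic scanner
#'
#' Defaults follow the high-field protocol the package emulates: bSSFP with
#' TR/TE = 10/5 ms, flip 16 degrees, phase-cycling in \{0, 90, 180, 270\};
#' spoiled GRE with TR/TE = 20/10 ms and flip 8 degrees.
#'
#' @param sequence `"bssfp"` or `"gre"`.
#' @param TR,TE repetition and echo time in ms; `TE <= TR` required.
#' @param flip_angle flip angle in degrees.
#' @param phase_cycling per-TR RF phase increment in degrees (bSSFP only).
#' @param matrix_size integer pair `(n_ro, n_pe)`.
#' @param noise_sd additive complex-Gaussian k-space noise, standard
#'   deviation per real/imaginary channel (a.u.).
#' @param seed integer RNG seed for the noise stream.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(sequence = c("bssfp", "gre"),
                               TR = NULL, TE = NULL, flip_angle = NULL,
                               phase_cycling = 180,
                               matrix_size = c(64L, 48L),
                               noise_sd = 0, seed = 1L) {
  sequence <- match.arg(sequence)
  if (sequence == "bssfp") {
    TR <- TR %||% 10; TE <- TE %||% (TR / 2); flip_angle <- flip_angle %||% 16
  } else {
    TR <- TR %||% 20; TE <- TE %||% (TR / 2); flip_angle <- flip_angle %||% 8
    phase_cycling <- NA_real_
  }
  if (TE > TR) stop("TE must not exceed TR")
  matrix_size <- as.integer(matrix_size)
  if (any(matrix_size <= 0L)) stop("matrix dimensions must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(sequence = sequence, TR = TR, TE = TE,
                 flip_angle = flip_angle, phase_cycling = phase_cycling,
                 matrix_size = matrix_size, noise_sd = noise_sd, seed = seed),
            class = "acquisition_config")
}

#' Steady-state complex signal of the phantom under a pulse sequence
#'
#' For spoiled GRE the Ernst steady state
#' \deqn{S = \rho \sin\alpha (1 - E_1)/(1 - E_1\cos\alpha)\, e^{-TE/T_2}}
#' with an off-resonance phase accrued over TE.  For balanced SSFP the
#' steady-state profile as a function of the per-TR precession phase
#' \eqn{\beta = 2\pi \Delta f\, TR + \theta_{pc}}:
#' \deqn{S = \rho \sin\alpha (1-E_1)\frac{1 - E_2 e^{-i\beta}}
#'   {(1-E_1\cos\alpha)(1-E_2\cos\beta) - E_2(E_1-\cos\alpha)(E_2-\cos\beta)}}
#' refocused to the echo time, which traces the familiar pass-band /
#' stop-band (banding) profile: an on-resonance pixel is in the stop band at
#' 0 degrees phase-cycling and in the pass band at 180 degrees.
#'
#' @param phantom a [make_phantom()] object.
#' @param acq an [acquisition_config()].
#' @return complex matrix of per-pixel steady-state signal; exactly 0 where
#'   proton density is 0.
#' @export
steady_state_signal <- function(phantom, acq) {
  stopifnot(inherits(phantom, "phantom"), inherits(acq, "acquisition_config"))
  pd <- phantom$proton_density
  sup <- pd > 0
  if (any(phantom$T1[sup] <= 0) || any(phantom$T2[sup] <= 0))
    stop("T1 and T2 must be positive wherever proton density is positive")
  s <- matrix(0 + 0i, nrow(pd), ncol(pd))
  if (!any(sup)) return(s)
  a <- acq$flip_angle * pi / 180
  e1 <- exp(-acq$TR / phantom$T1[sup])
  e2 <- exp(-acq$TR / phantom$T2[sup])
  df <- phantom$off_resonance[sup]
  if (acq$sequence == "gre") {
    mag <- pd[sup] * sin(a) * (1 - e1) / (1 - e1 * cos(a)) *
      exp(-acq$TE / phantom$T2[sup])
    s[sup] <- mag * exp(2i * pi * df * acq$TE * 1e-3)
  } else {
    beta <- 2 * pi * df * acq$TR * 1e-3 + acq$phase_cycling * pi / 180
    den <- (1 - e1 * cos(a)) * (1 - e2 * cos(beta)) -
      e2 * (e1 - cos(a)) * (e2 - cos(beta))
    m <- pd[sup] * sin(a) * (1 - e1) * (1 - e2 * exp(-1i * beta)) / den
    s[sup] <- m * exp(1i * beta * acq$TE / acq$TR) * exp(-acq$TE / phantom$T2[sup])
  }
  s
}
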