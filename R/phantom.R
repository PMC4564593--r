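# Synthetic digital phantom for phase-cycled bSSFP / spoiled GRE fMRI.
#
# The phantom is an elliptical "brain" with a cortical rim and two (or more)
# activation foci placed in the rim.  The off-resonance field is a smooth
# in-plane gradient arranged so the foci sit at off-resonance values that
# differ by >= 1/(2 TR) Hz (60 Hz at TR = 10 ms): under balanced SSFP one
# focus lies in the pass-band and the other in the stop-band of any given
# phase-cycling angle, so different angles emphasise different foci --- the
# synthetic analogue of the spatial shift of activation foci seen in
# phase-cycled high-field data.

#' Build a synthetic brain-like phantom with heterogeneous activation foci
#'
#' @param shape integer pair `(n_ro, n_pe)`, at least `c(32, 32)`.
#' @param seed integer; the phantom is a deterministic function of
#'   `(shape, seed)`.
#' @param focus_spec optional list overriding the default foci, with elements
#'   `centers` (k x 2 matrix of pixel coordinates), `radius` (pixels),
#'   `amplitude` (peak fractional signal change) and `off_resonance`
#'   (length-k Hz values imposed at the focus centres).
#' @return an object of class `phantom`: a list of per-pixel maps
#'   `proton_density` (a.u., peak 1000 --- the scale of raw scanner data),
#'   `T1`/`T2` (ms), `off_resonance` (Hz),
#'   `activation_mask` (logical) and `activation_amplitude` (fractional,
#'   zero outside the mask), plus `focus_centers`.
#' @examples
#' ph <- make_phantom(c(64, 48), seed = 1)
#' range(ph$off_resonance[ph$proton_density > 0])
#' @export
make_phantom <- function(shape = c(64L, 48L), seed = 1L, focus_spec = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L))
    stop("phantom shape must be at least 32 x 32 pixels", call. = FALSE)
  nr <- shape[1L]; nc <- shape[2L]
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  xg <- matrix(seq_len(nr), nr, nc)
  yg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # elliptical support with a soft edge
  ex <- (xg - cx) / (0.44 * nr)
  ey <- (yg - cy) / (0.42 * nc)
  e2 <- ex^2 + ey^2
  # proton density in arbitrary units at the scale of raw scanner data
  # (peak 1000), so the default regularization factors of the
  # reconstruction sit in their intended small-relative-to-signal regime
  pd <- 1000 * matrix(pmin(1, pmax(0, (1 - e2) / 0.08)), nr, nc)
  inside <- pd > 0

  # tissue bands: cortical rim vs deeper tissue (values typical of rodent
  # brain at high field, milliseconds)
  rim <- inside & e2 >= 0.52
  t1 <- matrix(0, nr, nc); t2 <- matrix(0, nr, nc)
  t1[inside] <- 1900; t2[inside] <- 38
  t1[rim] <- 1750;    t2[rim] <- 48

  def <- with_seed(seed, {
    jit <- function(s) stats::runif(1, -s, s)
    ang <- c(2.30 + jit(0.08), 0.85 + jit(0.08))   # radians, upper-left / upper-right rim
    rad <- sqrt(0.72)
    centers <- cbind(cx + rad * 0.44 * nr * cos(ang) * 0.92,
                     cy + rad * 0.42 * nc * sin(ang) * 0.92)
    list(centers = centers,
         radius = max(2.5, 0.055 * min(shape)) * (1 + jit(0.05)),
         amplitude = 0.06 * (1 + jit(0.1)),
         off_resonance = c(0, 60),
         ripple_phase = stats::runif(2, 0, 2 * pi))
  })
  if (!is.null(focus_spec)) def[names(focus_spec)] <- focus_spec
  centers <- def$centers

  # smooth off-resonance field: in-plane linear shim residual pinned to the
  # requested values at the two focus centres, plus a low-amplitude ripple
  a <- def$off_resonance[1L]; b <- def$off_resonance[2L]
  dxy <- centers[2L, ] - centers[1L, ]
  g <- (b - a) / sum(dxy^2) * dxy
  off <- a + g[1L] * (xg - centers[1L, 1L]) + g[2L] * (yg - centers[1L, 2L])
  off <- off + 1.5 * sin(2 * pi * xg / nr + def$ripple_phase[1L]) *
               cos(2 * pi * yg / nc + def$ripple_phase[2L])
  # pin the focus centres exactly so the contrast between foci is controlled
  for (k in seq_len(nrow(centers))) {
    d2 <- (xg - centers[k, 1L])^2 + (yg - centers[k, 2L])^2
    w <- exp(-d2 / (2 * (1.2 * def$radius)^2))
    off <- off * (1 - w) + def$off_resonance[min(k, length(def$off_resonance))] * w
  }
  off[!inside] <- 0

  amp <- matrix(0, nr, nc)
  act <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(centers))) {
    d2 <- (xg - centers[k, 1L])^2 + (yg - centers[k, 2L])^2
    hit <- d2 <= def$radius^2 & inside
    act <- act | hit
    prof <- def$amplitude * exp(-d2 / (2 * (def$radius / 1.4)^2))
    amp[hit] <- pmax(amp[hit], prof[hit])
  }
  amp[!act] <- 0
  amp <- matrix(pmin(amp, 0.5), nr, nc)

  structure(list(proton_density = pd, T1 = t1, T2 = t2,
                 off_resonance = off, activation_mask = act,
                 activation_amplitude = amp,
                 focus_centers = centers, shape = shape, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %d x %d, %d activation focus pixel(s) in %d component(s)>\n",
              x$shape[1L], x$shape[2L], sum(x$activation_mask),
              max(label_components(x$activation_mask))))
  invisible(x)
}
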