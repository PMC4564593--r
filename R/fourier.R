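# Discrete Fourier conventions shared by the generator, the mask design and
# the reconstruction engine.
#
# For an even-length axis of n points the k-space index grid is
#   k = -(n/2 - 1), ..., -1, 0, 1, ..., n/2
# stored in array rows 1..n, so DC (k = 0) sits at row n/2.  For n = 192 this
# reproduces the phase-encode index range -95..96.  All DFTs are unitary
# (1/sqrt(n) both ways) so Parseval holds exactly between domains.

#' k-space index grid for an even-length axis
#'
#' @param n number of samples along the axis (even).
#' @return integer vector `-(n/2-1) .. n/2`; `ky_index(n) == 0` marks the DC
#'   row `n/2`.
#' @export
ky_index <- function(n) {
  stopifnot_even(n, "axis length")
  seq.int(-(n %/% 2L - 1L), n %/% 2L)
}

# Permutation taking R's native fft frequency order (0, 1, ..., n-1) to the
# centred layout above: row r holds frequency (r - n/2) mod n.
.kshift_perm <- function(n) ((seq_len(n) - n %/% 2L) %% n) + 1L

# Unitary DFT along one dimension of a complex array, output (forward) or
# input (inverse) in the centred k-space layout.
fft_centered <- function(x, dim, inverse = FALSE) {
  d <- dim(x) %||% length(x)
  if (is.null(dim(x))) dim(x) <- d
  n <- d[dim]
  perm <- c(dim, setdiff(seq_along(d), dim))
  xp <- aperm(x, perm)
  dim(xp) <- c(n, prod(d) / n)
  map <- .kshift_perm(n)
  if (!inverse) {
    out <- stats::mvfft(xp)[map, , drop = FALSE] / sqrt(n)
  } else {
    ip <- integer(n); ip[map] <- seq_len(n)
    out <- stats::mvfft(xp[ip, , drop = FALSE], inverse = TRUE) / sqrt(n)
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# Unitary 2D spatial DFT of every frame of an (n_ro x n_pe x T) stack.
fft2_frames <- function(x, inverse = FALSE) {
  fft_centered(fft_centered(x, 1L, inverse), 2L, inverse)
}

# Unitary temporal DFT matrix (T x T); rows index temporal frequency.
dft_matrix <- function(n) {
  j <- 0:(n - 1L)
  exp(-2i * pi * outer(j, j) / n) / sqrt(n)
}

# Right-multiply the time axis (last dim) of an array by a T x T matrix.
apply_time_matrix <- function(x, m) {
  d <- dim(x)
  nt <- d[length(d)]
  dim(x) <- c(prod(d) / nt, nt)
  out <- x %*% m
  dim(out) <- d
  out
}
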