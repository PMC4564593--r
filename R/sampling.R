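# Cartesian k-t undersampling mask generators.
#
# A mask selects phase-encode (PE) lines per time frame; every generator
# samples exactly N_PE / D distinct lines per frame.  Weighted
# without-replacement draws use randomized systematic probability-
# proportional-to-size selection, whose per-line inclusion probability is
# exactly n * p_i (requires n * max(p) <= 1, satisfied by every shipped
# pattern at D = 4); uniform draws are plain simple random samples.  This
# keeps the empirical per-line sampling frequency an unbiased estimate of
# the target density, which the Gaussian-pattern design relies on.

mask_patterns <- c("R", "G", "GR", "GRC1", "CENTER_ONLY", "GRC1_PAIRED", "FULL")

new_sampling_mask <- function(lines, pattern, D, sigma = NA_real_, seed = NA_integer_) {
  stopifnot(is.matrix(lines))
  structure(list(pattern = match.arg(pattern, mask_patterns),
                 lines = lines, D = D, sigma = sigma, seed = seed,
                 n_pe = nrow(lines), n_frames = ncol(lines)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask %s: %d PE lines x %d frames, D = %s, %d lines/frame>\n",
              x$pattern, x$n_pe, x$n_frames, format(x$D), sum(x$lines[, 1L])))
  invisible(x)
}

check_divisor <- function(n_pe, D) {
  if (n_pe %% D != 0L)
    stop("downsampling factor D = ", D, " must divide N_PE = ", n_pe, call. = FALSE)
  n_pe %/% D
}

# Randomized systematic PPS draw of n indices with inclusion probability
# exactly n * prob (prob summing to 1; requires n * max(prob) <= 1).
draw_weighted <- function(prob, n) {
  prob <- prob / sum(prob)
  incl <- n * prob
  if (max(incl) > 1 + 1e-9) {
    # density too concentrated for exact-marginal systematic selection
    # (n * max(p) > 1): fall back to sequential renormalized draws
    return(sort(sample.int(length(prob), n, prob = prob)))
  }
  ord <- sample.int(length(prob))
  cp <- cumsum(incl[ord])
  pts <- stats::runif(1) + seq_len(n) - 1
  sort(ord[pmin(findInterval(pts, cp) + 1L, length(prob))])
}

# Discrete Gaussian PE-line density P(ky) = A exp(-ky^2 / 2 sigma^2),
# renormalized on the centred index grid.
gaussian_line_density <- function(n_pe, sigma) {
  if (is.null(sigma)) sigma <- n_pe / 9
  if (sigma <= 0) stop("sigma must be positive")
  ky <- ky_index(n_pe)
  p <- exp(-ky^2 / (2 * sigma^2))
  list(p = p / sum(p), sigma = sigma)
}

#' Uniform random k-t sampling mask (Pattern R)
#'
#' Each frame holds `N_PE / D` distinct phase-encode lines drawn uniformly
#' without replacement, frames independent.
#'
#' @param n_pe number of phase-encode lines (even).
#' @param n_frames number of time frames.
#' @param D integer downsampling factor; must divide `n_pe`.
#' @param seed RNG seed; the mask is deterministic given `(args, seed)`.
#' @return a `sampling_mask` (logical `n_pe x n_frames` line matrix).
#' @export
gen_uniform <- function(n_pe, n_frames, D = 4L, seed = 1L) {
  n <- check_divisor(n_pe, D)
  lines <- with_seed(seed, {
    m <- matrix(FALSE, n_pe, n_frames)
    for (t in seq_len(n_frames)) m[sample.int(n_pe, n), t] <- TRUE
    m
  })
  new_sampling_mask(lines, "R", D, seed = seed)
}

#' Gaussian random k-t sampling mask (Pattern G)
#'
#' Lines drawn without replacement with probabilities proportional to the
#' centre-weighted density `P(ky) = A exp(-ky^2 / 2 sigma^2)` on the index
#' grid `-(N_PE/2 - 1) .. N_PE/2`, default `sigma = N_PE / 9`.
#'
#' @inheritParams gen_uniform
#' @param sigma density standard deviation in PE-line units
#'   (default `n_pe / 9`).
#' @export
gen_gaussian <- function(n_pe, n_frames, D = 4L, seed = 1L, sigma = NULL) {
  n <- check_divisor(n_pe, D)
  g <- gaussian_line_density(n_pe, sigma)
  lines <- with_seed(seed, {
    m <- matrix(FALSE, n_pe, n_frames)
    for (t in seq_len(n_frames)) m[draw_weighted(g$p, n), t] <- TRUE
    m
  })
  new_sampling_mask(lines, "G", D, sigma = g$sigma, seed = seed)
}

# 2:1 Gaussian-to-uniform split of n lines, Gaussian rounded up.
mixture_split <- function(n) {
  ng <- ceiling(2 * n / 3)
  c(gaussian = ng, uniform = n - ng)
}

# One frame of the Gaussian + uniform mixture over candidate rows `rows`,
# with Gaussian weights `p` (aligned with rows).
draw_mixture_frame <- function(rows, p, ng, nu) {
  g <- rows[draw_weighted(p, ng)]
  rest <- setdiff(rows, g)
  u <- if (nu > 0L) rest[sample.int(length(rest), nu)] else integer(0)
  c(g, u)
}

#' Mixture of Gaussian and uniform random sampling (Pattern GR)
#'
#' Per frame, `N_PE/6` lines are drawn from the Gaussian density and a
#' further `N_PE/12` uniformly from the remaining lines (at the canonical
#' D = 4; the 2:1 Gaussian-to-uniform split is kept for other D, Gaussian
#' count rounded up).
#'
#' @inheritParams gen_gaussian
#' @export
gen_mixture <- function(n_pe, n_frames, D = 4L, seed = 1L, sigma = NULL) {
  if (n_pe %% 12L != 0L)
    stop("the mixture pattern requires N_PE divisible by 12, got ", n_pe)
  n <- check_divisor(n_pe, D)
  sp <- mixture_split(n)
  g <- gaussian_line_density(n_pe, sigma)
  lines <- with_seed(seed, {
    m <- matrix(FALSE, n_pe, n_frames)
    for (t in seq_len(n_frames))
      m[draw_mixture_frame(seq_len(n_pe), g$p, sp[1L], sp[2L]), t] <- TRUE
    m
  })
  new_sampling_mask(lines, "GR", D, sigma = g$sigma, seed = seed)
}

#' Mixture sampling with guaranteed centre line (Pattern GRC1)
#'
#' The DC line `ky = 0` is sampled in every frame; the remaining
#' `N_PE/D - 1` lines follow the mixture rule with the 2:1 split applied to
#' the reduced count (Gaussian rounded up).
#'
#' @inheritParams gen_mixture
#' @export
gen_mixture_center1 <- function(n_pe, n_frames, D = 4L, seed = 1L, sigma = NULL) {
  if (n_pe %% 12L != 0L)
    stop("the mixture pattern requires N_PE divisible by 12, got ", n_pe)
  n <- check_divisor(n_pe, D)
  dc <- n_pe %/% 2L                       # row of ky = 0
  sp <- mixture_split(n - 1L)
  g <- gaussian_line_density(n_pe, sigma)
  rows <- setdiff(seq_len(n_pe), dc)
  p <- g$p[rows]
  lines <- with_seed(seed, {
    m <- matrix(FALSE, n_pe, n_frames)
    for (t in seq_len(n_frames))
      m[c(dc, draw_mixture_frame(rows, p, sp[1L], sp[2L])), t] <- TRUE
    m
  })
  new_sampling_mask(lines, "GRC1", D, sigma = g$sigma, seed = seed)
}

#' Contiguous centre-block mask (non-CS control)
#'
#' Deterministic: the central `N_PE/D` lines (ky in
#' `-(N_PE/2D - 1) .. N_PE/2D`, centred on DC) in every frame --- the
#' quarter-downsampled low-frequency-only control.
#'
#' @inheritParams gen_uniform
#' @export
gen_center_only <- function(n_pe, n_frames, D = 4L) {
  n <- check_divisor(n_pe, D)
  stopifnot_even(n, "centre block size N_PE/D")
  rows <- (n_pe %/% 2L - n %/% 2L + 1L):(n_pe %/% 2L + n %/% 2L)
  lines <- matrix(FALSE, n_pe, n_frames)
  lines[rows, ] <- TRUE
  new_sampling_mask(lines, "CENTER_ONLY", D)
}

#' Pairwise GRC1-style mask for eddy-current suppression
#'
#' Lines are sampled in adjacent-index pairs (0-based row couples
#' `(2m, 2m+1)`), suppressing eddy-current artifacts from large
#' phase-encode jumps in balanced SSFP. The pair containing `ky = 0` is
#' sampled in every frame; the remaining pairs are drawn without
#' replacement with probability proportional to the GRC1 mixture density
#' (2/3 Gaussian + 1/3 uniform) summed within each pair.
#'
#' @inheritParams gen_mixture
#' @export
gen_pairwise <- function(n_pe, n_frames, D = 4L, seed = 1L, sigma = NULL) {
  if (n_pe %% 12L != 0L)
    stop("the mixture pattern requires N_PE divisible by 12, got ", n_pe)
  n <- check_divisor(n_pe, D)
  stopifnot_even(n, "per-frame line count N_PE/D")
  g <- gaussian_line_density(n_pe, sigma)
  pmix <- (2 / 3) * g$p + (1 / 3) / n_pe
  pair_id <- (seq_len(n_pe) - 1L) %/% 2L + 1L       # n_pe/2 pairs of rows
  pair_p <- as.numeric(tapply(pmix, pair_id, sum))
  dc_pair <- pair_id[n_pe %/% 2L]
  npair <- n %/% 2L
  other <- setdiff(seq_len(n_pe %/% 2L), dc_pair)
  lines <- with_seed(seed, {
    m <- matrix(FALSE, n_pe, n_frames)
    for (t in seq_len(n_frames)) {
      sel <- c(dc_pair, other[draw_weighted(pair_p[other], npair - 1L)])
      m[pair_id %in% sel, t] <- TRUE
    }
    m
  })
  new_sampling_mask(lines, "GRC1_PAIRED", D, sigma = g$sigma, seed = seed)
}

#' Fully sampled mask
#'
#' @inheritParams gen_uniform
#' @export
full_mask <- function(n_pe, n_frames) {
  new_sampling_mask(matrix(TRUE, n_pe, n_frames), "FULL", 1L)
}

#' Retrospectively downsample fully sampled k-space data
#'
#' Entries on sampled phase-encode lines are copied exactly; all other
#' entries are set to zero and the mask is attached to the result.
#'
#' @param full a fully sampled [kspace_series()] (no mask, or a full mask).
#' @param mask a [sampling_mask()] with matching dimensions.
#' @return a masked [kspace_series()].
#' @export
apply_mask <- function(full, mask) {
  stopifnot(inherits(full, "kspace_series"), inherits(mask, "sampling_mask"))
  if (!is.null(full$mask) && !all(full$mask$lines))
    stop("input k-space is already undersampled")
  d <- dim(full$data)
  if (mask$n_pe != d[2L] || mask$n_frames != d[3L])
    stop("mask dimensions (", mask$n_pe, " x ", mask$n_frames,
         ") do not match k-space data (", d[2L], " x ", d[3L], ")")
  out <- full$data
  for (t in seq_len(d[3L])) out[, !mask$lines[, t], t] <- 0 + 0i
  kspace_series(out, mask = mask, paradigm = full$paradigm)
}

#' Write a sampling mask as plain text with a JSON sidecar
#'
#' @param mask a [sampling_mask()].
#' @param path output path for the 0/1 line matrix (TSV); metadata is
#'   written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  utils::write.table(mask$lines * 1L, path, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  jsonlite::write_json(list(pattern = mask$pattern, D = mask$D,
                            sigma = mask$sigma, seed = mask$seed,
                            n_pe = mask$n_pe, n_frames = mask$n_frames),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
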