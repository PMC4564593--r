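# k-t FOCUSS reconstruction of undersampled k-t data.
#
# Signal model: the readout axis is fully sampled, so a single inverse DFT
# along readout decouples it; each reconstruction then relates the
# transform-domain coefficient stack x(readout, y, f) to the sampled hybrid
# measurements through
#     A x = M . F_pe . Phi^H x
# where Phi is a unitary temporal transform (Fourier or Karhunen-Loeve),
# F_pe the unitary spatial DFT along phase encoding and M the k-t sampling
# mask. FOCUSS reweighting promotes sparsity of x along the temporal-
# transform axis.

#' k-t FOCUSS reconstruction parameters
#'
#' Defaults follow established practice for this reconstruction: weighting
#' power `p = 0.5` (targets the l1 solution), `n_cg = 30` conjugate-gradient
#' iterations per reweighting, regularization `lambda = 0.1` for the
#' temporal-Fourier transform and `0.01` for the KLT, a 2-iteration
#' preliminary Fourier pass to seed the KLT covariance, one KLT update, and
#' the relative-change stopping tolerance 0.1 for automatic selection of the
#' reweighting count.
#'
#' @param transform `"temporal_ft"` or `"klt"`.
#' @param p FOCUSS weighting power in (0, 1].
#' @param lambda nonnegative Tikhonov regularization of the inner solve.
#' @param n_cg inner CG iteration count (>= 1).
#' @param n_foc outer reweighting count, or `"auto"` to stop at the first
#'   iteration whose relative Frobenius change falls below `stop_tol`
#'   (hard cap `max_auto`).
#' @param n_klt number of KLT basis updates (KLT only).
#' @param prelim_n_foc outer count of the preliminary Fourier pass that
#'   seeds the KLT covariance.
#' @param stop_tol relative Frobenius stopping tolerance.
#' @param max_auto hard cap on `"auto"` outer iterations.
#' @param seed carried seed for provenance.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(transform = c("temporal_ft", "klt"),
                         p = 0.5, lambda = NULL, n_cg = 30L, n_foc = "auto",
                         n_klt = 1L, prelim_n_foc = 2L, stop_tol = 0.1,
                         max_auto = 20L, seed = 1L) {
  transform <- match.arg(transform)
  lambda <- lambda %||% if (transform == "temporal_ft") 0.1 else 0.01
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (n_cg < 1L) stop("n_cg must be at least 1")
  if (stop_tol <= 0) stop("stop_tol must be positive")
  if (!identical(n_foc, "auto") && (!is.numeric(n_foc) || n_foc < 1L))
    stop("n_foc must be a positive integer or \"auto\"")
  structure(list(transform = transform, p = p, lambda = lambda,
                 n_cg = as.integer(n_cg), n_foc = n_foc,
                 n_klt = as.integer(n_klt), prelim_n_foc = as.integer(prelim_n_foc),
                 stop_tol = stop_tol, max_auto = as.integer(max_auto),
                 seed = seed),
            class = "recon_config")
}

#' @export
print.recon_config <- function(x, ...) {
  cat(sprintf("<recon_config %s: p = %g, lambda = %g, n_cg = %d, n_foc = %s>\n",
              x$transform, x$p, x$lambda, x$n_cg, format(x$n_foc)))
  invisible(x)
}

#' Unitary temporal transform
#'
#' @param Phi unitary `T x T` complex matrix whose rows are the analysis
#'   basis (coefficients `c = Phi v` for a time series `v`).
#' @param kind `"FT"` or `"KLT"`.
#' @param eigenvalues optional covariance spectrum (KLT provenance).
#' @return object of class `temporal_transform`.
#' @export
temporal_transform <- function(Phi, kind = c("FT", "KLT"), eigenvalues = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(Phi) || nrow(Phi) != ncol(Phi))
    stop("Phi must be a square matrix")
  if (!is.complex(Phi)) Phi <- Phi + 0i
  assert_unitary(Phi)
  structure(list(Phi = Phi, kind = kind, eigenvalues = eigenvalues),
            class = "temporal_transform")
}

assert_unitary <- function(Phi, tol = 1e-10) {
  n <- nrow(Phi)
  err <- max(Mod(Phi %*% Conj(t(Phi)) - diag(n)))
  if (err > tol)
    stop("temporal transform is not unitary (max deviation ", format(err), ")")
  invisible(TRUE)
}

#' Temporal Fourier transform of length T
#' @param n_frames number of time frames.
#' @return a `temporal_transform` of kind `"FT"`.
#' @export
ft_transform <- function(n_frames) {
  structure(list(Phi = dft_matrix(n_frames), kind = "FT", eigenvalues = NULL),
            class = "temporal_transform")
}

#' @export
print.temporal_transform <- function(x, ...) {
  cat(sprintf("<temporal_transform %s, T = %d>\n", x$kind, nrow(x$Phi)))
  invisible(x)
}

# Mask as a numeric (n_ro x n_pe x T) multiplier.
mask_array <- function(mask, n_ro) {
  m <- array(0, c(n_ro, mask$n_pe, mask$n_frames))
  m[] <- rep(as.numeric(mask$lines), each = n_ro)
  m
}

# Forward/adjoint closures for one mask + transform on hybrid-space data.
kt_operators <- function(mask, Phi, n_ro) {
  marr <- mask_array(mask, n_ro)
  phi_h <- Conj(Phi)        # right-multiplier applying Phi^H along time
  phi_f <- t(Phi)           # right-multiplier applying Phi along time
  list(
    A = function(x) marr * fft_centered(apply_time_matrix(x, phi_h), 2L),
    Ah = function(d) apply_time_matrix(fft_centered(marr * d, 2L, inverse = TRUE), phi_f)
  )
}

#' Forward k-t measurement model
#'
#' Maps a transform-domain coefficient stack to sampled hybrid-space
#' k-space: inverse temporal transform along time, unitary DFT along phase
#' encoding, then the sampling mask. The readout axis is assumed already
#' decoupled (inverse-transformed once); see [ktfocuss()].
#'
#' @param x complex array `(n_ro, n_pe, T)` of transform-domain coefficients.
#' @param mask a [sampling_mask()].
#' @param transform a [temporal_transform()] (checked for unitarity).
#' @return complex array of masked hybrid k-space measurements.
#' @export
forward_model <- function(x, mask, transform) {
  stopifnot(is.array(x), length(dim(x)) == 3L,
            inherits(mask, "sampling_mask"),
            inherits(transform, "temporal_transform"))
  assert_unitary(transform$Phi)
  if (dim(x)[2L] != mask$n_pe || dim(x)[3L] != mask$n_frames)
    stop("coefficient stack does not match mask dimensions")
  kt_operators(mask, transform$Phi, dim(x)[1L])$A(x + 0i)
}

#' Adjoint of the forward k-t measurement model
#'
#' @param d complex array `(n_ro, n_pe, T)` of (masked) hybrid measurements.
#' @inheritParams forward_model
#' @return transform-domain coefficient stack.
#' @export
adjoint_model <- function(d, mask, transform) {
  stopifnot(is.array(d), length(dim(d)) == 3L)
  assert_unitary(transform$Phi)
  kt_operators(mask, transform$Phi, dim(d)[1L])$Ah(d + 0i)
}

#' Regularized weighted least-squares inner solve
#'
#' Approximately solves `(W A^H A W + lambda I) q = W A^H y` by `n_cg`
#' conjugate-gradient iterations (early exit when the gradient norm drops
#' below 1e-12), where `A` is [forward_model()] for the given mask and
#' transform and `W` acts elementwise.
#'
#' @param mask a [sampling_mask()].
#' @param transform a [temporal_transform()].
#' @param W nonnegative weight array, same shape as the coefficients.
#' @param y masked hybrid-space measurements (array).
#' @param lambda nonnegative regularization.
#' @param n_cg iteration count.
#' @param q0 starting iterate (default zero).
#' @return list with `q` and the per-iteration data residual
#'   `residual_trace` (`||y - A W q||^2`, recorded before the first and
#'   after each iteration).
#' @export
cg_solve <- function(mask, transform, W, y, lambda = 0.1, n_cg = 30L,
                     q0 = NULL) {
  stopifnot(is.array(y), length(dim(y)) == 3L)
  assert_unitary(transform$Phi)
  ops <- kt_operators(mask, transform$Phi, dim(y)[1L])
  q0 <- q0 %||% array(0 + 0i, dim(y))
  cg_weighted(ops$A, ops$Ah, W, y + 0i, lambda, n_cg, q0)
}

#' k-t FOCUSS reconstruction
#'
#' Reconstructs a 2D+time image series from undersampled k-t measurements
#' by FOCUSS reweighting: starting from the zero-filled adjoint
#' reconstruction, each outer iteration sets `W = |x|^p`, solves the
#' weighted regularized least-squares problem by conjugate gradients
#' (restarted from zero, so the recorded data residual decreases
#' monotonically within every inner solve) and forms `x = W q`. With
#' `n_foc = "auto"` the loop stops at the first iteration whose relative
#' Frobenius change `||U(k) - U(k-1)||_F / ||U(k)||_F` falls below
#' `stop_tol` (see [stopping_criterion()]); if the criterion never fires
#' within `max_auto` iterations the result is returned with
#' `converged = FALSE` rather than an error.
#'
#' @param y a [kspace_series()] with an attached mask (use [full_mask()]
#'   for fully sampled data).
#' @param config a [recon_config()].
#' @param transform optional [temporal_transform()]; defaults to the
#'   temporal Fourier transform. (KLT reconstructions are orchestrated by
#'   [reconstruct_series()], which builds the transform from a preliminary
#'   Fourier pass.)
#' @param x0 optional initial coefficient stack.
#' @return object of class `recon_result`: the reconstructed
#'   [image_series()], `residual_trace` (one vector of per-CG-iteration
#'   data residuals per outer iteration), `n_foc_used`, `converged`, the
#'   transform used and the final coefficient stack `x`.
#'
#' @details When the mask is full and `lambda = 0` the measurement operator
#' is square and unitary, so the least-squares problem has the unique exact
#' solution `x = A^H y` for any weighting; it is computed directly instead
#' of iterated.
#' @export
ktfocuss <- function(y, config = recon_config(), transform = NULL, x0 = NULL) {
  stopifnot(inherits(y, "kspace_series"), inherits(config, "recon_config"))
  if (is.null(y$mask))
    stop("k-space series has no attached sampling mask; use full_mask() for ",
         "fully sampled data")
  d <- dim(y$data)
  transform <- transform %||% ft_transform(d[3L])
  assert_unitary(transform$Phi)
  # decouple the fully sampled readout axis once
  yh <- fft_centered(y$data, 1L, inverse = TRUE)
  ops <- kt_operators(y$mask, transform$Phi, d[1L])
  inv <- function(x) apply_time_matrix(x, Conj(transform$Phi))
  if (all(y$mask$lines) && config$lambda == 0) {
    # fully determined: A is unitary, the exact solution is the adjoint
    x <- ops$Ah(yh)
    fit <- list(x = x, image = inv(x), residual_trace = list(0),
                n_foc_used = 1L, converged = TRUE)
  } else
  fit <- focuss_engine(ops$A, ops$Ah, yh, p = config$p, lambda = config$lambda,
                       n_cg = config$n_cg, n_foc = config$n_foc,
                       stop_tol = config$stop_tol, x0 = x0, invert = inv,
                       max_auto = config$max_auto)
  series <- image_series(fit$image, paradigm = y$paradigm,
                         provenance = "reconstruction")
  structure(list(series = series, residual_trace = fit$residual_trace,
                 n_foc_used = fit$n_foc_used, converged = fit$converged,
                 transform = transform, config = config, x = fit$x,
                 mask = y$mask),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  d <- dim(x$series$frames)
  cat(sprintf("<recon_result %s: %d x %d x %d, N_FOC used = %d%s>\n",
              x$transform$kind, d[1L], d[2L], d[3L], x$n_foc_used,
              if (x$converged) "" else " (stopping criterion did not fire)"))
  invisible(x)
}

#' Karhunen-Loeve temporal transform from a preliminary reconstruction
#'
#' Builds the `T x T` time covariance `C = U^H U` of the preliminary image
#' stack (frames as columns) and returns its eigenvectors, sorted by
#' descending eigenvalue, as the unitary KL analysis transform.
#'
#' @param prelim a `recon_result` or [image_series()] (typically a
#'   2-iteration temporal-Fourier reconstruction).
#' @return a [temporal_transform()] of kind `"KLT"` carrying the covariance
#'   spectrum.
#' @export
build_klt <- function(prelim) {
  series <- if (inherits(prelim, "recon_result")) prelim$series else prelim
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  u <- series$frames
  dim(u) <- c(d[1L] * d[2L], d[3L])
  if (all(Mod(u) == 0)) stop("preliminary reconstruction is identically zero")
  C <- Conj(t(u)) %*% u
  e <- eigen(C, symmetric = TRUE)
  structure(list(Phi = t(Conj(e$vectors)), kind = "KLT",
                 eigenvalues = e$values),
            class = "temporal_transform")
}

#' Reconstruct a masked k-space series under a configuration
#'
#' Dispatcher over the two transform variants: the temporal-Fourier variant
#' calls [ktfocuss()] directly; the KLT variant first runs a preliminary
#' Fourier reconstruction with `prelim_n_foc` outer iterations, builds the
#' KL transform from it with [build_klt()], and reruns `n_klt` times with
#' the data-driven basis.
#'
#' @inheritParams ktfocuss
#' @return a `recon_result`.
#' @export
reconstruct_series <- function(y, config = recon_config()) {
  if (config$transform == "temporal_ft")
    return(ktfocuss(y, config))
  prelim_cfg <- recon_config("temporal_ft", n_foc = config$prelim_n_foc,
                             n_cg = config$n_cg, p = config$p)
  res <- ktfocuss(y, prelim_cfg)
  for (j in seq_len(max(1L, config$n_klt))) {
    Phi <- build_klt(res)
    res <- ktfocuss(y, config, transform = Phi)
  }
  res
}

#' Relative-change stopping criterion for the FOCUSS outer loop
#'
#' Fires when `||U_k - U_km1||_F / ||U_k||_F < stop_tol`.
#'
#' @param U_k,U_km1 current and previous image iterates ([image_series()]
#'   or complex arrays of equal shape).
#' @param stop_tol positive tolerance (default 0.1).
#' @return logical.
#' @export
stopping_criterion <- function(U_k, U_km1, stop_tol = 0.1) {
  a <- if (inherits(U_k, "image_series")) U_k$frames else U_k
  b <- if (inherits(U_km1, "image_series")) U_km1$frames else U_km1
  if (!identical(dim(a), dim(b))) stop("iterates have different shapes")
  na <- frob(a)
  if (na == 0) stop("current iterate has zero norm")
  frob(a - b) / na < stop_tol
}

#' Data-fit residual between measured and reconstructed k-space
#'
#' `sum |y - y_hat|^2` over the sampled entries only.
#'
#' @param y,y_hat [kspace_series()] objects carrying identical masks.
#' @return nonnegative scalar.
#' @export
residual_error <- function(y, y_hat) {
  stopifnot(inherits(y, "kspace_series"), inherits(y_hat, "kspace_series"))
  ml <- function(k) if (is.null(k$mask)) NULL else k$mask$lines
  if (!identical(ml(y), ml(y_hat)))
    stop("residual_error requires both series to carry the same mask")
  d <- dim(y$data)
  if (!identical(d, dim(y_hat$data))) stop("k-space shapes differ")
  sel <- if (is.null(y$mask)) TRUE else rep(as.logical(y$mask$lines), each = d[1L])
  sum(Mod(y$data[sel] - y_hat$data[sel])^2)
}

#' Predicted k-space of a reconstruction under its mask
#'
#' @param result a `recon_result`.
#' @return a masked [kspace_series()] comparable to the measurements via
#'   [residual_error()].
#' @export
predict_kspace <- function(result) {
  stopifnot(inherits(result, "recon_result"))
  full <- kspace_series(fft2_frames(result$series$frames),
                        paradigm = result$series$paradigm)
  apply_mask(full, result$mask)
}

#' Cross-validated selection of the outer iteration count
#'
#' Subject-based leave-one-out selection of `N_FOC`: every dataset is
#' undersampled with its own seeded mask of the requested pattern and
#' reconstructed with `n_foc = "auto"`; the stopping iteration of each
#' dataset is recorded, and the value assigned to each held-out dataset is
#' the mode (ties toward the smaller value) over the remaining training
#' datasets. The overall returned value is the mode of the per-fold values.
#'
#' @param datasets list of at least two fully sampled [kspace_series()].
#' @param mask_pattern one of `"R"`, `"G"`, `"GR"`, `"GRC1"`,
#'   `"GRC1_PAIRED"`.
#' @param config a [recon_config()] (its `n_foc` is forced to `"auto"`).
#' @param D downsampling factor.
#' @param seed base seed; dataset `i` uses mask seed `seed + i`.
#' @return object of class `nfoc_cv`: `n_foc` (consensus), `per_fold`
#'   (held-out assignments) and `per_dataset` (raw stopping iterations).
#' @export
select_nfoc_cv <- function(datasets, mask_pattern = "GRC1",
                           config = recon_config(), D = 4L, seed = 1L) {
  if (!is.list(datasets) || length(datasets) < 2L)
    stop("leave-one-out selection needs at least 2 datasets")
  gen <- switch(mask_pattern,
                R = gen_uniform, G = gen_gaussian, GR = gen_mixture,
                GRC1 = gen_mixture_center1, GRC1_PAIRED = gen_pairwise,
                stop("unknown mask pattern: ", mask_pattern))
  config$n_foc <- "auto"
  per_dataset <- vapply(seq_along(datasets), function(i) {
    y <- datasets[[i]]
    d <- dim(y$data)
    m <- gen(d[2L], d[3L], D, seed = seed + i)
    reconstruct_series(apply_mask(y, m), config)$n_foc_used
  }, integer(1))
  per_fold <- vapply(seq_along(datasets), function(i)
    int_mode(per_dataset[-i]), integer(1))
  structure(list(n_foc = int_mode(per_fold), per_fold = per_fold,
                 per_dataset = per_dataset, pattern = mask_pattern,
                 transform = config$transform),
            class = "nfoc_cv")
}

#' @export
print.nfoc_cv <- function(x, ...) {
  cat(sprintf("<nfoc_cv %s/%s: N_FOC = %d (per fold: %s)>\n", x$pattern,
              x$transform, x$n_foc, paste(x$per_fold, collapse = ", ")))
  invisible(x)
}
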