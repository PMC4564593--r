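# Activation statistics and reconstruction-fidelity metrics.

#' Per-pixel Welch t-score map of a block-design series
#'
#' Magnitude images are compared between the pre-stimulus baseline block
#' `x` and the stimulation block `y` (optionally shifted by a hemodynamic
#' delay) with the unequal-variance statistic
#' \deqn{T = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}}
#' and Welch-Satterthwaite degrees of freedom. Note the sign convention:
#' baseline minus activation, so activated pixels carry negative T; all
#' thresholding is two-sided on |T|. Pixels with zero variance in both
#' blocks receive a signed large-value sentinel (1e6) and are flagged.
#'
#' @param series an [image_series()] with a paradigm (or supply `paradigm`).
#' @param paradigm optional [paradigm()] overriding the series metadata.
#' @param delay hemodynamic delay in frames applied to the stimulation
#'   block (default 0).
#' @return object of class `activation_map` with matrices `t_scores` and
#'   `df`, the zero-variance `flags`, and block sizes `n_x`, `n_y`.
#'   [threshold_and_cluster()] adds the thresholded `active_mask`.
#' @export
tscore_map <- function(series, paradigm = NULL, delay = 0L) {
  stopifnot(inherits(series, "image_series"))
  par <- paradigm %||% series$paradigm
  if (is.null(par)) stop("no paradigm available for the t-test")
  d <- dim(series$frames)
  xidx <- seq_len(par$n_pre)
  yidx <- par$n_pre + delay + seq_len(par$n_stim)
  if (max(yidx) > d[3L] || min(yidx) < 1L)
    stop("stimulation block falls outside the series after delay shift")
  if (length(xidx) < 2L || length(yidx) < 2L)
    stop("both baseline and activation blocks need at least 2 frames")
  mag <- Mod(series$frames)
  dim(mag) <- c(d[1L] * d[2L], d[3L])
  mstat <- function(idx) {
    m <- rowMeans(mag[, idx, drop = FALSE])
    v <- rowSums((mag[, idx, drop = FALSE] - m)^2) / (length(idx) - 1L)
    list(m = m, v = v, n = length(idx))
  }
  sx <- mstat(xidx); sy <- mstat(yidx)
  se2 <- sx$v / sx$n + sy$v / sy$n
  diff <- sx$m - sy$m
  tval <- diff / sqrt(se2)
  df <- se2^2 / (sx$v^2 / (sx$n^2 * (sx$n - 1L)) + sy$v^2 / (sy$n^2 * (sy$n - 1L)))
  flags <- se2 == 0
  tval[flags] <- sign(diff[flags]) * 1e6
  df[flags | !is.finite(df)] <- sx$n + sy$n - 2L
  shape <- d[1:2]
  structure(list(t_scores = matrix(tval, shape[1L], shape[2L]),
                 df = matrix(df, shape[1L], shape[2L]),
                 flags = matrix(flags, shape[1L], shape[2L]),
                 n_x = sx$n, n_y = sy$n, delay = delay,
                 alpha = NULL, min_cluster = NULL, active_mask = NULL,
                 source = series$provenance),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map %d x %d%s>\n", nrow(x$t_scores), ncol(x$t_scores),
              if (is.null(x$active_mask)) "" else
                sprintf(", %d active pixels (alpha = %g, min cluster = %d)",
                        sum(x$active_mask), x$alpha, x$min_cluster)))
  invisible(x)
}

#' Threshold a t-score map and reject small clusters
#'
#' Two-sided thresholding of |T| at significance `alpha` under the t
#' distribution with each pixel's Welch degrees of freedom, followed by
#' removal of 4-connected components smaller than `min_cluster` pixels.
#' Idempotent: the active mask is always recomputed from the scores.
#'
#' @param map an `activation_map` from [tscore_map()].
#' @param alpha significance level in (0, 1).
#' @param min_cluster minimum surviving component size in pixels.
#' @return the map with `active_mask`, `alpha`, `min_cluster` filled in.
#' @export
threshold_and_cluster <- function(map, alpha = 0.05, min_cluster = 6L) {
  stopifnot(inherits(map, "activation_map"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  thr <- stats::qt(1 - alpha / 2, df = map$df)
  supra <- abs(map$t_scores) > thr
  lab <- label_components(supra)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    fg <- lab > 0L
    supra[fg][sizes[lab[fg]] < min_cluster] <- FALSE
  }
  map$active_mask <- supra
  map$alpha <- alpha
  map$min_cluster <- as.integer(min_cluster)
  map
}

#' Region of interest from a full-sampled activation map
#'
#' The ROI is the set of pixels declared functionally active (null
#' hypothesis rejected) on the fully sampled data; a fresh ROI is defined
#' per dataset and never shared.
#'
#' @param full_map a thresholded `activation_map` derived from fully
#'   sampled data.
#' @param source provenance label stored with the ROI.
#' @return object of class `roi` with a logical `mask`.
#' @export
select_roi <- function(full_map, source = "full_sampled") {
  stopifnot(inherits(full_map, "activation_map"))
  if (is.null(full_map$active_mask))
    stop("threshold the map first with threshold_and_cluster()")
  if (!any(full_map$active_mask))
    stop("no active pixels survive thresholding; lower alpha or min_cluster, ",
         "or check that the data contain activation")
  structure(list(mask = full_map$active_mask, source = source), class = "roi")
}

#' Mean time course over a region of interest
#'
#' @param series an [image_series()].
#' @param roi an `roi` (or logical matrix) with at least one pixel.
#' @return numeric vector: per-frame mean magnitude over the ROI.
#' @export
roi_timecourse <- function(series, roi) {
  stopifnot(inherits(series, "image_series"))
  mask <- if (inherits(roi, "roi")) roi$mask else roi
  if (!any(mask)) stop("ROI is empty")
  d <- dim(series$frames)
  mag <- Mod(series$frames)
  dim(mag) <- c(d[1L] * d[2L], d[3L])
  colMeans(mag[as.vector(mask), , drop = FALSE])
}

#' Frame-wise normalized mean squared error
#'
#' `||u_t - uhat_t||^2 / ||u_t||^2` for frame `t` (all frames when `t` is
#' omitted).
#'
#' @param truth,recon [image_series()] objects of equal shape.
#' @param t frame index or vector of indices; default all frames.
#' @return numeric vector of per-frame NMSE values.
#' @export
frame_nmse <- function(truth, recon, t = NULL) {
  stopifnot(inherits(truth, "image_series"), inherits(recon, "image_series"))
  if (!identical(dim(truth$frames), dim(recon$frames)))
    stop("series shapes differ")
  t <- t %||% seq_len(dim(truth$frames)[3L])
  vapply(t, function(tt) {
    u <- truth$frames[, , tt]
    den <- sum(Mod(u)^2)
    if (den == 0) stop("truth frame ", tt, " has zero norm")
    sum(Mod(u - recon$frames[, , tt])^2) / den
  }, numeric(1))
}

#' Average mean squared error of a whole time series
#'
#' `sum_t ||u_t - uhat_t||^2 / (T N)`: the mean squared modulus error over
#' all pixels and frames.
#'
#' @inheritParams frame_nmse
#' @return nonnegative scalar.
#' @export
average_mse <- function(truth, recon) {
  stopifnot(inherits(truth, "image_series"), inherits(recon, "image_series"))
  if (!identical(dim(truth$frames), dim(recon$frames)))
    stop("series shapes differ")
  mean(Mod(truth$frames - recon$frames)^2)
}

#' ROC curve of activation detection against a ground-truth map
#'
#' Sweeps the two-sided significance threshold (equivalently a threshold on
#' |T|) over `n_thresholds` pooled-quantile values spanning the observed
#' score range; at each threshold the true positive fraction is the number
#' of true-positive pixels over the truly active count and the false
#' positive fraction the false positives over the truly inactive count.
#' The curve is anchored at (0,0) and (1,1) and the AUC computed by
#' trapezoidal integration.
#'
#' @param t_map an `activation_map` (scores of the reconstruction under
#'   test) or a numeric score matrix.
#' @param ground_truth logical matrix: the activation map of the fully
#'   sampled data (must contain both active and inactive pixels).
#' @param n_thresholds number of sweep points (default 200).
#' @return object of class `roc_result` with `fpf`, `tpf`, `thresholds`
#'   and `auc`.
#' @export
roc_curve <- function(t_map, ground_truth, n_thresholds = 200L) {
  scores <- if (inherits(t_map, "activation_map")) abs(t_map$t_scores) else abs(t_map)
  stopifnot(is.matrix(scores), is.logical(ground_truth) || all(ground_truth %in% c(0, 1)))
  gt <- as.logical(ground_truth)
  if (!any(gt) || all(gt))
    stop("ground truth must contain both active and inactive pixels")
  if (length(gt) != length(scores)) stop("score and ground-truth shapes differ")
  thr <- stats::quantile(scores, probs = seq(0, 1, length.out = n_thresholds),
                         names = FALSE, type = 7)
  # always include the class-boundary operating points so an achievable
  # perfect-separation corner (FPF 0 at TPF 1) is never missed by the grid
  thr <- sort(unique(c(thr, max(scores[!gt]), min(scores[gt]))))
  npos <- sum(gt); nneg <- sum(!gt)
  tpf <- vapply(thr, function(h) sum(scores > h & gt) / npos, numeric(1))
  fpf <- vapply(thr, function(h) sum(scores > h & !gt) / nneg, numeric(1))
  # loosest threshold anchor (everything declared active) and strictest
  fpf <- c(0, fpf, 1); tpf <- c(0, tpf, 1)
  ord <- order(fpf, tpf)
  fpf <- fpf[ord]; tpf <- tpf[ord]
  auc <- sum(diff(fpf) * (utils::head(tpf, -1) + utils::tail(tpf, -1)) / 2)
  structure(list(fpf = fpf, tpf = tpf, thresholds = thr, auc = auc,
                 ground_truth = gt, n_thresholds = n_thresholds),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.4f over %d thresholds>\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpf, x$tpf, type = "l", xlab = "False positive fraction",
                 ylab = "True positive fraction",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
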