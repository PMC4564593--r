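test_that("forward model and adjoint are a true operator pair", {
  m <- gen_mixture_center1(48, 16, 4, seed = 1)
  tf <- ft_transform(16)
  x <- rcarr(c(8, 48, 16), seed = 2)
  y <- rcarr(c(8, 48, 16), seed = 3)
  expect_true(all(forward_model(x * 0, m, tf) == 0))
  ax <- forward_model(x, m, tf)
  ahy <- adjoint_model(y, m, tf)
  lhs <- sum(Conj(ax) * y)
  rhs <- sum(Conj(x) * ahy)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-8)
  # full mask: A^H A is the identity (all transforms unitary)
  fm <- full_mask(48, 16)
  expect_lt(max(Mod(adjoint_model(forward_model(x, fm, tf), fm, tf) - x)), 1e-10)
  # non-unitary transforms are rejected
  bad <- tf; bad$Phi <- bad$Phi * 2
  expect_error(forward_model(x, m, bad), "unitary")
  expect_error(temporal_transform(diag(3) * 2), "unitary")
})

test_that("cg_solve reproduces reference solutions", {
  tf <- ft_transform(16)
  fm <- full_mask(48, 16)
  y <- rcarr(c(4, 48, 16), seed = 4)
  W <- array(1, dim(y))
  # identity weights, full mask, lambda 0: q is the transform of the data
  sol <- cg_solve(fm, tf, W, y, lambda = 0, n_cg = 10)
  expect_lt(max(Mod(sol$q - adjoint_model(y, fm, tf))) / max(Mod(sol$q)), 1e-6)
  # a dominant regularizer bounds the solution norm
  b <- adjoint_model(y, fm, tf)
  sol6 <- cg_solve(fm, tf, W, y, lambda = 1e6, n_cg = 30)
  expect_lte(ktfmri:::frob(sol6$q),
             ktfmri:::frob(b) / 1e6 * (1 + 1e-6))
})

test_that("cg_solve matches a dense normal-equations oracle on a toy system", {
  # 4 PE lines x 2 frames = 8 unknowns, half sampled
  lines <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                    FALSE, TRUE, TRUE, FALSE), 4, 2)
  m <- ktfmri:::new_sampling_mask(lines, "R", 2L)
  tf <- ft_transform(2L)
  A <- dense_forward_matrix(m, tf)
  y <- rcarr(c(1, 4, 2), seed = 5)
  W <- ktfmri:::with_seed(6, array(stats::runif(8, 0.2, 2), c(1, 4, 2)))
  lambda <- 0.3
  H <- diag(as.vector(W)) %*% Conj(t(A)) %*% A %*% diag(as.vector(W)) +
    lambda * diag(8)
  b <- diag(as.vector(W)) %*% Conj(t(A)) %*% as.vector(y)
  q_ref <- solve(H, b)
  sol <- cg_solve(m, tf, W, y, lambda = lambda, n_cg = 50)
  expect_lt(max(Mod(as.vector(sol$q) - as.vector(q_ref))), 1e-6)
})

test_that("fully sampled data are reconstructed exactly at lambda 0", {
  fx <- fix_bssfp()
  kf <- kspace_series(fx$kfull$data, mask = full_mask(48, 48),
                      paradigm = fx$paradigm)
  for (tr in c("temporal_ft", "klt")) {
    res <- reconstruct_series(kf, recon_config(tr, lambda = 0))
    expect_lt(ktfmri:::frob(res$series$frames - fx$truth$frames) /
                ktfmri:::frob(fx$truth$frames), 1e-6, label = tr)
  }
  expect_error(ktfocuss(fx$kfull), "mask")
})

test_that("reconstruction is deterministic and records diagnostics", {
  fx <- fix_bssfp()
  ym <- apply_mask(fx$kfull, gen_mixture_center1(48, 48, 4, seed = 3))
  r1 <- ktfocuss(ym, recon_config("temporal_ft"))
  r2 <- ktfocuss(ym, recon_config("temporal_ft"))
  expect_identical(r1$series$frames, r2$series$frames)
  expect_identical(r1$n_foc_used, length(r1$residual_trace))
  expect_true(r1$converged)
  expect_s3_class(r1$series, "image_series")
  expect_identical(dim(r1$series$frames), dim(fx$kfull$data))
})

test_that("data residual is monotone within each inner solve", {
  fx <- fix_bssfp()
  ym <- apply_mask(fx$kfull, gen_mixture_center1(48, 48, 4, seed = 3))
  res <- ktfocuss(ym, recon_config("temporal_ft", n_foc = 3))
  for (k in seq_along(res$residual_trace)) {
    tr <- res$residual_trace[[k]]
    expect_gt(length(tr), 1)
    expect_lte(max(diff(tr)), 1e-8 * tr[1])
  }
  # the recorded residual matches an independent recomputation
  yhat <- predict_kspace(res)
  final <- res$residual_trace[[res$n_foc_used]]
  expect_equal(residual_error(ym, yhat), final[length(final)],
               tolerance = 1e-6)
})

test_that("residual_error sums squared moduli over sampled entries", {
  lines <- matrix(TRUE, 3, 1)
  m <- ktfmri:::new_sampling_mask(lines, "R", 1L)
  y <- kspace_series(array(c(1 + 0i, 0 + 1i, 2 + 0i), c(1, 3, 1)), mask = m)
  y0 <- kspace_series(array(0 + 0i, c(1, 3, 1)), mask = m)
  expect_equal(residual_error(y, y), 0)
  expect_equal(residual_error(y, y0), 6)
  ym <- kspace_series(array(0 + 0i, c(1, 3, 1)),
                      mask = ktfmri:::new_sampling_mask(matrix(c(TRUE, FALSE, TRUE), 3, 1), "R", 1L))
  expect_error(residual_error(y, ym), "mask")
})

test_that("stopping criterion implements the relative Frobenius rule", {
  u <- array(1 + 0i, c(2, 2, 1))
  expect_true(stopping_criterion(u, u))                 # ratio 0
  expect_false(stopping_criterion(u, u * 0))            # ratio 1
  # hand case: ||(0, 0.4)|| / ||(3, 4)|| = 0.08 < 0.1
  uk <- array(c(3, 4) + 0i, c(1, 2, 1))
  ukm <- array(c(3, 3.6) + 0i, c(1, 2, 1))
  expect_true(stopping_criterion(uk, ukm, 0.1))
  expect_false(stopping_criterion(uk, ukm, 0.07))
  expect_error(stopping_criterion(u * 0, u), "zero norm")
  expect_error(stopping_criterion(u, array(0i, c(1, 1, 1))), "shapes")
})

test_that("KLT construction: covariance eigenbasis, sorted and unitary", {
  # rank-1 series: a single temporal mode carries all the energy
  mode <- exp(2i * pi * (0:15) / 16)
  sp <- rcarr(c(6, 4, 1), seed = 7)
  frames <- array(0i, c(6, 4, 16))
  for (t in 1:16) frames[, , t] <- sp[, , 1] * mode[t]
  kl <- build_klt(image_series(frames))
  expect_gt(kl$eigenvalues[1] / sum(kl$eigenvalues), 0.999)
  expect_lt(max(Mod(kl$Phi %*% Conj(t(kl$Phi)) - diag(16))), 1e-10)
  expect_error(build_klt(image_series(frames * 0)), "zero")
})

test_that("KLT eigendecomposition matches a dense oracle on a 4x4 toy", {
  # frames built from orthogonal temporal modes with distinct norms
  modes <- qr.Q(qr(matrix(c(1, 1, 1, 1,
                            1, -1, 1, -1,
                            1, 1, -1, -1,
                            1, -1, -1, 1), 4, 4)))
  scales <- c(5, 3, 2, 1)
  pix <- diag(4)                    # 4 "pixels", one per mode
  frames <- array(0i, c(2, 2, 4))
  um <- matrix(0i, 4, 4)
  for (j in 1:4) um[j, ] <- scales[j] * modes[, j]
  frames[] <- um
  kl <- build_klt(image_series(frames))
  C <- Conj(t(um)) %*% um
  expect_lt(max(Mod(C - Conj(t(C)))), 1e-12)            # Hermitian
  expect_equal(kl$eigenvalues, scales^2, tolerance = 1e-8)
  for (j in 1:4)                                         # eigenvectors up to phase
    expect_equal(Mod(sum(kl$Phi[j, ] * modes[, j])), 1, tolerance = 1e-8)
})

test_that("FT and KLT reconstructions agree on fully sampled data", {
  fx <- fix_bssfp()
  kf <- kspace_series(fx$kfull$data, mask = full_mask(48, 48),
                      paradigm = fx$paradigm)
  rf <- reconstruct_series(kf, recon_config("temporal_ft", lambda = 0))
  rk <- reconstruct_series(kf, recon_config("klt", lambda = 0))
  expect_lt(ktfmri:::frob(rf$series$frames - rk$series$frames) /
              ktfmri:::frob(rf$series$frames), 1e-6)
})

test_that("cross-validated N_FOC selection applies the consensus rule", {
  expect_error(select_nfoc_cv(list(fix_bssfp()$kfull)), "at least 2")
  expect_identical(ktfmri:::int_mode(c(3L, 3L, 4L)), 3L)
  expect_identical(ktfmri:::int_mode(c(3L, 4L)), 3L)     # tie -> smaller
  expect_identical(ktfmri:::int_mode(c(5L, 5L, 2L, 2L, 2L)), 2L)
  # three synthetic subjects at desk scale; KLT needs at least as many
  # outer iterations as temporal FT on the same data
  par <- paradigm(6, 4, 6)
  datasets <- lapply(1:3, function(s) {
    ph <- make_phantom(c(32, 36), seed = s)
    acq <- acquisition_config("bssfp", phase_cycling = 180,
                              matrix_size = c(32, 36))
    ser <- simulate_timeseries(ph, par, acq)
    to_kspace(ser, noise_sd = noise_sd_for_snr(ser, 20), seed = 40 + s)
  })
  cv_ft <- select_nfoc_cv(datasets, "GRC1", recon_config("temporal_ft"), seed = 2)
  cv_klt <- select_nfoc_cv(datasets, "GRC1", recon_config("klt"), seed = 2)
  expect_true(all(cv_ft$per_dataset >= 1))
  expect_identical(cv_ft$per_fold,
                   vapply(1:3, function(i) ktfmri:::int_mode(cv_ft$per_dataset[-i]),
                          integer(1)))
  expect_gte(cv_klt$n_foc, cv_ft$n_foc)
})

test_that("the auto cap returns a flag rather than an error", {
  # adversarial tolerance that can never fire
  fx <- fix_bssfp()
  ym <- apply_mask(fx$kfull, gen_uniform(48, 48, 4, seed = 4))
  res <- ktfocuss(ym, recon_config("temporal_ft", stop_tol = 1e-12,
                                   max_auto = 3, n_cg = 5))
  expect_false(res$converged)
  expect_identical(res$n_foc_used, 3L)
})

test_that("recon_config validates parameters and applies transform defaults", {
  expect_equal(recon_config("temporal_ft")$lambda, 0.1)
  expect_equal(recon_config("klt")$lambda, 0.01)
  expect_error(recon_config(p = 0), "p must")
  expect_error(recon_config(lambda = -1), "nonnegative")
  expect_error(recon_config(n_foc = 0), "positive")
})
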