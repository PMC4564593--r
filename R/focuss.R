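# FOCUSS (FOCal Underdetermined System Solver) core: iteratively reweighted
# least squares driven by weights W = |x|^p, each reweighted subproblem
# solved by conjugate gradients on the regularized normal equations
#   (W A^H A W + lambda I) q = W A^H y,        x = W . q.
# With p = 0.5 the fixed points match the minimum-l1 (basis pursuit)
# solution on the measurement-consistent set.

# Conjugate gradients for the Hermitian PSD operator
#   M(q) = W * Ah(A(W * q)) + lambda * q.
# Returns q plus the data-fit residual ||y - A(W q)||^2 recorded before the
# first and after every CG update. Early exit when the residual (gradient)
# norm drops below `grad_tol`.
cg_weighted <- function(A, Ah, W, y, lambda, n_cg, q0, grad_tol = 1e-12,
                        track = TRUE) {
  Mop <- function(q) W * Ah(A(W * q)) + lambda * q
  b <- W * Ah(y)
  q <- q0
  r <- b - Mop(q)
  d <- r
  rho <- sum(Mod(r)^2)
  trace <- if (track) sum(Mod(y - A(W * q))^2) else numeric(0)
  for (i in seq_len(n_cg)) {
    if (sqrt(rho) < grad_tol) break
    Md <- Mop(d)
    denom <- Re(sum(Conj(d) * Md))
    if (denom <= 0) break                       # numerically rank-deficient
    alpha <- rho / denom
    q <- q + alpha * d
    r <- r - alpha * Md
    rho_new <- sum(Mod(r)^2)
    d <- r + (rho_new / rho) * d
    rho <- rho_new
    if (track) trace <- c(trace, sum(Mod(y - A(W * q))^2))
  }
  list(q = q, residual_trace = trace)
}

# FOCUSS outer loop over generic linear operators. `invert` maps the sparse
# coefficient stack back to the image domain for the relative-change
# stopping rule. Each inner solve restarts CG at q0 = 0: from the origin the
# CG iterate norm ||q_k|| is nondecreasing while the quadratic objective
# ||A W q - y||^2 + lambda ||q||^2 is nonincreasing, so the data-fit
# residual itself decreases monotonically across CG iterations --- the
# convergence behaviour the residual_trace diagnostics rely on.
focuss_engine <- function(A, Ah, y, p, lambda, n_cg, n_foc, stop_tol,
                          x0 = NULL, invert = identity, max_auto = 20L,
                          track = TRUE) {
  auto <- identical(n_foc, "auto")
  kmax <- if (auto) max_auto else n_foc
  x <- x0 %||% Ah(y)
  u_prev <- invert(x)
  traces <- vector("list", 0L)
  converged <- !auto
  n_used <- 0L
  for (k in seq_len(kmax)) {
    mx <- max(Mod(x))
    if (mx == 0) {                       # zero data: zero solution is exact
      n_used <- k; converged <- TRUE
      traces[[k]] <- sum(Mod(y)^2)
      break
    }
    W <- pmax(Mod(x)^p, 1e-12 * mx^p)
    sol <- cg_weighted(A, Ah, W, y, lambda, n_cg, q0 = x * 0, track = track)
    x <- W * sol$q
    traces[[k]] <- sol$residual_trace
    u <- invert(x)
    n_used <- k
    if (auto && frob(u - u_prev) < stop_tol * frob(u)) {
      converged <- TRUE
      u_prev <- u
      break
    }
    u_prev <- u
  }
  list(x = x, image = u_prev, residual_trace = traces,
       n_foc_used = n_used, converged = converged)
}
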