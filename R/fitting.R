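# Vectorized voxelwise curve fitting.
#
# All fitters operate on a signal matrix S (voxels x frames) and run
# Gauss-Newton updates simultaneously for every voxel with 2x2 normal
# equations, so a whole-brain fit is a handful of matrix operations per
# iteration instead of 1e5 separate optimizer calls.

# Gauss-Newton for S = s0 * f(rate * x), given f and f' as functions of the
# (voxel rate) outer (frame x) matrix argument. Returns refined s0, rate.
gn_separable <- function(S, x, s0, rate, ffun, fprime,
                         max_iter = 60L, tol = 1e-13,
                         rate_bounds = c(1e-9, 1e3)) {
  nv <- nrow(S)
  active <- rep(TRUE, nv)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    A <- outer(rate[idx], x)                 # nv_act x nx
    Fm <- ffun(A)
    Dm <- fprime(A)                          # d f / d A
    model <- s0[idx] * Fm
    R <- S[idx, , drop = FALSE] - model
    # Jacobian columns: d/ds0 = Fm ; d/drate = s0 * Dm * x
    J2 <- (s0[idx] * Dm) * rep(x, each = length(idx))
    a11 <- rowSums(Fm * Fm)
    a12 <- rowSums(Fm * J2)
    a22 <- rowSums(J2 * J2)
    g1 <- rowSums(Fm * R)
    g2 <- rowSums(J2 * R)
    det <- a11 * a22 - a12 * a12
    det[abs(det) < 1e-300] <- NA_real_
    d_s0 <- (a22 * g1 - a12 * g2) / det
    d_rate <- (-a12 * g1 + a11 * g2) / det
    bad <- !is.finite(d_s0) | !is.finite(d_rate)
    d_s0[bad] <- 0; d_rate[bad] <- 0
    # damp steps that would throw the rate far outside its bounds
    new_rate <- pmin(pmax(rate[idx] + d_rate, rate_bounds[1]), rate_bounds[2])
    d_rate <- new_rate - rate[idx]
    s0[idx] <- s0[idx] + d_s0
    rate[idx] <- new_rate
    scale_ref <- pmax(abs(rate[idx]), rate_bounds[1])
    moved <- abs(d_rate) > tol * scale_ref |
      abs(d_s0) > tol * pmax(abs(s0[idx]), 1e-12)
    active[idx] <- moved
  }
  list(s0 = s0, rate = rate)
}

# Coarse separable grid search: for each candidate rate the optimal s0 is
# linear, so the residual sum of squares is available in closed form.
grid_init <- function(S, x, rate_grid, ffun) {
  nv <- nrow(S)
  best_rss <- rep(Inf, nv)
  best_rate <- rep(rate_grid[1], nv)
  best_s0 <- rep(0, nv)
  for (r in rate_grid) {
    f <- ffun(r * x)
    denom <- sum(f * f)
    if (denom <= 0) next
    s0_hat <- as.vector(S %*% f) / denom
    rss <- rowSums(S * S) - s0_hat^2 * denom
    upd <- rss < best_rss
    if (any(upd)) {
      best_rss[upd] <- rss[upd]
      best_rate[upd] <- r
      best_s0[upd] <- s0_hat[upd]
    }
  }
  list(s0 = best_s0, rate = best_rate, rss = best_rss)
}

# Mono-exponential decay fit S = s0 * exp(-x * rate) with log-linear
# initialization. Returns s0, rate (no clamping; callers apply caps/floors).
fit_monoexp <- function(S, x, refine = TRUE) {
  Y <- log(S)
  xc <- x - mean(x)
  rate <- -as.vector(Y %*% xc) / sum(xc * xc)
  s0 <- exp(rowMeans(Y) + rate * mean(x))
  if (refine) {
    ok <- is.finite(rate) & is.finite(s0) & rate > 0
    if (any(ok)) {
      ref <- gn_separable(S[ok, , drop = FALSE], x, s0[ok], rate[ok],
                          ffun = function(a) exp(-a),
                          fprime = function(a) -exp(-a))
      s0[ok] <- ref$s0
      rate[ok] <- ref$rate
    }
  }
  list(s0 = s0, rate = rate)
}

as_signal_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, prod(d[1:3]), d[4])
}

mask_vector <- function(mask, dims3) {
  if (is.null(mask)) return(rep(TRUE, prod(dims3)))
  m <- if (inherits(mask, "roi_mask")) mask$data else mask
  if (!identical(dim(m), dims3)) stop("mask grid mismatch", call. = FALSE)
  as.vector(m)
}
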