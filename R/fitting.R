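# Vectorised two-parameter Levenberg-Marquardt.
#
# All voxel-wise models in the package (mono-exponential R2* decay, SPGR T1)
# have exactly two free parameters per voxel, so the normal equations are 2x2
# and can be solved in closed form simultaneously for every voxel. Each voxel
# carries its own damping factor; convergence is declared when the largest
# relative parameter change drops below `tol`.
#
# theta        n x 2 matrix of starting values
# predict_jac  function(theta) -> list(pred = n x m, J1 = n x m, J2 = n x m)
# y            n x m data matrix
# lower/upper  length-2 bounds applied by projection after each step
#
# Returns list(theta, converged, iterations).
lm_fit2 <- function(theta, predict_jac, y, lower = c(-Inf, -Inf),
                    upper = c(Inf, Inf), tol = 1e-8, max_iter = 60L) {
  n <- nrow(theta)
  lambda <- rep(1e-3, n)
  converged <- rep(FALSE, n)
  pj <- predict_jac(theta)
  sse <- rowSums((y - pj$pred)^2)
  iter <- 0L
  active <- which(!converged & is.finite(sse))
  while (length(active) && iter < max_iter) {
    iter <- iter + 1L
    r <- y[active, , drop = FALSE] - pj$pred[active, , drop = FALSE]
    J1 <- pj$J1[active, , drop = FALSE]
    J2 <- pj$J2[active, , drop = FALSE]
    a11 <- rowSums(J1 * J1); a22 <- rowSums(J2 * J2); a12 <- rowSums(J1 * J2)
    g1 <- rowSums(J1 * r); g2 <- rowSums(J2 * r)
    la <- lambda[active]
    d11 <- a11 * (1 + la); d22 <- a22 * (1 + la)
    det <- d11 * d22 - a12^2
    det[abs(det) < .Machine$double.xmin] <- NA
    s1 <- (g1 * d22 - g2 * a12) / det
    s2 <- (g2 * d11 - g1 * a12) / det
    th_new <- theta[active, , drop = FALSE]
    th_new[, 1] <- pmin(pmax(th_new[, 1] + s1, lower[1]), upper[1])
    th_new[, 2] <- pmin(pmax(th_new[, 2] + s2, lower[2]), upper[2])
    th_try <- theta
    th_try[active, ] <- th_new
    pj_try <- predict_jac(th_try)
    sse_try <- rowSums((y[active, , drop = FALSE] -
                          pj_try$pred[active, , drop = FALSE])^2)
    better <- is.finite(sse_try) & sse_try <= sse[active]
    step <- pmax(abs(th_new - theta[active, , drop = FALSE]) /
                   pmax(abs(theta[active, , drop = FALSE]), 1e-12))
    rel <- pmax(step[, 1], step[, 2])
    acc <- active[better]
    theta[acc, ] <- th_new[better, , drop = FALSE]
    sse[acc] <- sse_try[better]
    lambda[acc] <- pmax(lambda[acc] / 3, 1e-12)
    lambda[active[!better]] <- pmin(lambda[active[!better]] * 8, 1e12)
    converged[active[better & rel < tol]] <- TRUE
    # a rejected step with huge damping means the gradient is flat: converged
    converged[active[!better & lambda[active] >= 1e10]] <- TRUE
    pj <- predict_jac(theta)
    active <- which(!converged & is.finite(sse))
  }
  list(theta = theta, converged = converged, iterations = iter)
}

# Per-voxel ordinary least-squares line y = a + b x with per-observation 0/1
# weights, vectorised over voxels. x is a common design (length m) or an
# n x m matrix; y and w are n x m. Returns intercept, slope and the number of
# usable points per voxel.
ols_line_voxels <- function(x, y, w) {
  if (is.null(dim(x))) x <- matrix(x, nrow(y), ncol(y), byrow = TRUE)
  y0 <- ifelse(w > 0, y, 0)
  x0 <- ifelse(w > 0, x, 0)
  n <- rowSums(w)
  sx <- rowSums(x0); sy <- rowSums(y0)
  sxx <- rowSums(x0 * x); sxy <- rowSums(x0 * y0)
  denom <- n * sxx - sx^2
  denom[denom == 0] <- NA
  slope <- (n * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / n
  list(intercept = intercept, slope = slope, n = n)
}
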