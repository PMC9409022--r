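# Shared weighted nonlinear least-squares machinery.
#
# All fits in the package are separable: the model is linear in a set of
# amplitudes/baselines given a small number of nonlinear parameters
# (lifetimes, rates, Tm, Kd). We exploit this by variable projection: for a
# candidate nonlinear vector theta, the weighted linear subproblem is solved
# exactly by lm.wfit on the basis matrix, and only theta is optimised by
# L-BFGS-B from several deterministic starts. This is far more robust than
# optimising the full parameter vector and mirrors what dedicated TCSPC
# packages do internally.

# basis_fn(theta) must return a numeric matrix with one column per linear
# coefficient, rows matching y. Weights w are 1/sigma^2. Linear coefficients
# may be constrained nonnegative (nonneg = TRUE) via a clipped refit.
varpro_objective <- function(theta, basis_fn, y, w, nonneg) {
  A <- basis_fn(theta)
  if (any(!is.finite(A))) return(list(rss = Inf))
  fit <- tryCatch(stats::lm.wfit(A, y, w), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf))
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  if (nonneg && any(coef < 0)) {
    # active-set style clip: zero out negative coefs and refit the rest
    for (i in seq_len(ncol(A))) {
      neg <- which(coef < 0)
      if (!length(neg)) break
      keep <- setdiff(which(coef != 0), neg)
      coef[] <- 0
      if (length(keep)) {
        f2 <- stats::lm.wfit(A[, keep, drop = FALSE], y, w)
        coef[keep] <- f2$coefficients
        coef[is.na(coef)] <- 0
      }
    }
    coef[coef < 0] <- 0
  }
  fitted <- drop(A %*% coef)
  rss <- sum(w * (y - fitted)^2)
  list(rss = rss, coef = coef, fitted = fitted)
}

# Multi-start variable-projection WLS.
# starts: list of numeric theta vectors; lower/upper: box for theta.
# Returns theta, coef, chi2r, fitted, convergence info and asymptotic
# standard errors for c(theta, coef).
varpro_fit <- function(y, w, basis_fn, starts, lower, upper,
                       nonneg = FALSE, theta_names = NULL,
                       coef_names = NULL) {
  check_that(length(y) == length(w), "y and w lengths differ")
  obj <- function(theta) varpro_objective(theta, basis_fn, y, w, nonneg)$rss
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 10, maxit = 1000,
                                  ndeps = rep(1e-7, length(s)))),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && res$par[1] < best$par[1])) {
      best <- res
    }
  }
  if (is.null(best)) {
    return(list(ok = FALSE, message = "all starts failed"))
  }
  sol <- varpro_objective(best$par, basis_fn, y, w, nonneg)
  theta <- best$par
  coef <- sol$coef
  if (!is.null(theta_names)) names(theta) <- theta_names
  if (!is.null(coef_names)) names(coef) <- coef_names
  n <- length(y)
  p <- length(theta) + sum(coef != 0 | !nonneg)
  dof <- max(n - p, 1L)
  chi2r <- sol$rss / dof
  se <- fit_stderr(c(theta, coef), y, w, function(par) {
    th <- par[seq_along(theta)]
    cf <- par[-seq_along(theta)]
    drop(basis_fn(th) %*% cf)
  }, sol$rss, dof)
  list(ok = TRUE, theta = theta, coef = coef, chi2r = chi2r,
       rss = sol$rss, fitted = sol$fitted, residuals = y - sol$fitted,
       stderr = se, converged = best$convergence == 0, dof = dof)
}

# Asymptotic standard errors from a numeric jacobian of the model function:
# cov = sigma2 * (J' W J)^-1 with sigma2 = rss/dof.
fit_stderr <- function(par, y, w, model_fn, rss, dof) {
  n <- length(y)
  p <- length(par)
  J <- matrix(0, n, p)
  f0 <- model_fn(par)
  for (j in seq_len(p)) {
    h <- max(abs(par[j]) * 1e-6, 1e-9)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (model_fn(pj) - f0) / h
  }
  JtWJ <- crossprod(J * sqrt(w))
  cov <- tryCatch(solve(JtWJ) * rss / dof, error = function(e) NULL)
  if (is.null(cov)) return(rep(NA_real_, p))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(par)
  se
}

# Wald-Wolfowitz runs test on the signs of weighted residuals; returns the
# z statistic and a logical "random" verdict at |z| < 1.96. Used as the
# residual-randomness acceptance check alongside reduced chi-square.
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n <- length(s)
  if (n < 10) return(list(z = NA_real_, random = NA))
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  runs <- 1 + sum(s[-1] != s[-n])
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(list(z = NA_real_, random = NA))
  z <- (runs - mu) / sqrt(v)
  list(z = z, random = abs(z) < 1.96)
}
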