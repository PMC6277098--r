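#' @title Beta-likelihood EM for Gaussian-mixture QTL models
#'
#' @description
#' The phenotype of individual `j` is modelled as a mixture over the `m`
#' joint QTL genotype classes,
#' `f(y_j) = sum_i p_ji phi((y_j - mu_ji)/sigma)/sigma`, with component means
#' `mu_ji = X_j gamma + D_i . E` (genetic design row `D_i`, effect vector
#' `E`, covariate coefficients `gamma`). Parameters are estimated by
#' maximising the beta-likelihood
#' `L_beta = (1/beta) [ (1/n) sum_j f(y_j)^beta / l_beta,j - 1 ]`, where
#' `l_beta,j = [int f_j(y)^(beta+1) dy]^(beta/(beta+1))` is the model
#' normaliser. As `beta -> 0` this reduces to the mean log-likelihood, so the
#' classical interval-mapping ML fit is the `beta = 0` special case.
#' Observations with low model density are down-weighted by `f(y_j)^beta`,
#' which is what makes the estimator robust to phenotypic outliers.
#' @name beta_em
NULL

row_logsumexp <- function(M) {
  mx <- M[, 1]
  for (i in seq_len(ncol(M))[-1]) mx <- pmax(mx, M[, i])
  mx[!is.finite(mx)] <- 0
  log(rowSums(exp(M - mx))) + mx
}

theta_new <- function(E, gamma, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  list(E = as.numeric(E), gamma = as.numeric(gamma), sigma2 = sigma2)
}

#' Component means of the mixture model
#'
#' `mu_ji = X_j gamma + (D row i) . E`; for a single F2 QTL with `X gamma`
#' the covariate part, the three columns are the printed genotype means
#' `a - d/2 + X gamma`, `d/2 + X gamma`, `-a - d/2 + X gamma` in the class
#' order QQ, Qq, qq.
#'
#' @param theta Parameter list with elements `E`, `gamma`, `sigma2`.
#' @param X Covariate matrix (n x p, first column usually the intercept).
#' @param D Genetic design matrix (m x length(E)); a 1 x 0 matrix gives the
#'   null (single-component) model.
#' @return An `n x m` matrix of means.
#' @export
component_means <- function(theta, X, D) {
  X <- as.matrix(X)
  if (length(theta$gamma) != ncol(X)) {
    stop("length(gamma) must equal ncol(X)", call. = FALSE)
  }
  if (length(theta$E) != ncol(D)) {
    stop("length(E) must equal ncol(D)", call. = FALSE)
  }
  xb <- as.numeric(X %*% theta$gamma)
  offs <- if (ncol(D) > 0) as.numeric(D %*% theta$E) else rep(0, nrow(D))
  outer(xb, rep(1, nrow(D))) +
    matrix(offs, nrow(X), nrow(D), byrow = TRUE)
}

#' Gaussian mixture density of one observation
#'
#' @param y Numeric vector of evaluation points.
#' @param means Component means (length m).
#' @param probs Mixing proportions on the simplex (length m).
#' @param sigma2 Common component variance (> 0).
#' @return Density values, strictly positive.
#' @examples
#' mixture_density(0, means = c(1, 0, -1), probs = c(.25, .5, .25), sigma2 = 1)
#' @export
mixture_density <- function(y, means, probs, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-8 || any(probs < 0)) {
    stop("probs must lie on the simplex", call. = FALSE)
  }
  s <- sqrt(sigma2)
  vapply(y, function(yy) sum(probs * stats::dnorm(yy, means, s)), numeric(1))
}

# log densities of all observations: list(logphi (n x m), logf (n))
mixture_logdens <- function(y, probs, means, sigma2) {
  s2 <- sigma2
  logphi <- -0.5 * log(2 * pi * s2) - (y - means)^2 / (2 * s2)
  logp <- log(probs)
  logf <- row_logsumexp(logp + logphi)
  list(logphi = logphi, logf = logf)
}

l_beta_closed <- function(sigma2, beta) {
  ((2 * pi * sigma2)^(-beta / 2) * (beta + 1)^(-0.5))^(beta / (beta + 1))
}

#' Beta-likelihood normaliser
#'
#' Computes `l_beta,j = [int f_j(y)^(beta+1) dy]^(beta/(beta+1))` for every
#' observation. For a single-Gaussian density (null model, or degenerate
#' class probabilities) the closed form
#' `int N(mu, sigma2)^(beta+1) dy = (2 pi sigma2)^(-beta/2) (beta+1)^(-1/2)`
#' is used; genuine mixtures are integrated by Simpson quadrature over
#' `[min mu - 8 sigma, max mu + 8 sigma]`. Equals 1 for `beta = 0`. The
#' integral is translation invariant, so only the genetic offsets `D E` and
#' the class probabilities matter, not the covariate part of the means.
#'
#' @param probs `n x m` class-probability matrix.
#' @param D Genetic design matrix.
#' @param theta Parameter list (`E`, `gamma`, `sigma2`).
#' @param beta Robustness tuning parameter (>= 0).
#' @param n_grid Number of quadrature points (made odd internally).
#' @return Length-n vector of normalisers.
#' @export
l_beta_normalizer <- function(probs, D, theta, beta, n_grid = 401) {
  n <- nrow(probs)
  if (beta == 0) return(rep(1, n))
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  sigma2 <- theta$sigma2
  offs <- if (ncol(D) > 0) as.numeric(D %*% theta$E) else 0
  degen <- ncol(probs) == 1 || diff(range(offs)) < 1e-12
  if (!degen) {
    rmax <- probs[, 1]
    for (i in seq_len(ncol(probs))[-1]) rmax <- pmax(rmax, probs[, i])
    degen <- all(rmax > 1 - 1e-12)
  }
  if (degen) return(rep(l_beta_closed(sigma2, beta), n))
  if (n_grid %% 2 == 0) n_grid <- n_grid + 1
  s <- sqrt(sigma2)
  lo <- min(offs) - 8 * s
  hi <- max(offs) + 8 * s
  grid <- seq(lo, hi, length.out = n_grid)
  h <- grid[2] - grid[1]
  dens <- vapply(offs, function(mu) stats::dnorm(grid, mu, s),
                 numeric(n_grid)) # n_grid x m
  Fg <- tcrossprod(probs, dens) # n x n_grid
  w <- c(1, rep(c(4, 2), length.out = n_grid - 2), 1)
  w[n_grid - 1] <- 4
  w <- w * h / 3
  I <- as.numeric(Fg^(beta + 1) %*% w)
  if (any(!is.finite(I)) || any(I <= 0)) {
    stop("quadrature failure in l_beta (range ", lo, " to ", hi,
         ", sigma2 = ", sigma2, ")", call. = FALSE)
  }
  I^(beta / (beta + 1))
}

#' Beta-likelihood objective
#'
#' The per-observation-mean objective
#' `(1/beta)[(1/n) sum_j f(y_j)^beta / l_beta,j - 1]`; the `beta = 0` branch
#' returns the mean log-likelihood, which is the analytic limit.
#'
#' @param y Phenotype vector.
#' @param X Covariate matrix.
#' @param probs Class-probability matrix.
#' @param D Genetic design matrix.
#' @param theta Parameter list.
#' @param beta Tuning parameter (>= 0).
#' @param n_grid Quadrature resolution for the normaliser.
#' @return A single number.
#' @export
beta_likelihood <- function(y, X, probs, D, theta, beta, n_grid = 401) {
  mu <- component_means(theta, X, D)
  ld <- mixture_logdens(y, probs, mu, theta$sigma2)
  if (any(!is.finite(ld$logf))) stop("non-finite density", call. = FALSE)
  if (beta == 0) return(mean(ld$logf))
  l <- l_beta_normalizer(probs, D, theta, beta, n_grid)
  mean(exp(beta * ld$logf) / l - 1) / beta
}

#' E-step: beta-weighted posterior class probabilities
#'
#' `Pi_beta[j, i] = pi_ji f(y_j)^beta`, where `pi_ji` is the ordinary
#' posterior probability of class `i` for observation `j`. At `beta = 0`
#' rows are ordinary posteriors (sum to 1); in general row `j` sums to
#' `f(y_j)^beta`, the robustness weight of that observation. Computed in
#' log space.
#'
#' @inheritParams beta_likelihood
#' @return The `n x m` matrix `Pi_beta`.
#' @export
e_step <- function(y, X, probs, D, theta, beta) {
  mu <- component_means(theta, X, D)
  ld <- mixture_logdens(y, probs, mu, theta$sigma2)
  exp(log(probs) + ld$logphi + (beta - 1) * ld$logf)
}

#' M-step: closed-form parameter updates
#'
#' Given `Pi_beta`, the genetic effects solve the weighted normal equations
#' `V E = b` with `V[i,i'] = 1' Pi_beta (D_i # D_i')` and
#' `b_i = (y - X gamma)' Pi_beta D_i` (each observation-class pair weighted
#' by `Pi_beta[j, c]`); `gamma` is the weighted least-squares update
#' `[X'(X # w)]^{-1} X'(y # w - Pi_beta D E)` with `w_j = f(y_j)^beta`; and
#' `sigma2` is the (1 + beta)-scaled weighted residual quadratic form. By
#' default the normal equations are solved exactly; `effects_update =
#' "recurrence"` instead performs the one-sweep Jacobi update
#' `E <- m - M E` (same fixed point, slower per-iteration progress).
#'
#' @param Pi Output of [e_step()].
#' @param y,X,D As in [beta_likelihood()].
#' @param theta_prev Parameter list from the previous iteration.
#' @param beta Tuning parameter.
#' @param effects_update `"solve"` or `"recurrence"`.
#' @return An updated parameter list.
#' @export
m_step <- function(Pi, y, X, D, theta_prev, beta,
                   effects_update = c("solve", "recurrence")) {
  effects_update <- match.arg(effects_update)
  X <- as.matrix(X)
  w <- rowSums(Pi)
  p_g <- ncol(D)
  if (p_g > 0) {
    S_c <- colSums(Pi)
    V <- crossprod(D, D * S_c)
    PiD <- Pi %*% D
    r <- y - as.numeric(X %*% theta_prev$gamma)
    b <- as.numeric(crossprod(PiD, r))
    E <- if (effects_update == "solve") {
      tryCatch(as.numeric(solve(V, b)), error = function(e) {
        stop("degenerate fit: singular effects system (columns ",
             paste(colnames(D), collapse = ", "), ")", call. = FALSE)
      })
    } else {
      dV <- diag(V)
      (b - (V %*% theta_prev$E - dV * theta_prev$E)) / dV
    }
    E <- as.numeric(E)
    PiDE <- as.numeric(PiD %*% E)
    quad_E <- as.numeric(crossprod(E, V %*% E))
  } else {
    E <- numeric(0)
    PiDE <- rep(0, length(y))
    quad_E <- 0
  }
  A <- crossprod(X, X * w)
  rhs <- crossprod(X, y * w - PiDE)
  gamma <- tryCatch(as.numeric(solve(A, rhs)), error = function(e) {
    bad <- colnames(X)[which.min(abs(diag(A)))]
    stop("degenerate fit: singular weighted X'X (column ", bad, ")",
         call. = FALSE)
  })
  r2 <- y - as.numeric(X %*% gamma)
  quad <- sum(w * r2^2) - 2 * sum(r2 * PiDE) + quad_E
  sigma2 <- max((1 + beta) * quad / sum(w), 1e-12)
  theta_new(E, gamma, sigma2)
}

default_init <- function(y, X, probs, D) {
  X <- as.matrix(X)
  f0 <- stats::lm.fit(X, y)
  gamma <- f0$coefficients
  gamma[is.na(gamma)] <- 0
  res <- y - as.numeric(X %*% gamma)
  if (ncol(D) > 0) {
    Z <- probs %*% D
    fe <- stats::lm.fit(Z, res)
    E <- fe$coefficients
    E[is.na(E)] <- 0
    res <- res - as.numeric(Z %*% E)
  } else {
    E <- numeric(0)
  }
  theta_new(E, gamma, max(mean(res^2), 1e-8))
}

#' Fit the beta-likelihood mixture model by EM
#'
#' Alternates [e_step()] and [m_step()] until the relative change of the
#' beta-likelihood objective falls below `tol` or `max_iter` is reached.
#' Initialisation is deterministic: `gamma` from OLS of `y` on `X`, `E` from
#' OLS of the residuals on the expected genotype codes `probs %*% D`, and
#' `sigma2` from the residual variance.
#'
#' @inheritParams beta_likelihood
#' @param init Optional parameter list (`E`, `gamma`, `sigma2`).
#' @param tol Relative objective-change tolerance.
#' @param max_iter Iteration cap; non-convergence is flagged, not raised.
#' @param effects_update Passed to [m_step()].
#' @return An object of class `beta_em_fit`: `theta`, `objective`,
#'   `trace` (per-iteration objective values), `converged`, `n_iter`,
#'   `beta`, `n`.
#' @export
beta_em_fit <- function(y, X, probs, D, beta = 0, init = NULL, tol = 1e-8,
                        max_iter = 200,
                        effects_update = c("solve", "recurrence"),
                        n_grid = 401) {
  effects_update <- match.arg(effects_update)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(probs) == length(y),
            ncol(probs) == nrow(D), beta >= 0)
  theta <- if (is.null(init)) default_init(y, X, probs, D) else
    theta_new(init$E, init$gamma, init$sigma2)
  trace <- numeric(max_iter)
  converged <- FALSE
  it <- 0
  logp <- log(probs)
  for (it in seq_len(max_iter)) {
    mu <- component_means(theta, X, D)
    ld <- mixture_logdens(y, probs, mu, theta$sigma2)
    if (any(!is.finite(ld$logf))) stop("non-finite density", call. = FALSE)
    trace[it] <- if (beta == 0) mean(ld$logf) else
      mean(exp(beta * ld$logf) /
             l_beta_normalizer(probs, D, theta, beta, n_grid) - 1) / beta
    if (it > 1 &&
        abs(trace[it] - trace[it - 1]) <= tol * (abs(trace[it - 1]) + tol)) {
      converged <- TRUE
      break
    }
    Pi <- exp(logp + ld$logphi + (beta - 1) * ld$logf)
    theta <- m_step(Pi, y, X, D, theta, beta, effects_update)
  }
  structure(list(theta = theta, objective = trace[it], trace = trace[1:it],
                 converged = converged, n_iter = it, beta = beta,
                 n = length(y), model = if (ncol(D) > 0) "mixture" else "null",
                 term_names = c(colnames(D),
                                colnames(X) %||% paste0("x", seq_len(ncol(X))),
                                "sigma2")),
            class = "beta_em_fit")
}

#' Fit the null (no-QTL) model
#'
#' Single-Gaussian regression `y = X gamma + e` estimated by the same
#' beta-weighted iteration; the normaliser uses its closed form, no
#' quadrature. At `beta = 0` this is OLS with the ML variance.
#'
#' @inheritParams beta_em_fit
#' @param X Covariate matrix; defaults to an intercept-only column.
#' @return A `beta_em_fit` with empty `E`.
#' @export
beta_null_fit <- function(y, X = NULL, beta = 0, init = NULL, tol = 1e-8,
                          max_iter = 200) {
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  probs <- matrix(1, length(y), 1)
  D <- matrix(numeric(0), nrow = 1, ncol = 0)
  beta_em_fit(y, X, probs, D, beta = beta, init = init, tol = tol,
              max_iter = max_iter)
}

#' @export
print.beta_em_fit <- function(x, ...) {
  cat("<beta_em_fit> ", x$model, " model, beta = ", format(x$beta),
      ", n = ", x$n, "\n", sep = "")
  cat("  objective ", format(x$objective, digits = 8), " after ", x$n_iter,
      " iteration(s)", if (!x$converged) " (NOT converged)", "\n", sep = "")
  if (length(x$theta$E)) cat("  E: ", paste(format(x$theta$E, digits = 4),
                                            collapse = ", "), "\n", sep = "")
  cat("  sigma2: ", format(x$theta$sigma2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Beta-LOD score
#'
#' `LOD_beta = log10(e) n (L_beta(alt) - L_beta(null))`. At `beta = 0` this
#' is the classical LOD, i.e. the base-10 log likelihood ratio. Negative
#' values (possible for `beta > 0`, where the objectives are not nested) are
#' reported as computed; plotting floors them at zero.
#'
#' @param fit_alt,fit_null `beta_em_fit` objects on the same data and beta.
#' @return A single number.
#' @export
lod_beta <- function(fit_alt, fit_null) {
  if (fit_alt$beta != fit_null$beta || fit_alt$n != fit_null$n) {
    stop("alternative and null fits must share data size and beta",
         call. = FALSE)
  }
  log10(exp(1)) * fit_alt$n * (fit_alt$objective - fit_null$objective)
}

#' Numeric boundedness check of the estimating function
#'
#' Evaluates the gradient of the per-observation objective (the estimating
#' function psi_beta) with respect to each parameter component over a wide
#' grid of phenotype values, by central differences, and reports the
#' supremum of each component's absolute value and where it is attained.
#' For `beta > 0` every component behaves like `exp(-beta z^2)` times a
#' polynomial and the suprema sit in the interior of the grid; at `beta = 0`
#' (maximum likelihood) the components grow without bound towards the grid
#' boundary.
#'
#' @param theta Parameter list.
#' @param probs_row Mixing proportions of the observation (simplex).
#' @param D Genetic design matrix.
#' @param beta Tuning parameter.
#' @param y_grid Grid of phenotype values (should span many sigma).
#' @param x_row Covariate row (defaults to intercept only).
#' @return A tibble with columns `term`, `sup`, `argmax`, `at_boundary`.
#' @export
psi_bounds <- function(theta, probs_row, D, beta, y_grid, x_row = NULL) {
  if (is.null(x_row)) x_row <- matrix(1, 1, length(theta$gamma))
  x_row <- matrix(as.numeric(x_row), nrow = 1)
  par <- c(theta$E, theta$gamma, theta$sigma2)
  nm <- c(if (length(theta$E)) paste0("E", seq_along(theta$E)),
          paste0("gamma", seq_along(theta$gamma)), "sigma2")
  probs_mat <- matrix(probs_row, 1)
  ng <- length(y_grid)
  m <- nrow(D)
  obj_at <- function(p) {
    th <- theta_new(p[seq_along(theta$E)],
                    p[length(theta$E) + seq_along(theta$gamma)],
                    p[length(p)])
    mu <- as.numeric(component_means(th, x_row, D))
    ld <- mixture_logdens(y_grid, matrix(probs_row, ng, m, byrow = TRUE),
                          matrix(mu, ng, m, byrow = TRUE), th$sigma2)
    if (beta == 0) return(ld$logf)
    l <- l_beta_normalizer(probs_mat, D, th, beta)[1]
    (exp(beta * ld$logf) / l - 1) / beta
  }
  grads <- vapply(seq_along(par), function(i) {
    h <- 1e-5 * (1 + abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (obj_at(up) - obj_at(dn)) / (2 * h)
  }, numeric(length(y_grid)))
  idx <- apply(abs(grads), 2, which.max)
  tibble::tibble(
    term = nm,
    sup = vapply(seq_along(nm), function(i) abs(grads[idx[i], i]), numeric(1)),
    argmax = y_grid[idx],
    at_boundary = idx == 1 | idx == length(y_grid)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
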