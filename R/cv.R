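#' Default beta grid for cross-validation
#'
#' Spans near-zero (efficient, non-robust) through 0.5 (strongly robust).
#' @return Numeric vector.
#' @export
beta_grid_default <- function() {
  c(0.001, 0.005, 0.01, 0.02, 0.041, 0.06, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5)
}

#' K-fold cross-validation selection of beta
#'
#' For each candidate `beta`, the null (single-Gaussian) model is fitted on
#' each training set `D'_k` by [beta_null_fit()], and the held-out fold
#' `D_k` is scored with the beta0-divergence measure
#' `L'_beta0 = (1/beta0) [ 1 - (1/(n_k l_beta0)) sum_{D_k} f(y | theta_beta)^beta0 ]`,
#' aggregated as `D_beta0(beta) = (1/n) sum_k L'_beta0`. The selected beta
#' minimises this; ties go to the smallest beta. As `beta0 -> 0` the
#' held-out measure tends to the negative mean held-out log-likelihood.
#' Clean data select beta near zero; contaminated data select larger beta.
#'
#' On clean data the efficiency loss of large beta is a second-order effect,
#' so a single fold assignment gives a noisy argmin; the score curve is
#' therefore averaged over `repeats` independent fold assignments
#' (repeated K-fold CV) before minimising.
#'
#' @param y Phenotype vector.
#' @param X Covariate matrix (default intercept only). For scans this should
#'   match the scan's null model: intercept + cofactor codes.
#' @param beta_grid Candidate beta values (sorted internally).
#' @param K Number of folds (>= 2).
#' @param beta0 Fixed evaluation divergence parameter.
#' @param seed Optional integer seed for the fold assignments.
#' @param repeats Number of fold assignments to average over.
#' @param tol,max_iter Controls for the null fits.
#' @return A list of class `beta_cv`: `grid` (tibble `beta`, `score`),
#'   `beta_opt`, `K`, `beta0`, `repeats`, `folds` (labels of the first
#'   assignment).
#' @export
cv_select_beta <- function(y, X = NULL, beta_grid = beta_grid_default(),
                           K = 10, beta0 = 0.1, seed = NULL, repeats = 5,
                           tol = 1e-8, max_iter = 200) {
  y <- as.numeric(y)
  n <- length(y)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (length(beta_grid) == 0) stop("empty beta grid", call. = FALSE)
  if (n < 2 * K) stop("folds too small for a stable fit with K = ", K,
                      call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  beta_grid <- sort(unique(beta_grid))
  score_one <- function(beta, folds) {
    per_fold <- vapply(seq_len(K), function(k) {
      tr <- folds != k
      fit <- beta_null_fit(y[tr], X[tr, , drop = FALSE], beta = beta,
                           tol = tol, max_iter = max_iter)
      mu <- as.numeric(X[!tr, , drop = FALSE] %*% fit$theta$gamma)
      s2 <- fit$theta$sigma2
      logf <- stats::dnorm(y[!tr], mu, sqrt(s2), log = TRUE)
      l0 <- l_beta_closed(s2, beta0)
      nk <- sum(!tr)
      (1 - sum(exp(beta0 * logf)) / (nk * l0)) / beta0
    }, numeric(1))
    sum(per_fold) / n
  }
  fold_sets <- lapply(seq_len(repeats), function(r) {
    sample(rep(seq_len(K), length.out = n))
  })
  scores <- rowMeans(matrix(vapply(fold_sets, function(folds) {
    vapply(beta_grid, score_one, numeric(1), folds = folds)
  }, numeric(length(beta_grid))), nrow = length(beta_grid)))
  grid <- tibble::tibble(beta = beta_grid, score = scores)
  out <- list(grid = grid, beta_opt = beta_grid[which.min(scores)], K = K,
              beta0 = beta0, repeats = repeats, folds = fold_sets[[1]])
  class(out) <- "beta_cv"
  out
}

#' Select beta for a cross
#'
#' Convenience wrapper around [cv_select_beta()] that builds the null-model
#' covariates (intercept + cofactor codes) from a cross, matching the scan's
#' null model.
#'
#' @param cross A `qtl_cross` with phenotype.
#' @param cofactors A `cofactor_set` or `NULL`.
#' @param covariates Optional non-genetic covariates.
#' @param ... Passed to [cv_select_beta()].
#' @return A `beta_cv` object.
#' @export
select_beta <- function(cross, cofactors = NULL, covariates = NULL, ...) {
  y <- as.numeric(cross$pheno)
  codes <- marker_codes(cross)
  mk <- if (is.null(cofactors)) character(0) else cofactors$marker
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates,
             codes[, mk, drop = FALSE])
  cv_select_beta(y, X, ...)
}

#' @export
print.beta_cv <- function(x, ...) {
  cat("<beta_cv> ", x$K, "-fold CV, beta0 = ", format(x$beta0),
      "; selected beta = ", format(x$beta_opt), "\n", sep = "")
  invisible(x)
}
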