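#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a beta-likelihood EM fit
#'
#' @param x A `beta_em_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @method tidy beta_em_fit
#' @export
tidy.beta_em_fit <- function(x, ...) {
  est <- c(x$theta$E, x$theta$gamma, x$theta$sigma2)
  tibble::tibble(term = x$term_names, estimate = est)
}

#' One-row summary of a beta-likelihood EM fit
#'
#' @param x A `beta_em_fit`.
#' @param ... Unused.
#' @return A tibble: `objective`, `sigma2`, `beta`, `n`, `n_iter`,
#'   `converged`.
#' @method glance beta_em_fit
#' @export
glance.beta_em_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, sigma2 = x$theta$sigma2,
                 beta = x$beta, n = x$n, n_iter = x$n_iter,
                 converged = x$converged)
}

#' Tidy a cross-validation beta selection
#'
#' @param x A `beta_cv`.
#' @param ... Unused.
#' @return The grid tibble (`beta`, `score`).
#' @method tidy beta_cv
#' @export
tidy.beta_cv <- function(x, ...) x$grid

#' One-row summary of a beta selection
#'
#' @param x A `beta_cv`.
#' @param ... Unused.
#' @return A tibble: `beta_opt`, `K`, `beta0`.
#' @method glance beta_cv
#' @export
glance.beta_cv <- function(x, ...) {
  tibble::tibble(beta_opt = x$beta_opt, K = x$K, beta0 = x$beta0)
}
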