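#' Additive marker codes used for cofactor adjustment
#'
#' Backcross markers are coded `{1, 0}` (QQ/Qq), F2 markers `{1, 0, -1}`
#' (QQ/Qq/qq). Dominance cofactor columns are not used.
#'
#' @param cross A `qtl_cross`.
#' @return An `n x M` numeric matrix with marker column names.
#' @export
marker_codes <- function(cross) {
  if (cross$cross_type == "bc") cross$geno * 1.0 else cross$geno - 1.0
}

#' Forward stepwise cofactor selection by BIC
#'
#' Regresses the phenotype on marker codes, adding at each step the marker
#' that most decreases the BIC, stopping when no candidate improves it or
#' when `max_cofactors` is reached. Markers whose addition makes the design
#' rank-deficient are skipped. The selected markers act as the background-QTL
#' covariates of composite interval mapping.
#'
#' @param cross A `qtl_cross` with phenotype.
#' @param max_cofactors Cap on the number of cofactors; default
#'   `min(10, round(2 sqrt(n) / log(n)))`.
#' @param covariates Optional non-genetic covariate matrix included in every
#'   model.
#' @param trim_outliers If `TRUE`, observations outside the quartile fence
#'   `[Q1 - 3 IQR, Q3 + 3 IQR]` of the phenotype are excluded from the
#'   stepwise regression (the selection only; downstream fits keep all
#'   observations). Least-squares stepwise selection is itself not robust,
#'   so the robust scan path enables this.
#' @return A tibble of class `cofactor_set` with columns `step`, `marker`,
#'   `chrom`, `pos`, `bic` (the BIC after adding the marker), ordered by
#'   selection step. Zero rows when nothing improves the BIC.
#' @export
select_cofactors <- function(cross, max_cofactors = NULL, covariates = NULL,
                             trim_outliers = FALSE) {
  stopifnot(inherits(cross, "qtl_cross"), !is.null(cross$pheno))
  y <- as.numeric(cross$pheno)
  keep <- rep(TRUE, length(y))
  if (trim_outliers) {
    qs <- stats::quantile(y, c(0.25, 0.75))
    iqr <- qs[2] - qs[1]
    keep <- y >= qs[1] - 3 * iqr & y <= qs[2] + 3 * iqr
  }
  y_all <- y
  y <- y[keep]
  n <- length(y)
  if (is.null(max_cofactors)) {
    max_cofactors <- min(10L, max(1L, round(2 * sqrt(n) / log(n))))
  }
  codes_all <- marker_codes(cross)
  codes <- codes_all[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  bic_of <- function(Xm) {
    fit <- stats::lm.fit(Xm, y)
    if (fit$rank < ncol(Xm)) return(NA_real_)
    rss <- sum(fit$residuals^2)
    n * log(rss / n) + (ncol(Xm) + 1) * log(n)
  }
  current_bic <- bic_of(X)
  chosen <- character(0)
  bics <- numeric(0)
  remaining <- colnames(codes)
  while (length(chosen) < max_cofactors && length(remaining) > 0) {
    cand_bic <- vapply(remaining, function(mk) {
      bic_of(cbind(X, codes[, mk]))
    }, numeric(1))
    if (all(is.na(cand_bic))) break
    best <- names(which.min(cand_bic))
    if (cand_bic[best] >= current_bic) break
    current_bic <- cand_bic[best]
    X <- cbind(X, codes[, best])
    chosen <- c(chosen, best)
    bics <- c(bics, current_bic)
    remaining <- setdiff(remaining, best)
  }
  out <- tibble::tibble(step = seq_along(chosen), marker = chosen) |>
    dplyr::left_join(cross$map, by = "marker") |>
    dplyr::mutate(bic = bics[.data$step] %||% numeric(0)) |>
    dplyr::select("step", "marker", "chrom", "pos", "bic")
  class(out) <- c("cofactor_set", class(tibble::tibble()))
  out
}

# cofactor markers retained at a test position: everything except cofactors
# within `window` cM of the position on the same chromosome
included_cofactors <- function(cofactors, chrom, pos, window) {
  if (is.null(cofactors) || nrow(cofactors) == 0) return(character(0))
  keep <- cofactors$chrom != as.character(chrom) |
    abs(cofactors$pos - pos) > window
  cofactors$marker[keep]
}

# scan grid: per chromosome, seq(first, last, by = step) plus the last marker
scan_positions <- function(map, step) {
  map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(pos = list(union(seq(min(.data$pos), max(.data$pos),
                                          by = step), max(.data$pos))),
                     .groups = "drop") |>
    tidyr::unnest("pos") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Genome scan by IM, CIM or BetaCIM
#'
#' Walks a cM grid over every chromosome; at each position the conditional
#' QTL-genotype probabilities given the flanking markers form the mixture,
#' the model matrix is intercept + covariates + the additive codes of the
#' cofactors outside the exclusion window, and the (beta-)LOD score compares
#' the beta-likelihood EM fit against the matching null fit. `method = "im"`
#' ignores cofactors and uses `beta = 0`; `"cim"` uses cofactors with
#' `beta = 0`; `"betacim"` uses cofactors with `beta >= 0` (`beta = "auto"`
#' selects it by cross-validation under the null, see [cv_select_beta()]).
#'
#' @param cross A `qtl_cross` with phenotype.
#' @param method `"im"`, `"cim"` or `"betacim"`.
#' @param beta Tuning parameter for `"betacim"`: a number or `"auto"`.
#' @param cofactors A `cofactor_set` (or `NULL`; `"auto"` selects one with
#'   [select_cofactors()]). Ignored for `"im"`.
#' @param step Scan step in cM (default 1).
#' @param window Cofactor exclusion window in cM around the test position
#'   (default 10).
#' @param covariates Optional non-genetic covariate matrix.
#' @param tol,max_iter EM controls.
#' @return A tibble of class `qtl_scan`: `chrom`, `pos`, `lod`, `a`
#'   (estimated additive effect), `d` (F2 only, else `NA`), `method`,
#'   `beta`. Attribute `"beta"` holds the beta actually used and
#'   `"cofactors"` the cofactor set.
#' @export
genome_scan <- function(cross, method = c("betacim", "cim", "im"),
                        beta = NULL, cofactors = NULL, step = 1, window = 10,
                        covariates = NULL, tol = 1e-8, max_iter = 200) {
  method <- match.arg(method)
  stopifnot(inherits(cross, "qtl_cross"), !is.null(cross$pheno))
  y <- as.numeric(cross$pheno)
  if (method == "im") {
    cofactors <- NULL
    beta <- 0
  } else if (method == "cim") {
    beta <- 0
  }
  if (identical(cofactors, "auto")) {
    cofactors <- select_cofactors(cross,
                                  trim_outliers = method == "betacim")
  }
  if (method == "betacim") {
    if (is.null(beta)) beta <- "auto"
    if (identical(beta, "auto")) {
      beta <- select_beta(cross, cofactors = cofactors,
                          covariates = covariates)$beta_opt
    }
    stopifnot(is.numeric(beta), beta >= 0)
  }
  codes <- marker_codes(cross)
  D <- design_matrix(cross$cross_type, 1)
  grid <- scan_positions(cross$map, step)
  null_cache <- new.env(parent = emptyenv())
  fit_one <- function(chrom, pos) {
    inc <- included_cofactors(cofactors, chrom, pos, window)
    X <- cbind(`(Intercept)` = rep(1, length(y)), covariates,
               codes[, inc, drop = FALSE])
    key <- paste0("k:", paste(inc, collapse = ";"))
    null <- get0(key, envir = null_cache)
    if (is.null(null)) {
      null <- beta_null_fit(y, X, beta = beta, tol = tol,
                            max_iter = max_iter)
      assign(key, null, envir = null_cache)
    }
    q <- interval_qtl_probs(cross, chrom, pos)
    alt <- beta_em_fit(y, X, q, D, beta = beta, tol = tol,
                       max_iter = max_iter)
    c(lod = lod_beta(alt, null), a = alt$theta$E[1],
      d = if (cross$cross_type == "f2") alt$theta$E[2] else NA_real_)
  }
  res <- purrr::map2(grid$chrom, grid$pos, function(ch, p) {
    tryCatch(fit_one(ch, p), error = function(e) {
      warning("scan position ", ch, "@", p, " failed: ",
              conditionMessage(e), call. = FALSE)
      c(lod = NA_real_, a = NA_real_, d = NA_real_)
    })
  })
  out <- grid |>
    dplyr::mutate(lod = purrr::map_dbl(res, "lod"),
                  a = purrr::map_dbl(res, "a"),
                  d = purrr::map_dbl(res, "d"),
                  method = method, beta = beta)
  attr(out, "beta") <- beta
  attr(out, "cofactors") <- cofactors
  attr(out, "map") <- cross$map
  class(out) <- c("qtl_scan", class(tibble::tibble()))
  out
}

#' Permutation-based genome-wide LOD threshold
#'
#' Shuffles the phenotype against the genotype rows `n_perm` times, reruns
#' the full genome scan on each permuted dataset, and returns the empirical
#' `1 - alpha` quantile of the genome-wide maximum LOD. The cofactor set and
#' beta are held fixed at the values used for the observed data.
#'
#' @inheritParams genome_scan
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param alpha Genome-wide significance level.
#' @param seed Optional integer seed.
#' @return A list of class `qtl_threshold`: `threshold`, `alpha`, `n_perm`,
#'   `maxima` (the null max-LOD sample), `method`, `beta`.
#' @export
permutation_threshold <- function(cross, method = c("betacim", "cim", "im"),
                                  beta = 0, cofactors = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = NULL, step = 1,
                                  window = 10, covariates = NULL) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1, alpha > 0, alpha <= 1)
  if (!is.null(seed)) set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(p) {
    perm <- cross
    perm$pheno <- sample(as.numeric(cross$pheno))
    sc <- genome_scan(perm, method = method, beta = beta,
                      cofactors = cofactors, step = step, window = window,
                      covariates = covariates)
    max(sc$lod, na.rm = TRUE)
  }, numeric(1))
  structure(list(threshold = stats::quantile(maxima, 1 - alpha, names = FALSE,
                                             type = 7),
                 alpha = alpha, n_perm = n_perm, maxima = maxima,
                 method = method, beta = beta),
            class = "qtl_threshold")
}

#' @export
print.qtl_threshold <- function(x, ...) {
  cat("<qtl_threshold> ", x$method, " genome-wide ",
      format(100 * (1 - x$alpha)), "% threshold = ",
      format(x$threshold, digits = 4), " (", x$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}

#' Call QTL peaks from a scan
#'
#' Grid positions that are local maxima of the LOD profile, exceed the
#' threshold, and are separated by at least one marker interval (the
#' chromosome's median marker spacing); ties are broken towards the lower
#' cM position. Each peak is annotated with its nearest marker.
#'
#' @param scan A `qtl_scan`.
#' @param threshold A number or a `qtl_threshold`.
#' @return A tibble `chrom`, `pos`, `lod`, `marker` (nearest), `marker_pos`.
#' @export
call_peaks <- function(scan, threshold) {
  if (inherits(threshold, "qtl_threshold")) threshold <- threshold$threshold
  map <- attr(scan, "map")
  peaks <- scan |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$lod), .data$lod > threshold) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      mk <- map[map$chrom == key$chrom, ]
      sep <- stats::median(diff(sort(mk$pos)))
      df <- df[order(df$pos), ]
      lodv <- df$lod
      is_max <- lodv >= dplyr::lag(lodv, default = -Inf) &
        lodv >= dplyr::lead(lodv, default = -Inf)
      df <- df[is_max, , drop = FALSE]
      df <- df[order(-df$lod, df$pos), ]
      kept <- df[0, ]
      for (i in seq_len(nrow(df))) {
        if (nrow(kept) == 0 || all(abs(kept$pos - df$pos[i]) >= sep)) {
          kept <- rbind(kept, df[i, ])
        }
      }
      near <- vapply(kept$pos, function(p) which.min(abs(mk$pos - p)),
                     integer(1))
      kept$marker <- mk$marker[near]
      kept$marker_pos <- mk$pos[near]
      kept
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::select("chrom", "pos", "lod", "marker", "marker_pos")
  peaks
}

#' Effect estimates at given positions
#'
#' Fits the single-QTL model at each requested position (with cofactors
#' outside the exclusion window, as in a scan) and returns the estimated
#' genetic effects and LOD score. Used to read off effects at known or
#' detected QTL positions.
#'
#' @inheritParams genome_scan
#' @param at A data frame with columns `chrom` and `pos`.
#' @return A tibble `chrom`, `pos`, `a`, `d`, `lod`, `method`, `beta`.
#' @export
effect_estimates <- function(cross, at, method = c("betacim", "cim", "im"),
                             beta = NULL, cofactors = NULL, window = 10,
                             covariates = NULL, tol = 1e-8, max_iter = 200) {
  method <- match.arg(method)
  y <- as.numeric(cross$pheno)
  if (method == "im") {
    cofactors <- NULL
    beta <- 0
  } else if (method == "cim") beta <- 0
  if (method == "betacim") {
    if (is.null(beta) || identical(beta, "auto")) {
      beta <- select_beta(cross, cofactors = cofactors,
                          covariates = covariates)$beta_opt
    }
  }
  codes <- marker_codes(cross)
  D <- design_matrix(cross$cross_type, 1)
  purrr::pmap_dfr(list(at$chrom, at$pos), function(ch, p) {
    inc <- included_cofactors(cofactors, ch, p, window)
    X <- cbind(`(Intercept)` = rep(1, length(y)), covariates,
               codes[, inc, drop = FALSE])
    q <- interval_qtl_probs(cross, ch, p)
    alt <- beta_em_fit(y, X, q, D, beta = beta, tol = tol,
                       max_iter = max_iter)
    null <- beta_null_fit(y, X, beta = beta, tol = tol, max_iter = max_iter)
    tibble::tibble(chrom = as.character(ch), pos = p, a = alt$theta$E[1],
                   d = if (cross$cross_type == "f2") alt$theta$E[2]
                       else NA_real_,
                   lod = lod_beta(alt, null), method = method, beta = beta)
  })
}
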