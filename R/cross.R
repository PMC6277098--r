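#' Construct an experimental-cross data object
#'
#' Container for genotypes, phenotype and map of a backcross or F2 intercross.
#' Genotypes are coded `QQ = 1, Qq = 0` for a backcross and
#' `QQ = 2, Qq = 1, qq = 0` for an F2; missing genotypes are not supported.
#'
#' @param cross_type `"bc"` or `"f2"`.
#' @param geno Integer matrix, individuals x markers, column names matching
#'   `map$marker`.
#' @param pheno Numeric phenotype vector (or `NULL` before phenotypes are
#'   simulated or read).
#' @param map A `genetic_map` tibble (see [sim_map()]).
#' @return An object of class `qtl_cross`.
#' @export
qtl_cross <- function(cross_type = c("bc", "f2"), geno, pheno = NULL, map) {
  cross_type <- match.arg(cross_type)
  map <- validate_map(map)
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)) || !identical(colnames(geno), map$marker)) {
    stop("genotype columns must match map markers (same order)", call. = FALSE)
  }
  if (nrow(geno) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (anyNA(geno)) stop("missing genotypes are not supported", call. = FALSE)
  alphabet <- if (cross_type == "bc") c(0L, 1L) else c(0L, 1L, 2L)
  if (!all(geno %in% alphabet)) {
    stop("genotype codes outside the ", cross_type, " alphabet {",
         paste(alphabet, collapse = ","), "}", call. = FALSE)
  }
  if (!is.null(pheno)) {
    pheno <- as.numeric(pheno)
    if (length(pheno) != nrow(geno)) {
      stop("phenotype length does not match number of individuals",
           call. = FALSE)
    }
  }
  structure(list(cross_type = cross_type, geno = geno, pheno = pheno,
                 map = map),
            class = "qtl_cross")
}

#' @export
print.qtl_cross <- function(x, ...) {
  cat("<qtl_cross> ", x$cross_type, " cross: ", nrow(x$geno),
      " individuals, ", ncol(x$geno), " markers on ",
      dplyr::n_distinct(x$map$chrom), " chromosome(s); phenotype ",
      if (is.null(x$pheno)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Simulate genotypes for a backcross or F2 intercross
#'
#' Gametes are generated marker-by-marker along each chromosome: the allele at
#' the first marker follows the cross's segregation ratio and each subsequent
#' allele recombines with the Haldane probability implied by the adjacent
#' marker spacing. Chromosomes are independent and there is no crossover
#' interference. A backcross individual inherits one informative gamete
#' (genotype = allele); an F2 individual sums two independent gametes.
#'
#' @param map A `genetic_map` tibble.
#' @param n Number of individuals.
#' @param cross_type `"bc"` or `"f2"`.
#' @param seed Optional integer seed (sets the global RNG).
#' @return A `qtl_cross` with genotypes only (phenotype `NULL`).
#' @examples
#' cr <- sim_cross(sim_map(1, 2, 10), n = 100, cross_type = "bc", seed = 1)
#' @export
sim_cross <- function(map, n, cross_type = c("bc", "f2"), seed = NULL) {
  cross_type <- match.arg(cross_type)
  map <- validate_map(map)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_gam <- if (cross_type == "bc") 1L else 2L
  chroms <- unique(map$chrom)
  geno <- matrix(0L, nrow = n, ncol = nrow(map),
                 dimnames = list(NULL, map$marker))
  for (ch in chroms) {
    mk <- chrom_markers(map, ch)
    r <- recomb_fraction(diff(mk$pos))
    for (g in seq_len(n_gam)) {
      allele <- matrix(0L, n, nrow(mk))
      allele[, 1] <- stats::rbinom(n, 1L, 0.5)
      for (k in seq_along(r)) {
        flip <- stats::rbinom(n, 1L, r[k])
        allele[, k + 1] <- ifelse(flip == 1L, 1L - allele[, k], allele[, k])
      }
      geno[, mk$marker] <- geno[, mk$marker] + allele
    }
  }
  qtl_cross(cross_type, geno, pheno = NULL, map = map)
}

# genotype of each individual at a QTL position: marker genotype if the
# position is typed, otherwise a draw from the flanking-marker conditional
# distribution (so off-marker QTLs are simulated consistently with the map)
qtl_genotype_at <- function(cross, chrom, pos) {
  mk <- chrom_markers(cross$map, chrom)
  hit <- which(abs(mk$pos - pos) < 1e-8)
  if (length(hit) == 1) {
    return(cross$geno[, mk$marker[hit]])
  }
  if (pos < min(mk$pos) || pos > max(mk$pos)) {
    stop("QTL position ", pos, " off the map of chromosome ", chrom,
         call. = FALSE)
  }
  q <- interval_qtl_probs(cross, chrom, pos)
  codes <- if (cross$cross_type == "bc") c(1L, 0L) else c(2L, 1L, 0L)
  apply(q, 1, function(p) sample(codes, 1L, prob = p))
}

#' Simulate a heritability-scaled phenotype
#'
#' Genetic values are `g_j = sum_i a_i x*_ij + d_i z*_ij` with the standard
#' codings (backcross `x* in {1, 0}`; F2 `x* in {1, 0, -1}`,
#' `z* in {-1/2, 1/2, -1/2}` for QQ/Qq/qq). Residuals are Gaussian with
#' variance `Var(g) (1 - h2) / h2` computed from the *realised* sample
#' variance of `g`, so the per-replicate heritability is exact by
#' construction. QTLs at marker positions use the typed genotype; off-marker
#' QTLs are drawn from the flanking-marker conditional distribution.
#'
#' @param cross A `qtl_cross` (genotypes present).
#' @param qtls A [qtl_spec()] tibble.
#' @param heritability Fraction of phenotypic variance contributed by the
#'   QTLs, in (0, 1).
#' @param seed Optional integer seed.
#' @return The cross with `pheno` filled; the genetic values are stored in
#'   attribute `"genetic_values"` of the phenotype.
#' @export
sim_phenotype <- function(cross, qtls, heritability, seed = NULL) {
  stopifnot(inherits(cross, "qtl_cross"))
  if (heritability <= 0 || heritability >= 1) {
    stop("heritability must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cross$geno)
  g <- numeric(n)
  for (i in seq_len(nrow(qtls))) {
    code <- qtl_genotype_at(cross, qtls$chrom[i], qtls$pos[i])
    if (cross$cross_type == "bc") {
      g <- g + qtls$a[i] * code
    } else {
      xs <- code - 1
      zs <- ifelse(code == 1L, 0.5, -0.5)
      d <- if ("d" %in% names(qtls)) qtls$d[i] else 0
      g <- g + qtls$a[i] * xs + d * zs
    }
  }
  vg <- stats::var(g)
  if (vg <= 0) {
    stop("genetic values have zero variance; check QTL effects", call. = FALSE)
  }
  sigma_e <- sqrt(vg * (1 - heritability) / heritability)
  y <- g + stats::rnorm(n, 0, sigma_e)
  attr(y, "genetic_values") <- g
  cross$pheno <- y
  cross
}

#' Contaminate a phenotype vector with additive outliers
#'
#' Shifts exactly `round(rate * n)` distinct observations by draws from
#' `Normal(shift_mean * s, (shift_sd * s)^2)`, where `s` is the standard
#' deviation of the clean phenotype, emulating gross phenotyping errors. The
#' defaults place the shifted points well beyond the `Q3 + 3 IQR` outlier
#' fence of the clean data.
#'
#' @param y Numeric phenotype vector.
#' @param rate Contamination rate in `[0, 1)`.
#' @param shift_mean,shift_sd Location and spread of the shift, in units of
#'   the clean phenotype SD.
#' @param seed Optional integer seed.
#' @return The contaminated vector, with the shifted indices (sorted) in
#'   attribute `"outliers"`.
#' @examples
#' y <- rnorm(100)
#' yc <- contaminate(y, rate = 0.05, seed = 1)
#' attr(yc, "outliers")
#' @export
contaminate <- function(y, rate, shift_mean = 8, shift_sd = 2, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(y)
  n <- length(y)
  k <- round(rate * n)
  idx <- integer(0)
  if (k > 0) {
    idx <- sort(sample.int(n, k))
    s <- stats::sd(y)
    y[idx] <- y[idx] + stats::rnorm(k, shift_mean * s, shift_sd * s)
  }
  attr(y, "outliers") <- idx
  y
}

#' Contaminate the phenotype of a cross
#'
#' @inheritParams contaminate
#' @param cross A `qtl_cross` with phenotype present.
#' @return The cross with contaminated phenotype; outlier indices in
#'   `attr(cross$pheno, "outliers")`.
#' @export
contaminate_cross <- function(cross, rate, shift_mean = 8, shift_sd = 2,
                              seed = NULL) {
  stopifnot(inherits(cross, "qtl_cross"), !is.null(cross$pheno))
  cross$pheno <- contaminate(cross$pheno, rate, shift_mean, shift_sd, seed)
  cross
}

#' Mean squared error of effect estimates
#'
#' `MSE = (1/p) sum_i (theta_i - hat(theta)_i)^2` over the `p` simulated
#' effects.
#'
#' @param truth,estimate Numeric vectors of equal length.
#' @return A single number.
#' @examples
#' mse(c(1, 1), c(0, 2))
#' @export
mse <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) < 1) {
    stop("truth and estimate must have equal positive length", call. = FALSE)
  }
  mean((truth - estimate)^2)
}

#' Empirical detection power
#'
#' Fraction of replicates whose LOD score at a QTL position exceeds the
#' significance threshold, reported as a percentage.
#'
#' @param lod Per-replicate LOD (or beta-LOD) scores at the position.
#' @param threshold Significance threshold.
#' @return Power in percent (0-100).
#' @export
detection_power <- function(lod, threshold) {
  if (length(lod) == 0) stop("empty LOD vector", call. = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  100 * mean(lod > threshold)
}
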