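#' Haldane recombination fraction
#'
#' `r = (1 - exp(-2 d / 100)) / 2` for a map distance `d` in centimorgans,
#' assuming no crossover interference.
#'
#' @param d_cM Map distance(s) in cM (>= 0).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' recomb_fraction(10) # 0.0906
#' @export
recomb_fraction <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distance must be non-negative", call. = FALSE)
  0.5 * (1 - exp(-2 * d_cM / 100))
}

# per-locus genotype class labels, in fixed model order
genotype_classes <- function(cross_type) {
  if (cross_type == "bc") c("QQ", "Qq") else c("QQ", "Qq", "qq")
}

# joint class table for k loci: first locus varies slowest, matching the
# row order of the genetic design matrix and the column order of joint
# conditional probabilities
joint_classes <- function(cross_type, k) {
  per <- genotype_classes(cross_type)
  grid <- do.call(tidyr::expand_grid,
                  stats::setNames(rep(list(per), k), paste0("q", seq_len(k))))
  # expand_grid varies the last column fastest, as required
  grid
}

#' Genetic design matrix for single- or multi-QTL models
#'
#' Rows index the joint QTL genotype classes (first locus varying slowest;
#' per-locus order QQ, Qq(, qq)), columns the genetic parameters. The
#' single-QTL codings are `[[1], [0]]` for a backcross (additive effect `a`)
#' and `[[1, -1/2], [0, 1/2], [-1, -1/2]]` for an F2 (`a`, `d`). For `k >= 2`
#' backcross QTLs the additive entries are +1/2 (QQ) and -1/2 (Qq), giving the
#' `2^k x k` matrix of the generalized model; an F2 gets `3^k x 2k` with the
#' single-QTL coding per locus. Pairwise epistasis appends elementwise
#' products of the additive main-effect columns.
#'
#' @param cross_type `"bc"` or `"f2"`.
#' @param k_qtl Number of putative QTLs considered jointly (>= 1).
#' @param epistasis `"none"`, `"pairwise"`, or a list of integer pairs of
#'   main-effect column indices whose products are appended.
#' @return A numeric matrix with class-label rownames and parameter colnames;
#'   attributes `cross_type` and `k_qtl`.
#' @examples
#' design_matrix("f2", 1)
#' design_matrix("bc", 3)
#' @export
design_matrix <- function(cross_type = c("bc", "f2"), k_qtl = 1,
                          epistasis = "none") {
  cross_type <- match.arg(cross_type)
  if (k_qtl < 1) stop("k_qtl must be >= 1", call. = FALSE)
  cls <- joint_classes(cross_type, k_qtl)
  if (cross_type == "bc") {
    if (k_qtl == 1) {
      D <- matrix(c(1, 0), ncol = 1, dimnames = list(c("QQ", "Qq"), "a"))
    } else {
      D <- sapply(seq_len(k_qtl), function(i) {
        ifelse(cls[[i]] == "QQ", 0.5, -0.5)
      })
      colnames(D) <- paste0("a", seq_len(k_qtl))
    }
  } else {
    code_a <- c(QQ = 1, Qq = 0, qq = -1)
    code_d <- c(QQ = -0.5, Qq = 0.5, qq = -0.5)
    D <- do.call(cbind, lapply(seq_len(k_qtl), function(i) {
      cbind(code_a[cls[[i]]], code_d[cls[[i]]])
    }))
    colnames(D) <- if (k_qtl == 1) c("a", "d") else
      as.vector(rbind(paste0("a", seq_len(k_qtl)), paste0("d", seq_len(k_qtl))))
  }
  rownames(D) <- apply(as.matrix(cls), 1, paste, collapse = "/")
  add_cols <- grep("^a", colnames(D))
  if (identical(epistasis, "pairwise")) {
    if (k_qtl >= 2) {
      pairs <- utils::combn(add_cols, 2, simplify = FALSE)
      epistasis <- pairs
    } else {
      epistasis <- list()
    }
  }
  if (is.list(epistasis)) {
    for (pr in epistasis) {
      stopifnot(length(pr) == 2, all(pr %in% seq_len(ncol(D))))
      D <- cbind(D, D[, pr[1]] * D[, pr[2]])
      colnames(D)[ncol(D)] <-
        paste(colnames(D)[pr[1]], colnames(D)[pr[2]], sep = ":")
    }
  } else if (!identical(epistasis, "none")) {
    stop("epistasis must be \"none\", \"pairwise\" or a list of column pairs",
         call. = FALSE)
  }
  attr(D, "cross_type") <- cross_type
  attr(D, "k_qtl") <- k_qtl
  D
}

# P(gamete allele pattern at loci L, Q, R): allele 1 carries the P1 allele.
# Under no interference the two sub-interval recombinations are independent.
gamete_pattern_prob <- function(aL, aQ, aR, r1, r2) {
  0.5 * ifelse(aL == aQ, 1 - r1, r1) * ifelse(aQ == aR, 1 - r2, r2)
}

# lookup tables: conditional P(QTL genotype | flanking genotypes)
bc_cond_table <- function(r1, r2) {
  # rows indexed by (gL, gR) in {1,0}^2 -> c(P(QQ), P(Qq))
  out <- array(NA_real_, dim = c(2, 2, 2))
  for (gL in 0:1) for (gR in 0:1) {
    num <- c(gamete_pattern_prob(gL, 1, gR, r1, r2),
             gamete_pattern_prob(gL, 0, gR, r1, r2))
    out[gL + 1, gR + 1, ] <- num / sum(num)
  }
  out
}

f2_cond_table <- function(r1, r2) {
  # indexed by (gL, gR) in {0,1,2}^2 -> c(P(QQ), P(Qq), P(qq)) of summed codes
  out <- array(0, dim = c(3, 3, 3))
  pat <- expand.grid(aL1 = 0:1, aQ1 = 0:1, aR1 = 0:1,
                     aL2 = 0:1, aQ2 = 0:1, aR2 = 0:1)
  p <- gamete_pattern_prob(pat$aL1, pat$aQ1, pat$aR1, r1, r2) *
    gamete_pattern_prob(pat$aL2, pat$aQ2, pat$aR2, r1, r2)
  gL <- pat$aL1 + pat$aL2
  gQ <- pat$aQ1 + pat$aQ2
  gR <- pat$aR1 + pat$aR2
  for (i in seq_len(nrow(pat))) {
    # class index 1 = QQ (code 2), 2 = Qq (code 1), 3 = qq (code 0)
    out[gL[i] + 1, gR[i] + 1, 3 - gQ[i]] <-
      out[gL[i] + 1, gR[i] + 1, 3 - gQ[i]] + p[i]
  }
  for (iL in 1:3) for (iR in 1:3) {
    out[iL, iR, ] <- out[iL, iR, ] / sum(out[iL, iR, ])
  }
  out
}

#' Conditional QTL-genotype probabilities at a test position
#'
#' For every individual, the probability of each QTL genotype class at
#' `pos` on `chrom` given the genotypes of the two flanking markers,
#' computed by exact enumeration of gamete recombination patterns under the
#' Haldane map function (no interference). At a typed marker the rows are
#' unit vectors on the observed genotype. This is the standard interval
#' mapping conditioning (two flanking markers only).
#'
#' @param cross A `qtl_cross`.
#' @param chrom Chromosome identifier.
#' @param pos Test position in cM; must lie within the chromosome's marker
#'   span.
#' @return An `n x m` row-stochastic matrix (`m = 2` for bc, `3` for F2),
#'   columns ordered QQ, Qq(, qq) to match [design_matrix()] rows.
#' @export
interval_qtl_probs <- function(cross, chrom, pos) {
  stopifnot(inherits(cross, "qtl_cross"))
  mk <- chrom_markers(cross$map, chrom)
  m <- if (cross$cross_type == "bc") 2L else 3L
  cls <- genotype_classes(cross$cross_type)
  hit <- which(abs(mk$pos - pos) < 1e-8)
  if (length(hit) == 1) {
    g <- cross$geno[, mk$marker[hit]]
    cls_idx <- if (cross$cross_type == "bc") 2L - g else 3L - g
    q <- matrix(0, nrow = length(g), ncol = m, dimnames = list(NULL, cls))
    q[cbind(seq_along(g), cls_idx)] <- 1
    return(q)
  }
  if (pos < min(mk$pos) || pos > max(mk$pos)) {
    stop("position ", pos, " is off chromosome ", chrom, " (span ",
         min(mk$pos), "-", max(mk$pos), " cM)", call. = FALSE)
  }
  iL <- max(which(mk$pos < pos))
  gL <- cross$geno[, mk$marker[iL]]
  gR <- cross$geno[, mk$marker[iL + 1]]
  r1 <- recomb_fraction(pos - mk$pos[iL])
  r2 <- recomb_fraction(mk$pos[iL + 1] - pos)
  if (cross$cross_type == "bc") {
    tab <- bc_cond_table(r1, r2)
    q <- cbind(tab[cbind(gL + 1, gR + 1, 1)], tab[cbind(gL + 1, gR + 1, 2)])
  } else {
    tab <- f2_cond_table(r1, r2)
    q <- cbind(tab[cbind(gL + 1, gR + 1, 1)],
               tab[cbind(gL + 1, gR + 1, 2)],
               tab[cbind(gL + 1, gR + 1, 3)])
  }
  colnames(q) <- cls
  q
}

#' Joint conditional probabilities for several intervals
#'
#' Under no interference, the conditional distributions of the putative QTL
#' genotypes given their flanking markers are independent, so the joint
#' probabilities are row-wise outer products. Column order is lexicographic
#' over the per-QTL classes with the first QTL varying slowest, matching the
#' row order of [design_matrix()].
#'
#' @param probs_list List of single-interval probability matrices
#'   (all with the same number of rows).
#' @return An `n x prod(m_i)` row-stochastic matrix.
#' @export
joint_qtl_probs <- function(probs_list) {
  stopifnot(is.list(probs_list), length(probs_list) >= 1)
  ns <- vapply(probs_list, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop("all probability matrices must have the same number of rows",
         call. = FALSE)
  }
  Reduce(function(A, B) {
    m1 <- ncol(A); m2 <- ncol(B)
    out <- A[, rep(seq_len(m1), each = m2), drop = FALSE] *
      B[, rep(seq_len(m2), times = m1), drop = FALSE]
    colnames(out) <- paste(rep(colnames(A), each = m2),
                           rep(colnames(B), times = m1), sep = "/")
    out
  }, probs_list)
}
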