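#' Simulation scenario: four unlinked QTLs in a backcross
#'
#' Four chromosomes with fifteen markers at 10 cM spacing; QTLs at markers
#' C1M3, C2M6, C3M4 and C4M4 with additive effects 2.12, -1.23, -1.46 and
#' 1.74; the QTLs contribute half of the phenotypic variance; n = 300.
#'
#' @param n Sample size.
#' @param heritability Fraction of variance explained by the QTLs.
#' @return A list of class `qtl_scenario` with elements `map`, `qtls`,
#'   `cross_type`, `n`, `heritability`.
#' @export
unlinked_qtl_scenario <- function(n = 300, heritability = 0.5) {
  structure(list(
    map = sim_map(4, 15, 10),
    qtls = qtl_spec(chrom = c("1", "2", "3", "4"),
                    pos = c(20, 50, 30, 30),
                    a = c(2.12, -1.23, -1.46, 1.74)),
    cross_type = "bc", n = n, heritability = heritability
  ), class = "qtl_scenario")
}

#' Simulation scenario: ten linked QTLs in a backcross
#'
#' Four chromosomes with sixteen markers at 10 cM spacing; ten QTLs (nine on
#' the first three chromosomes, one on chromosome 4) at positions
#' 20/50/110, 10/50/80, 30/70/130 and 40 cM with effects 0.42, 0.75, 0.58,
#' 1.02, -1.23, -1.26, -0.46, 1.61, 0.88, 0.74; n = 300.
#'
#' @inheritParams unlinked_qtl_scenario
#' @export
linked_qtl_scenario <- function(n = 300, heritability = 0.7) {
  structure(list(
    map = sim_map(4, 16, 10),
    qtls = qtl_spec(
      chrom = c("1", "1", "1", "2", "2", "2", "3", "3", "3", "4"),
      pos = c(20, 50, 110, 10, 50, 80, 30, 70, 130, 40),
      a = c(0.42, 0.75, 0.58, 1.02, -1.23, -1.26, -0.46, 1.61, 0.88, 0.74)),
    cross_type = "bc", n = n, heritability = heritability
  ), class = "qtl_scenario")
}

#' Simulate one replicate of a scenario
#'
#' @param scenario A `qtl_scenario` (or compatible list).
#' @param seed Integer seed for this replicate.
#' @param contamination Contamination rate (0 for clean data).
#' @param shift_mean,shift_sd Contamination magnitude in clean-SD units.
#' @return A `qtl_cross` with phenotype (and outlier indices as attribute
#'   when contaminated).
#' @export
simulate_scenario <- function(scenario, seed = NULL, contamination = 0,
                              shift_mean = 8, shift_sd = 2) {
  if (!is.null(seed)) set.seed(seed)
  cross <- sim_cross(scenario$map, scenario$n, scenario$cross_type)
  cross <- sim_phenotype(cross, scenario$qtls, scenario$heritability)
  if (contamination > 0) {
    cross <- contaminate_cross(cross, contamination, shift_mean, shift_sd)
  }
  cross
}

#' Detection power and effect estimates for the unlinked-QTL design
#'
#' Replicates the unlinked-QTL backcross study: for each replicate the
#' scenario is simulated (optionally contaminated), cofactors are selected
#' by stepwise BIC, BetaCIM's beta is chosen by cross-validation, and the
#' LOD score and additive-effect estimate at each true QTL marker are
#' recorded for the requested methods. Genome-wide 5% thresholds are
#' obtained once per method by permutation on a representative replicate
#' and reused across replicates.
#'
#' @param n_rep Number of replicates.
#' @param contamination Contamination rate (e.g. 0 or 0.05).
#' @param n_perm Permutations for the thresholds.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param methods Subset of `c("im", "cim", "betacim")`.
#' @param step Scan step (cM) used for the permutation scans.
#' @param alpha Genome-wide significance level.
#' @param scenario Scenario object; defaults to [unlinked_qtl_scenario()].
#' @return A list: `summary` (tibble: method, marker, chrom, pos, true
#'   effect, power %, mean/sd of estimates), `thresholds` (per method),
#'   `replicates` (per-replicate records).
#' @export
unlinked_power_study <- function(n_rep = 20, contamination = 0, n_perm = 100,
                                 seed = 1, methods = c("im", "betacim"),
                                 step = 10, alpha = 0.05,
                                 scenario = unlinked_qtl_scenario()) {
  at <- scenario$qtls |>
    dplyr::mutate(marker = paste0("C", .data$chrom, "M", .data$pos / 10 + 1))
  ref <- simulate_scenario(scenario, seed = seed, contamination = contamination)
  ref_cof <- select_cofactors(ref)
  ref_cof_rob <- select_cofactors(ref, trim_outliers = TRUE)
  ref_beta <- select_beta(ref, cofactors = ref_cof_rob, seed = seed)$beta_opt
  thresholds <- purrr::map(stats::setNames(methods, methods), function(m) {
    b <- if (m == "betacim") ref_beta else 0
    cof <- switch(m, im = NULL, cim = ref_cof, betacim = ref_cof_rob)
    permutation_threshold(ref, method = m, beta = b, cofactors = cof,
                          n_perm = n_perm, alpha = alpha, seed = seed,
                          step = step)
  })
  reps <- purrr::map_dfr(seq_len(n_rep), function(r) {
    cross <- simulate_scenario(scenario, seed = seed + r,
                               contamination = contamination)
    cof <- if (any(c("cim") %in% methods)) select_cofactors(cross) else NULL
    cof_rob <- if ("betacim" %in% methods) {
      select_cofactors(cross, trim_outliers = TRUE)
    } else NULL
    beta_r <- if ("betacim" %in% methods) {
      select_beta(cross, cofactors = cof_rob, seed = seed + r)$beta_opt
    } else NA_real_
    purrr::map_dfr(methods, function(m) {
      est <- effect_estimates(
        cross, at, method = m,
        beta = if (m == "betacim") beta_r else 0,
        cofactors = switch(m, im = NULL, cim = cof, betacim = cof_rob))
      est$marker <- at$marker
      est$rep <- r
      est$beta_cv <- beta_r
      est
    })
  })
  summary <- reps |>
    dplyr::left_join(dplyr::select(at, "marker", true_a = "a"),
                     by = "marker") |>
    dplyr::group_by(.data$method, .data$marker, .data$chrom, .data$pos,
                    .data$true_a) |>
    dplyr::summarise(
      power = detection_power(.data$lod,
                              thresholds[[.data$method[1]]]$threshold),
      estimate = mean(.data$a), se = stats::sd(.data$a),
      mean_lod = mean(.data$lod), .groups = "drop")
  list(summary = summary, thresholds = thresholds, replicates = reps,
       n_rep = n_rep, contamination = contamination)
}

#' Effect-estimation MSE for the linked-QTL design
#'
#' For each seed, simulates the linked-QTL backcross design, selects
#' cofactors, and estimates the ten additive effects at the true QTL
#' positions with the requested method (composite-interval-mapping style:
#' one single-QTL fit per position, cofactors outside the exclusion
#' window). Returns the per-seed MSE of the ten estimates and its average.
#'
#' @param n_seeds Number of replicate seeds.
#' @param contamination Contamination rate.
#' @param seed Base seed.
#' @param method `"im"`, `"cim"` or `"betacim"`.
#' @param scenario Defaults to [linked_qtl_scenario()].
#' @param max_cofactors Cofactor cap for the stepwise selection. The dense
#'   ten-QTL architecture needs more background markers than the
#'   conservative scan default, so the cap here is `sqrt(n)` and the BIC
#'   stopping rule decides (it stops near eleven markers in practice).
#' @return A list: `mse` (average over seeds), `per_seed` (tibble),
#'   `estimates` (per-position estimates of the last seed).
#' @export
linked_mse_study <- function(n_seeds = 10, contamination = 0, seed = 1,
                             method = "betacim",
                             scenario = linked_qtl_scenario(),
                             max_cofactors = floor(sqrt(scenario$n))) {
  at <- scenario$qtls
  per_seed <- purrr::map_dfr(seq_len(n_seeds), function(r) {
    cross <- simulate_scenario(scenario, seed = seed + r,
                               contamination = contamination)
    cof <- if (method == "im") NULL else
      select_cofactors(cross, max_cofactors = max_cofactors,
                       trim_outliers = method == "betacim")
    b <- if (method == "betacim") {
      select_beta(cross, cofactors = cof, seed = seed + r)$beta_opt
    } else 0
    est <- effect_estimates(cross, at, method = method, beta = b,
                            cofactors = cof)
    tibble::tibble(rep = r, beta = b, mse = mse(at$a, est$a))
  })
  list(mse = mean(per_seed$mse), per_seed = per_seed, method = method,
       contamination = contamination)
}

#' Distribution of cross-validated beta across simulated datasets
#'
#' Simulates `n_datasets` replicates of the unlinked-QTL design at each
#' contamination rate and records the cross-validated beta, emulating the
#' tuning-parameter study: clean data select beta near the bottom of the
#' grid, and the selected beta rises with the contamination rate.
#'
#' @param n_datasets Replicates per contamination rate.
#' @param rates Contamination rates.
#' @param seed Base seed.
#' @param scenario Defaults to [unlinked_qtl_scenario()].
#' @param ... Passed to [cv_select_beta()] via [select_beta()].
#' @return A tibble `rate`, `rep`, `beta_opt`; summarise for medians.
#' @export
cv_beta_study <- function(n_datasets = 50, rates = c(0, 0.02, 0.05, 0.1, 0.2),
                          seed = 1, scenario = unlinked_qtl_scenario(), ...) {
  purrr::map_dfr(rates, function(rt) {
    purrr::map_dfr(seq_len(n_datasets), function(r) {
      cross <- simulate_scenario(scenario, seed = seed + r,
                                 contamination = rt)
      cv <- select_beta(cross, seed = seed + r, ...)
      tibble::tibble(rate = rt, rep = r, beta_opt = cv$beta_opt)
    })
  })
}
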