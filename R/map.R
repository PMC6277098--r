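#' Simulate an equally spaced genetic map
#'
#' Builds a genetic map with `n_chr` chromosomes, each carrying `n_markers`
#' markers starting at 0 cM and separated by `spacing` cM. Marker names follow
#' the `C<chrom>M<index>` convention used throughout the simulation studies.
#'
#' @param n_chr Number of chromosomes (>= 1).
#' @param n_markers Markers per chromosome (>= 2).
#' @param spacing Marker spacing in centimorgans (> 0).
#'
#' @return A tibble of class `genetic_map` with columns `chrom` (character),
#'   `marker` (character) and `pos` (cM, numeric, 0-based per chromosome).
#' @examples
#' sim_map(4, 15, 10)
#' @export
sim_map <- function(n_chr = 4, n_markers = 15, spacing = 10) {
  if (n_chr < 1 || n_markers < 2 || spacing <= 0) {
    stop("invalid map geometry: need n_chr >= 1, n_markers >= 2, spacing > 0",
         call. = FALSE)
  }
  map <- tidyr::expand_grid(chrom = as.character(seq_len(n_chr)),
                            idx = seq_len(n_markers)) |>
    dplyr::mutate(marker = paste0("C", .data$chrom, "M", .data$idx),
                  pos = (.data$idx - 1) * spacing) |>
    dplyr::select("chrom", "marker", "pos")
  validate_map(map)
}

#' Validate a genetic map tibble
#'
#' Checks marker-position monotonicity and minimum marker counts, and stamps
#' the `genetic_map` class. Positions must be strictly increasing within each
#' chromosome and every chromosome needs at least two markers.
#'
#' @param map A data frame with columns `chrom`, `marker`, `pos`.
#' @return The validated map as a `genetic_map` tibble.
#' @export
validate_map <- function(map) {
  map <- tibble::as_tibble(map)
  stopifnot(all(c("chrom", "marker", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) {
    stop("duplicated marker names in map", call. = FALSE)
  }
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n = dplyr::n(),
                     mono = all(diff(.data$pos) > 0), .groups = "drop") |>
    dplyr::filter(.data$n < 2 | !.data$mono)
  if (nrow(bad) > 0) {
    stop("map invalid on chromosome(s) ",
         paste(bad$chrom, collapse = ", "),
         ": need >= 2 markers and strictly increasing positions",
         call. = FALSE)
  }
  class(map) <- c("genetic_map", class(tibble::tibble()))
  map
}

#' Specify quantitative trait loci for simulation
#'
#' @param chrom Chromosome identifiers (coerced to character).
#' @param pos Positions in cM.
#' @param a Additive effects, in phenotype units.
#' @param d Dominance effects (F2 crosses only; ignored for backcross).
#' @return A tibble of class `qtl_spec` with columns `chrom`, `pos`, `a`, `d`.
#' @examples
#' qtl_spec(chrom = c(1, 2), pos = c(20, 50), a = c(2.12, -1.23))
#' @export
qtl_spec <- function(chrom, pos, a, d = 0) {
  out <- tibble::tibble(chrom = as.character(chrom), pos = pos, a = a, d = d)
  class(out) <- c("qtl_spec", class(tibble::tibble()))
  out
}

# markers of one chromosome, ordered; errors if chromosome absent
chrom_markers <- function(map, chrom) {
  sub <- map[map$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("chromosome '", chrom, "' not in map", call. = FALSE)
  }
  sub[order(sub$pos), , drop = FALSE]
}
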