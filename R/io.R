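#' Read a cross from the qtl-cross CSV dialect
#'
#' Expected layout: row 1 holds the phenotype name followed by marker names;
#' row 2 a blank field followed by chromosome identifiers; row 3 a blank
#' field followed by cM positions; each subsequent row one individual
#' (phenotype value, then genotype codes). Genotype codes are
#' case-insensitive `AA`/`AB`/`BB` or the short forms `A`/`H`/`B`; `AA` is
#' the homozygote of the first parent. Missing genotypes are rejected.
#'
#' @param path File path.
#' @param cross_type `"bc"`, `"f2"` or `NULL` to infer from the observed
#'   code alphabet (any `BB`/`B` implies F2).
#' @return A `qtl_cross`.
#' @export
read_cross_csv <- function(path, cross_type = NULL) {
  rows <- utils::read.csv(path, header = FALSE, colClasses = "character",
                          strip.white = TRUE)
  if (nrow(rows) < 5) stop("cross file too short: ", path, call. = FALSE)
  markers <- as.character(rows[1, -1])
  chroms <- as.character(rows[2, -1])
  pos <- suppressWarnings(as.numeric(rows[3, -1]))
  if (any(is.na(pos))) {
    stop("non-numeric cM position in header row 3", call. = FALSE)
  }
  if (nzchar(rows[2, 1]) || nzchar(rows[3, 1])) {
    stop("rows 2-3 must start with a blank field (one canonical dialect ",
         "is supported)", call. = FALSE)
  }
  map <- validate_map(tibble::tibble(chrom = chroms, marker = markers,
                                     pos = pos))
  body <- rows[-(1:3), , drop = FALSE]
  pheno <- suppressWarnings(as.numeric(body[, 1]))
  if (any(is.na(pheno))) {
    stop("non-numeric phenotype at data row ", which(is.na(pheno))[1],
         call. = FALSE)
  }
  codes <- toupper(as.matrix(body[, -1, drop = FALSE]))
  lut <- c(AA = 2L, AB = 1L, BB = 0L, A = 2L, H = 1L, B = 0L)
  num <- matrix(lut[codes], nrow = nrow(codes))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("unknown or missing genotype code '", codes[bad[1], bad[2]],
         "' at data row ", bad[1], ", marker ", markers[bad[2]],
         call. = FALSE)
  }
  seen_bb <- any(num == 0L)
  if (is.null(cross_type)) cross_type <- if (seen_bb) "f2" else "bc"
  if (cross_type == "bc") {
    if (seen_bb) stop("BB genotypes present but cross_type = \"bc\"",
                      call. = FALSE)
    num <- num - 1L # AA -> 1, AB -> 0
  }
  colnames(num) <- markers
  qtl_cross(cross_type, num, pheno, map)
}

#' Write a cross in the qtl-cross CSV dialect
#'
#' Inverse of [read_cross_csv()]; genotypes are written as `AA`/`AB` (bc) or
#' `AA`/`AB`/`BB` (F2), field order is deterministic (map order).
#'
#' @param cross A `qtl_cross` with phenotype.
#' @param path Output path.
#' @param pheno_name Name for the phenotype column.
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(cross, path, pheno_name = "pheno") {
  stopifnot(inherits(cross, "qtl_cross"), !is.null(cross$pheno))
  geno <- cross$geno
  code <- if (cross$cross_type == "bc") {
    matrix(c("AB", "AA")[geno + 1L], nrow = nrow(geno))
  } else {
    matrix(c("BB", "AB", "AA")[geno + 1L], nrow = nrow(geno))
  }
  hdr1 <- c(pheno_name, cross$map$marker)
  hdr2 <- c("", cross$map$chrom)
  hdr3 <- c("", format(cross$map$pos, trim = TRUE))
  body <- cbind(format(as.numeric(cross$pheno), trim = TRUE), code)
  lines <- apply(rbind(hdr1, hdr2, hdr3, body), 1, paste, collapse = ",")
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome scan (or peaks) as TSV
#'
#' @param x A `qtl_scan` tibble or any data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(x, path) {
  utils::write.table(tibble::as_tibble(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML scenario configuration
#'
#' Fields: `map` (`n_chr`, `n_markers`, `spacing`), `cross_type`,
#' `n_individuals`, `heritability`, `qtls` (list of `chrom`, `pos`, `a`,
#' optional `d`), optional `contamination` (`rate`, `shift_mean`,
#' `shift_sd`), optional `seed` and `replicates`. (The sample-size key is
#' spelled out because bare `n` is a YAML 1.1 boolean.)
#'
#' @param path YAML file path.
#' @return A `qtl_scenario` list (plus `contamination`, `seed`,
#'   `replicates` if present).
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("map", "cross_type", "n_individuals", "heritability", "qtls")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("scenario config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  qt <- purrr::map_dfr(cfg$qtls, function(q) {
    tibble::tibble(chrom = as.character(q$chrom), pos = q$pos, a = q$a,
                   d = q$d %||% 0)
  })
  structure(list(
    map = sim_map(cfg$map$n_chr, cfg$map$n_markers, cfg$map$spacing),
    qtls = qt, cross_type = cfg$cross_type, n = cfg$n_individuals,
    heritability = cfg$heritability,
    contamination = cfg$contamination, seed = cfg$seed,
    replicates = cfg$replicates
  ), class = "qtl_scenario")
}
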