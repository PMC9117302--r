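#' Marker genotype tables
#'
#' The genotype substrate of every stage is a wide tibble: one row per
#' marker with metadata columns `marker_id`, `chrom`, `pos_bp`, followed by
#' one column per line carrying calls coded `"A"` (first parent), `"B"`
#' (second parent), `"H"` (heterozygous) or `NA` (missing). Before phasing
#' ([phase_to_parents()]) the two homozygous codes may be any pair of
#' symbols (e.g. raw ref/alt calls); all curation and analysis stages assume
#' the phased A/B/H coding.
#'
#' @name marker_table
NULL

.meta_cols <- c("marker_id", "chrom", "pos_bp")

#' Line identifiers of a marker table
#' @param geno A marker genotype tibble (see [marker_table]).
#' @return Character vector of line column names.
#' @export
line_ids <- function(geno) {
  setdiff(names(geno), .meta_cols)
}

#' Validate a marker genotype table
#'
#' Checks the column contract and (optionally) that markers are sorted by
#' chromosome and position.
#' @param geno A marker genotype tibble.
#' @param sorted Require genome order?
#' @return `geno`, invisibly.
#' @export
validate_marker_table <- function(geno, sorted = FALSE) {
  if (!all(.meta_cols %in% names(geno))) {
    stop("marker table needs columns ", paste(.meta_cols, collapse = ", "))
  }
  if (length(line_ids(geno)) == 0L) stop("marker table has no line columns")
  if (sorted) {
    o <- order(geno$chrom, geno$pos_bp)
    if (!identical(o, seq_len(nrow(geno)))) {
      stop("markers are not sorted by (chrom, pos_bp); see sort_markers()")
    }
  }
  invisible(geno)
}

#' Sort markers by genome position
#'
#' @param geno A marker genotype tibble.
#' @param layout Optional [genome_layout()] giving chromosome order;
#'   otherwise chromosomes sort alphabetically.
#' @return The sorted tibble.
#' @export
sort_markers <- function(geno, layout = NULL) {
  validate_marker_table(geno)
  if (!is.null(layout)) {
    key <- match(geno$chrom, layout$chrom)
    if (anyNA(key)) stop("markers on chromosomes absent from the layout")
    geno[order(key, geno$pos_bp), ]
  } else {
    geno[order(geno$chrom, geno$pos_bp), ]
  }
}

#' Extract the call matrix of a marker table
#' @param geno A marker genotype tibble.
#' @return Character matrix (markers x lines) with `marker_id` rownames.
#' @export
calls_matrix <- function(geno) {
  m <- as.matrix(geno[, line_ids(geno), drop = FALSE])
  rownames(m) <- geno$marker_id
  m
}

# numeric coding used by compute kernels: A = +1, B = -1, H/missing = 0
score_matrix <- function(geno) {
  cm <- calls_matrix(geno)
  s <- matrix(0, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  s[cm == "A"] <- 1
  s[cm == "B"] <- -1
  s
}

new_marker_table <- function(info, calls) {
  out <- dplyr::bind_cols(tibble::as_tibble(info), tibble::as_tibble(calls))
  validate_marker_table(out)
  out
}

#' Read a genotype matrix from a tab-delimited file
#'
#' Expects columns `marker_id`, `chrom`, `pos_bp` followed by one column per
#' line. Two call dialects are supported: `"ABHU"` (`A`/`B`/`H`, `U` or
#' empty = missing) and `"numeric"` (`0` = A, `2` = B, `1` = H, `NA` =
#' missing).
#'
#' @param path File path.
#' @param dialect Call coding of the file.
#' @return A marker genotype tibble.
#' @export
read_genotypes <- function(path, dialect = c("ABHU", "numeric")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    chrom = readr::col_character(),
    pos_bp = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  calls <- as.matrix(df[, setdiff(names(df), .meta_cols), drop = FALSE])
  if (dialect == "ABHU") {
    calls[calls %in% c("U", "", "NA", ".")] <- NA_character_
  } else {
    rec <- c("0" = "A", "2" = "B", "1" = "H")
    calls <- matrix(rec[calls], nrow(calls), ncol(calls),
                    dimnames = dimnames(calls))
  }
  new_marker_table(df[.meta_cols], calls)
}

#' Write a genotype matrix to a tab-delimited file
#'
#' The inverse of [read_genotypes()]; missing calls are written as `U`.
#' Output is bit-stable for identical input.
#'
#' @param geno A marker genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  validate_marker_table(geno)
  out <- geno
  for (ln in line_ids(out)) {
    v <- out[[ln]]
    v[is.na(v)] <- "U"
    out[[ln]] <- v
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Long-format tab-delimited records: `line`, `trait`, `env`, `value`
#' (optionally `rep` for replicates).
#' @param path File path.
#' @return Tibble of phenotype records.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    line = readr::col_character(),
    trait = readr::col_character(),
    env = readr::col_character(),
    value = readr::col_double(),
    .default = readr::col_guess()
  ), progress = FALSE)
}

#' Write a phenotype table
#' @param pheno Tibble of phenotype records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}
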