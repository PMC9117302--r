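# Fixture builders shared across test files. Everything is generated in
# code; no data files are read.

# wide marker table from a list of per-line call vectors
mk_geno <- function(calls_by_line, chrom = NULL, pos_bp = NULL) {
  n <- length(calls_by_line[[1]])
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos_bp)) pos_bp <- seq_len(n) * 1e6 - 5e5
  out <- tibble::tibble(
    marker_id = paste0("m", seq_len(n)),
    chrom = chrom,
    pos_bp = pos_bp
  )
  for (ln in names(calls_by_line)) out[[ln]] <- calls_by_line[[ln]]
  out
}

# a single-marker table across many lines
mk_one_marker <- function(calls) {
  mk_geno(stats::setNames(as.list(calls), paste0("L", seq_along(calls))))
}

# small clean RIL population reused by several files
small_ril <- function(seed = 8, n_lines = 100, n_chrom = 2,
                      length_mbp = 100, spacing = 2, generation = 6,
                      ...) {
  lay <- toy_layout(n_chrom, length_mbp)
  simulate_ril(sim_config(lay, n_lines = n_lines, generation = generation,
                          marker_spacing_mbp = spacing, seed = seed, ...))
}

# brute-force window-pair mean of pairwise_r, the oracle for the matrix code
brute_window_r <- function(geno, members_i, members_j, min_informative = 10) {
  cm <- calls_matrix(geno)
  vals <- c()
  for (i in members_i) {
    for (j in members_j) {
      if (i == j) next
      vals <- c(vals, pairwise_r(cm[i, ], cm[j, ], min_informative))
    }
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}
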