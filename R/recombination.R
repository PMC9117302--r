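#' @title Physically scaled recombination matrices and anomaly detection
#' @description
#' The observed recombination rate r between two markers is the fraction of
#' lines carrying discordant homozygous parental calls among lines
#' homozygous and non-missing at both markers. Averaging r over all marker
#' pairs between sliding physical windows gives a genome-by-genome matrix
#' scaled by physical distance rather than marker density; blocks of low r
#' between chromosomes indicate pseudo-linkage (coupled segregation of a
#' translocation heterozygote) and off-pericentromeric low-r blocks within
#' a chromosome indicate recombination suppression (e.g. an inversion).
#' @name recombination_landscape
NULL

#' Pairwise observed recombination rate between two call vectors
#'
#' @param calls_i,calls_j Phased call vectors (`A`/`B`/`H`/`NA`) over the
#'   same lines.
#' @param min_informative Minimum doubly homozygous lines; below it the
#'   value is `NA` rather than a noisy estimate.
#' @return Fraction in `[0, 1]` or `NA`.
#' @export
pairwise_r <- function(calls_i, calls_j, min_informative = 10) {
  use <- calls_i %in% c("A", "B") & calls_j %in% c("A", "B")
  n <- sum(use)
  if (n < min_informative) return(NA_real_)
  sum(calls_i[use] != calls_j[use]) / n
}

# marker-by-marker discordance via score matrix algebra:
# informative count N = |G||G|', discordant D = (N - GG')/2
marker_r_matrix <- function(geno) {
  g <- score_matrix(geno)
  a <- abs(g)
  nmat <- tcrossprod(a)
  d <- (nmat - tcrossprod(g)) / 2
  r <- d / nmat
  list(r = r, n = nmat)
}

window_coords <- function(layout, step) {
  lm <- layout_mbp(layout)
  purrr::map_dfr(seq_len(nrow(lm)), function(i) {
    centers <- seq(lm$start_mbp[i], lm$end_mbp[i], by = step)
    tibble::tibble(chrom = lm$chrom[i], center_mbp = centers)
  })
}

#' Window-pair average recombination matrix
#'
#' Markers are binned into physical windows of `window` Mbp (half left,
#' half right of sliding coordinates spaced `step` Mbp apart); the value
#' for a pair of windows is the mean of [pairwise_r()] over all pairs of
#' distinct markers, one from each window. Windows containing no markers
#' are represented by the markers immediately adjacent on each side, so all
#' uniformly spaced coordinates carry values where data exist. Values above
#' 0.5 (sampling noise or residual phase error) are capped at 0.5 for the
#' display scale; raw values are retained in the `r_raw` matrix.
#'
#' @param geno A curated, phased marker genotype tibble.
#' @param layout A [genome_layout()].
#' @param window Window width in Mbp (default 16).
#' @param step Sliding-coordinate increment in Mbp (default 10).
#' @param min_informative Minimum doubly homozygous lines per marker pair.
#' @param cap Cap values at 0.5?
#' @return A `recomb_matrix` object: list with `coords` (tibble of window
#'   chromosome/centre), symmetric matrices `r`, `r_raw`, `n_pairs`, and
#'   the call parameters.
#' @export
recombination_matrix <- function(geno, layout, window = 16, step = 10,
                                 min_informative = 10, cap = TRUE) {
  validate_marker_table(geno)
  geno <- sort_markers(geno, layout)
  coords <- window_coords(layout, step)
  half <- window / 2
  pos <- locate_positions(layout, geno[, c("chrom", "pos_bp")])
  mbp <- pos$mbp
  mchrom <- pos$chrom

  low_marker <- table(mchrom)
  thin <- setdiff(layout$chrom, names(low_marker)[low_marker >= 2])
  if (length(thin) > 0) {
    message("chromosomes with < 2 markers yield missing rows: ",
            paste(thin, collapse = ", "))
  }

  # window membership (windows x markers), with nearest-flank fallback
  n_w <- nrow(coords)
  n_m <- nrow(geno)
  W <- matrix(0, n_w, n_m)
  for (w in seq_len(n_w)) {
    on_chr <- which(mchrom == coords$chrom[w])
    if (length(on_chr) == 0L) next
    lo <- coords$center_mbp[w] - half
    hi <- coords$center_mbp[w] + half
    inside <- on_chr[mbp[on_chr] >= lo & mbp[on_chr] <= hi]
    if (length(inside) > 0L) {
      W[w, inside] <- 1
    } else {
      below <- on_chr[mbp[on_chr] < lo]
      above <- on_chr[mbp[on_chr] > hi]
      picks <- c(
        if (length(below) > 0L) below[which.max(mbp[below])],
        if (length(above) > 0L) above[which.min(mbp[above])]
      )
      W[w, picks] <- 1
    }
  }

  mr <- marker_r_matrix(geno)
  valid <- mr$n >= min_informative
  rz <- mr$r
  rz[!valid] <- 0
  v <- valid * 1
  num <- W %*% rz %*% t(W)
  den <- W %*% v %*% t(W)
  # remove self-pairs (same marker in both windows)
  vd <- diag(v)
  selfn <- W %*% (vd * t(W))
  selfr <- W %*% (diag(rz) * t(W))
  num <- num - selfr
  den <- den - selfn
  r <- ifelse(den > 0, num / den, NA_real_)
  n_pairs <- den
  r_raw <- r
  if (cap) r <- pmin(r, 0.5)
  dimnames(r) <- dimnames(r_raw) <- dimnames(n_pairs) <-
    list(NULL, NULL)
  structure(
    list(coords = coords, r = r, r_raw = r_raw, n_pairs = n_pairs,
         window = window, step = step, min_informative = min_informative,
         layout = layout),
    class = "recomb_matrix"
  )
}

#' @export
print.recomb_matrix <- function(x, ...) {
  cat("<recomb_matrix> ", nrow(x$coords), " windows (",
      x$window, " Mbp wide, step ", x$step, " Mbp) over ",
      length(unique(x$coords$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

#' Tidy a recombination matrix into long format
#'
#' One row per unordered window pair: `chrom_i`, `center_i_mbp`, `chrom_j`,
#' `center_j_mbp`, `r`, `r_raw`, `n_pairs`.
#' @param x A `recomb_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.recomb_matrix <- function(x, ...) {
  n <- nrow(x$coords)
  idx <- which(upper.tri(x$r, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    chrom_i = x$coords$chrom[idx[, 1]],
    center_i_mbp = x$coords$center_mbp[idx[, 1]],
    chrom_j = x$coords$chrom[idx[, 2]],
    center_j_mbp = x$coords$center_mbp[idx[, 2]],
    r = x$r[idx],
    r_raw = x$r_raw[idx],
    n_pairs = x$n_pairs[idx]
  )
}

#' Export a recombination matrix to long-format TSV
#' @param x A `recomb_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recomb_matrix <- function(x, path) {
  readr::write_tsv(tidy.recomb_matrix(x), path, progress = FALSE)
  invisible(path)
}

#' Detect pseudo-linkage and recombination-suppression anomalies
#'
#' Reports maximal contiguous blocks of window pairs whose average r is at
#' or below `linkage_threshold`. Blocks between different chromosomes are
#' pseudo-linkage calls. Within a chromosome, only pairs of windows
#' separated by at least `min_intra_sep` Mbp are considered (close windows
#' are physically linked by definition), and pairs where both windows fall
#' inside the central `centromere_frac` of the chromosome are masked as
#' expected pericentromeric suppression.
#'
#' @param x A `recomb_matrix`.
#' @param linkage_threshold Maximum mean r of an anomalous block.
#' @param min_block Minimum number of window pairs in a reported block.
#' @param min_intra_sep Minimum centre separation (Mbp) for within-
#'   chromosome pairs.
#' @param centromere_frac Central chromosome fraction treated as expected
#'   suppression.
#' @return Tibble of anomaly calls: `kind`, the bounding regions of both
#'   window dimensions, `mean_r`, `n_window_pairs`, `threshold`.
#' @export
detect_anomalies <- function(x, linkage_threshold = 0.2, min_block = 2,
                             min_intra_sep = 50, centromere_frac = 0.5) {
  coords <- x$coords
  lm <- layout_mbp(x$layout)
  out <- list()
  chroms <- unique(coords$chrom)
  for (a in seq_along(chroms)) {
    for (b in a:length(chroms)) {
      ci <- chroms[a]; cj <- chroms[b]
      wi <- which(coords$chrom == ci)
      wj <- which(coords$chrom == cj)
      sub <- x$r[wi, wj, drop = FALSE]
      low <- !is.na(sub) & sub <= linkage_threshold
      if (ci == cj) {
        sep <- abs(outer(coords$center_mbp[wi], coords$center_mbp[wj], "-"))
        low <- low & sep >= min_intra_sep
        li <- lm[lm$chrom == ci, ]
        clo <- li$start_mbp + (li$n_mbp * (1 - centromere_frac)) / 2
        chi <- li$end_mbp - (li$n_mbp * (1 - centromere_frac)) / 2
        central_i <- coords$center_mbp[wi] >= clo & coords$center_mbp[wi] <= chi
        central_j <- coords$center_mbp[wj] >= clo & coords$center_mbp[wj] <= chi
        low <- low & !outer(central_i, central_j, "&")
        low[lower.tri(low, diag = TRUE)] <- FALSE
      }
      if (!any(low)) next
      comp <- grid_components(low)
      for (cc in comp) {
        if (nrow(cc) < min_block) next
        ri <- coords$center_mbp[wi[cc[, 1]]]
        rj <- coords$center_mbp[wj[cc[, 2]]]
        vals <- sub[cc]
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = if (ci == cj) "intra_chromosome_suppression"
                 else "inter_chromosome_pseudolinkage",
          chrom_i = ci,
          start_i_mbp = max(min(ri) - x$window / 2, 1),
          end_i_mbp = min(max(ri) + x$window / 2,
                          lm$end_mbp[lm$chrom == ci]),
          chrom_j = cj,
          start_j_mbp = max(min(rj) - x$window / 2, 1),
          end_j_mbp = min(max(rj) + x$window / 2,
                          lm$end_mbp[lm$chrom == cj]),
          mean_r = mean(vals),
          n_window_pairs = nrow(cc),
          threshold = linkage_threshold
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      kind = character(), chrom_i = character(), start_i_mbp = numeric(),
      end_i_mbp = numeric(), chrom_j = character(), start_j_mbp = numeric(),
      end_j_mbp = numeric(), mean_r = numeric(), n_window_pairs = integer(),
      threshold = numeric()
    ))
  }
  dplyr::bind_rows(out)
}

# connected components (4-adjacency) of TRUE cells in a logical matrix;
# returns a list of two-column index matrices
grid_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- list()
  nxt <- 0L
  idx <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    cells <- list()
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ci <- cur[1]; cj <- cur[2]
      if (ci < 1L || cj < 1L || ci > nrow(m) || cj > ncol(m)) next
      if (!m[ci, cj] || lab[ci, cj] != 0L) next
      lab[ci, cj] <- nxt
      cells[[length(cells) + 1L]] <- cur
      stack <- c(stack, list(c(ci - 1L, cj), c(ci + 1L, cj),
                             c(ci, cj - 1L), c(ci, cj + 1L)))
    }
    comp[[nxt]] <- do.call(rbind, cells)
  }
  comp
}

#' Segregation-distortion profile
#'
#' Per marker: frequency of the first-parent allele among homozygous calls
#' and an exact two-sided binomial tail probability against the 1:1
#' biparental expectation.
#'
#' @param geno A phased marker genotype tibble.
#' @return Tibble with `marker_id`, `chrom`, `pos_bp`, `n_hom`, `freq_a`,
#'   `p_value`.
#' @export
distortion_profile <- function(geno) {
  validate_marker_table(geno)
  cm <- calls_matrix(geno)
  n_a <- as.numeric(rowSums(cm == "A", na.rm = TRUE))
  n_b <- as.numeric(rowSums(cm == "B", na.rm = TRUE))
  n <- n_a + n_b
  pv <- vapply(seq_along(n), function(i) {
    if (n[i] == 0L) return(NA_real_)
    stats::binom.test(n_a[i], n[i], 0.5)$p.value
  }, numeric(1))
  tibble::tibble(
    marker_id = geno$marker_id,
    chrom = geno$chrom,
    pos_bp = geno$pos_bp,
    n_hom = n,
    freq_a = ifelse(n > 0, n_a / n, NA_real_),
    p_value = pv
  )
}
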