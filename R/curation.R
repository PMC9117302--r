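#' @title Marker curation: filtering, phasing, correction, imputation
#' @description
#' The curation chain mirrors manual curation of sparse biparental genotype
#' matrices: quality filtering, phasing to the mapping parents, detection
#' and correction of reverse-phase and outlier markers via double-crossover
#' counts, and heuristic run-based imputation. Every step appends rows to a
#' curation report retrievable with [curation_report()].
#' @name curation
NULL

add_report <- function(geno, step, ...) {
  vals <- c(...)
  rep0 <- attr(geno, "curation") %||% tibble::tibble(
    step = character(), metric = character(), value = numeric()
  )
  new <- tibble::tibble(step = step, metric = names(vals),
                        value = as.numeric(vals))
  attr(geno, "curation") <- dplyr::bind_rows(rep0, new)
  geno
}

#' Retrieve the curation audit report
#' @param geno A marker genotype tibble that has passed through curation steps.
#' @return Tibble with columns `step`, `metric`, `value`.
#' @export
curation_report <- function(geno) {
  attr(geno, "curation") %||% tibble::tibble(
    step = character(), metric = character(), value = numeric()
  )
}

#' Filter markers on missingness, allele frequency, and heterozygosity
#'
#' Retains markers whose missing-call fraction is at most `max_missing`,
#' whose minor allele frequency (over non-missing calls, heterozygous calls
#' contributing half to each allele) is at least `min_maf`, and whose
#' heterozygous fraction among non-missing calls is at most `max_het`.
#' Boundary values are retained. Markers failing several rules are counted
#' against the first failing rule, in the order missing, MAF, het.
#'
#' @param geno A marker genotype tibble.
#' @param max_missing Maximum missing fraction (default 0.50).
#' @param min_maf Minimum minor allele frequency (default 0.30).
#' @param max_het Maximum heterozygous fraction (default 0.10).
#' @return The filtered tibble, with the report updated.
#' @export
filter_markers <- function(geno, max_missing = 0.50, min_maf = 0.30,
                           max_het = 0.10) {
  validate_marker_table(geno)
  if (nrow(geno) == 0L) stop("empty marker table")
  thr <- c(max_missing, min_maf, max_het)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  cm <- calls_matrix(geno)
  n_lines <- ncol(cm)

  stats <- t(apply(cm, 1L, function(v) {
    miss <- sum(is.na(v))
    v <- v[!is.na(v)]
    nh <- sum(v == "H")
    hom <- v[v != "H"]
    tab <- sort(table(hom), decreasing = TRUE)
    minor <- if (length(tab) >= 2) tab[[2]] else 0
    denom <- length(hom) + nh
    maf <- if (denom > 0) (minor + 0.5 * nh) / denom else 0
    hetf <- if (length(v) > 0) nh / length(v) else 0
    c(miss / n_lines, maf, hetf)
  }))
  fail_miss <- stats[, 1] > max_missing
  fail_maf <- !fail_miss & stats[, 2] < min_maf
  fail_het <- !fail_miss & !fail_maf & stats[, 3] > max_het
  keep <- !(fail_miss | fail_maf | fail_het)

  out <- geno[keep, ]
  attr(out, "curation") <- attr(geno, "curation")
  add_report(out, "filter",
             n_input = nrow(geno),
             n_removed_missing = sum(fail_miss),
             n_removed_maf = sum(fail_maf),
             n_removed_het = sum(fail_het),
             n_retained = sum(keep))
}

#' Phase progeny calls against the two mapping parents
#'
#' Recode progeny calls to `A`/`B` by parental origin using the parents'
#' own genotype columns. Markers where either parent is missing or
#' heterozygous, or where the parents are identical (monomorphic), are
#' dropped as uninformative. Parent columns are removed from the output.
#'
#' @param geno A marker genotype tibble containing the parent columns.
#' @param parent_a,parent_b Line ids of the first and second parent.
#' @return Phased tibble coded `A`/`B`/`H`/`NA`.
#' @export
phase_to_parents <- function(geno, parent_a, parent_b) {
  validate_marker_table(geno)
  lines <- line_ids(geno)
  if (!parent_a %in% lines) stop("unknown parent id: ", parent_a)
  if (!parent_b %in% lines) stop("unknown parent id: ", parent_b)
  pa <- geno[[parent_a]]
  pb <- geno[[parent_b]]
  informative <- !is.na(pa) & !is.na(pb) & pa != "H" & pb != "H" & pa != pb
  kept <- geno[informative, ]
  pa <- pa[informative]
  pb <- pb[informative]
  prog <- setdiff(lines, c(parent_a, parent_b))
  cm <- as.matrix(kept[, prog, drop = FALSE])
  phased <- matrix(NA_character_, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  phased[cm == matrix(pa, nrow(cm), ncol(cm))] <- "A"
  phased[cm == matrix(pb, nrow(cm), ncol(cm))] <- "B"
  phased[cm == "H"] <- "H"
  out <- new_marker_table(kept[.meta_cols], phased)
  attr(out, "curation") <- attr(geno, "curation")
  add_report(out, "phase",
             n_input = nrow(geno),
             n_uninformative_dropped = sum(!informative),
             n_retained = nrow(out))
}

# nearest non-missing homozygous call before/after each marker, per line and
# chromosome; returns list(prev, nxt) of character matrices
flank_calls <- function(cm, chrom) {
  prev <- matrix(NA_character_, nrow(cm), ncol(cm))
  nxt <- matrix(NA_character_, nrow(cm), ncol(cm))
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    sub <- cm[rows, , drop = FALSE]
    n <- length(rows)
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      hom <- which(v == "A" | v == "B")
      if (length(hom) == 0L) next
      idx <- integer(n)
      idx[hom] <- hom
      last <- cummax(idx)                       # last hom at-or-before i
      p <- c(0L, last[-n])                      # strictly before
      prev[rows[p > 0L], j] <- v[p[p > 0L]]
      idx2 <- rep(n + 1L, n)
      idx2[hom] <- hom
      nxt_at <- rev(cummin(rev(idx2)))          # first hom at-or-after i
      q <- c(nxt_at[-1L], n + 1L)               # strictly after
      nxt[rows[q <= n], j] <- v[q[q <= n]]
    }
  }
  list(prev = prev, nxt = nxt)
}

dxo_events <- function(cm, chrom) {
  fl <- flank_calls(cm, chrom)
  hom <- cm == "A" | cm == "B"
  hom[is.na(hom)] <- FALSE
  inf <- !is.na(fl$prev) & !is.na(fl$nxt) & fl$prev == fl$nxt
  ev <- hom & inf & cm != fl$prev
  ev[is.na(ev)] <- FALSE
  list(events = ev, informative = inf & hom, flanks = fl)
}

#' Count double crossovers
#'
#' A double crossover at a marker, within one line, is a homozygous call
#' that differs from both of its nearest non-missing homozygous neighbours
#' on the same chromosome when those neighbours agree with each other.
#' Singleton calls inside otherwise uniform blocks are the dominant error
#' signature of sparse sequencing-based genotypes.
#'
#' @param geno A phased, sorted marker genotype tibble.
#' @param by Return counts per `"marker"` or per `"line"`.
#' @return Tibble of counts (`n_dxo`) with `n_informative` denominators.
#' @export
count_double_crossovers <- function(geno, by = c("marker", "line")) {
  by <- match.arg(by)
  validate_marker_table(geno)
  cm <- calls_matrix(geno)
  d <- dxo_events(cm, geno$chrom)
  if (by == "marker") {
    tibble::tibble(
      marker_id = geno$marker_id,
      chrom = geno$chrom,
      pos_bp = geno$pos_bp,
      n_dxo = as.numeric(rowSums(d$events)),
      n_informative = as.numeric(rowSums(d$informative))
    )
  } else {
    tibble::tibble(
      line = colnames(cm),
      n_dxo = unname(colSums(d$events)),
      n_informative = unname(colSums(d$informative))
    )
  }
}

#' Correct reverse-phase markers and remove outliers
#'
#' A marker is phase-flipped (A and B exchanged) when flipping reduces the
#' double crossovers it contributes by at least `flip_threshold` as a
#' fraction of its informative lines, and removed as an outlier when, in
#' its better phase, its double-crossover rate still exceeds
#' `outlier_rate`. Flips and removals change the flanking context of their
#' neighbours, so the procedure iterates to a fixed point with a bounded
#' pass count; non-convergence is reported, not fatal.
#'
#' @param geno A phased, sorted marker genotype tibble.
#' @param flip_threshold Minimum fractional double-crossover reduction to
#'   flip a marker (default 0.5).
#' @param outlier_rate Maximum tolerated per-marker double-crossover rate
#'   after optimal phasing (default 0.2).
#' @param min_informative Minimum informative lines to judge a marker.
#' @param max_pass Pass bound for the fixed-point iteration.
#' @return Corrected tibble with the report updated.
#' @export
correct_phase_and_outliers <- function(geno, flip_threshold = 0.5,
                                       outlier_rate = 0.2,
                                       min_informative = 4,
                                       max_pass = 10) {
  validate_marker_table(geno)
  cm <- calls_matrix(geno)
  chrom <- geno$chrom
  keep <- rep(TRUE, nrow(cm))
  total_flips <- 0L
  total_removed <- 0L
  converged <- FALSE
  for (pass in seq_len(max_pass)) {
    sub <- cm[keep, , drop = FALSE]
    fl <- flank_calls(sub, chrom[keep])
    hom <- sub == "A" | sub == "B"
    hom[is.na(hom)] <- FALSE
    inf <- hom & !is.na(fl$prev) & !is.na(fl$nxt) & fl$prev == fl$nxt
    mism <- inf & sub != fl$prev
    agree <- inf & sub == fl$prev
    n_inf <- rowSums(inf)
    dxo <- rowSums(mism, na.rm = TRUE)
    dxo_flip <- rowSums(agree, na.rm = TRUE)   # dxo count if A/B were swapped
    scored <- n_inf >= min_informative
    gain <- (dxo - dxo_flip) / pmax(n_inf, 1L)
    to_flip <- scored & gain >= flip_threshold
    if (any(to_flip)) {
      rows <- which(keep)[to_flip]
      block <- cm[rows, , drop = FALSE]
      flipped <- block
      flipped[block == "A"] <- "B"
      flipped[block == "B"] <- "A"
      cm[rows, ] <- flipped
      total_flips <- total_flips + length(rows)
      next
    }
    best_rate <- pmin(dxo, dxo_flip) / pmax(n_inf, 1L)
    to_drop <- scored & best_rate > outlier_rate
    if (any(to_drop)) {
      keep[which(keep)[to_drop]] <- FALSE
      total_removed <- total_removed + sum(to_drop)
      next
    }
    converged <- TRUE
    break
  }
  if (!converged) {
    warning("phase/outlier correction did not reach a fixed point within ",
            max_pass, " passes")
  }
  out <- new_marker_table(geno[keep, .meta_cols], cm[keep, , drop = FALSE])
  attr(out, "curation") <- attr(geno, "curation")
  add_report(out, "correct",
             n_phase_flipped = total_flips,
             n_outliers_removed = total_removed,
             converged = as.numeric(converged))
}

# run-based imputation of a single call vector (one line, one chromosome)
impute_call_vector <- function(v, zone, fix_singletons, fill_same,
                               fill_split, fill_terminal, max_pass = 10L) {
  n <- length(v)
  if (n < 2L) return(v)
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    if (fix_singletons) {
      hom <- which(v == "A" | v == "B")
      if (length(hom) >= 3L) {
        k <- length(hom)
        mid <- hom[2:(k - 1L)]
        lf <- v[hom[1:(k - 2L)]]
        rf <- v[hom[3:k]]
        bad <- lf == rf & v[mid] != lf
        if (any(bad)) {
          v[mid[bad]] <- lf[bad]
          changed <- TRUE
        }
      }
    }
    miss <- is.na(v)
    if (any(miss)) {
      r <- rle(miss)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        s <- starts[k]; e <- ends[k]
        lf <- if (s > 1L) v[s - 1L] else NA_character_
        rf <- if (e < n) v[e + 1L] else NA_character_
        lf_hom <- !is.na(lf) && lf != "H"
        rf_hom <- !is.na(rf) && rf != "H"
        if (lf_hom && rf_hom) {
          if (lf == rf) {
            if (fill_same) { v[s:e] <- lf; changed <- TRUE }
          } else if (fill_split) {
            m <- e - s + 1L
            n_fill <- max((m - zone) %/% 2L, 0L)
            if (n_fill > 0L) {
              v[s:(s + n_fill - 1L)] <- lf
              v[(e - n_fill + 1L):e] <- rf
              changed <- TRUE
            }
          }
        } else if (fill_terminal && xor(lf_hom, rf_hom) && (s == 1L || e == n)) {
          v[s:e] <- if (lf_hom) lf else rf
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  v
}

#' Heuristic run-based genotype imputation
#'
#' Emulates the decisions of manual curation, per line and chromosome:
#' \enumerate{
#'   \item missing runs flanked on both sides by the same homozygous call
#'     become that call;
#'   \item missing runs flanked by different homozygous calls are filled
#'     from each end toward the run centre, leaving a central uncertainty
#'     zone of `zone` markers (or `zone + 1` when parity requires) missing;
#'   \item isolated single homozygous calls contradicting identical
#'     homozygous flanks (residual double crossovers) are set to the
#'     flanking call;
#'   \item heterozygous calls are left untouched.
#' }
#' Runs touching a chromosome end are left missing unless `fill_terminal`.
#' No information crosses a chromosome boundary. Each rule is individually
#' switchable. The procedure is idempotent.
#'
#' @param geno A phased, sorted, corrected marker genotype tibble.
#' @param zone Width (markers) of the central uncertainty zone for runs with
#'   disagreeing flanks.
#' @param fix_singletons,fill_same,fill_split,fill_terminal Rule switches.
#' @return Imputed tibble with the report updated.
#' @export
impute_gbsi <- function(geno, zone = 1L, fix_singletons = TRUE,
                        fill_same = TRUE, fill_split = TRUE,
                        fill_terminal = FALSE) {
  validate_marker_table(geno)
  cm <- calls_matrix(geno)
  n_missing_before <- sum(is.na(cm))
  n_changed <- 0L
  for (ch in unique(geno$chrom)) {
    rows <- which(geno$chrom == ch)
    for (j in seq_len(ncol(cm))) {
      v0 <- cm[rows, j]
      v1 <- impute_call_vector(v0, zone, fix_singletons, fill_same,
                               fill_split, fill_terminal)
      if (!identical(v0, v1)) {
        n_changed <- n_changed + sum(v0 != v1, na.rm = TRUE) +
          sum(is.na(v0) & !is.na(v1))
        cm[rows, j] <- v1
      }
    }
  }
  out <- new_marker_table(geno[.meta_cols], cm)
  attr(out, "curation") <- attr(geno, "curation")
  add_report(out, "impute",
             n_missing_before = n_missing_before,
             n_missing_after = sum(is.na(cm)),
             n_cells_changed = n_changed)
}

#' Run the full curation chain
#'
#' Convenience wrapper: [filter_markers()] (optionally after
#' [phase_to_parents()] when parent ids are given), [sort_markers()],
#' [correct_phase_and_outliers()], [impute_gbsi()].
#'
#' @param geno A marker genotype tibble.
#' @param parent_a,parent_b Optional parent line ids; when given, phasing is
#'   applied after filtering.
#' @param layout Optional [genome_layout()] for chromosome ordering.
#' @param ... Passed on to [filter_markers()].
#' @return Curated tibble with a cumulative report.
#' @export
curate_markers <- function(geno, parent_a = NULL, parent_b = NULL,
                           layout = NULL, ...) {
  out <- filter_markers(geno, ...)
  if (!is.null(parent_a)) {
    out <- phase_to_parents(out, parent_a, parent_b)
  }
  rep0 <- attr(out, "curation")
  out <- sort_markers(out, layout)
  attr(out, "curation") <- rep0
  out <- correct_phase_and_outliers(out)
  impute_gbsi(out)
}
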