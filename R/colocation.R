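#' @title Candidate-gene / QTL co-location statistics
#' @description
#' Given the QTL support intervals for a trait and a set of M candidate
#' gene positions, the chance expectation of observing K or more genes
#' inside the intervals is the binomial tail
#' `P(K >= N) = sum_{k=N}^{M} choose(M, k) p^k (1-p)^(M-k)`, where p is
#' the fraction of the genome the intervals cover. A bootstrap null
#' relaxes the binomial's assumptions (sampling with replacement, uniform
#' gene density, no spacing constraint) by placing M genes on a simulated
#' genome of 1 Mbp units with a gene-density-weighted probability and a
#' minimum separation between genes on a chromosome. All arithmetic is in
#' whole Mbp units.
#' @name colocation
NULL

#' Genome coverage of a set of Mbp intervals
#'
#' Intervals (inclusive on both Mbp endpoints) are optionally widened
#' symmetrically, clipped to their chromosome, and merged where they
#' overlap; coverage is the merged width in Mbp units divided by the total
#' genome size in Mbp units.
#'
#' @param intervals Tibble with `chrom`, `start_mbp`, `end_mbp`.
#' @param layout A [genome_layout()].
#' @param widen Symmetric widening in Mbp applied to each interval before
#'   merging (default 0).
#' @return Fraction of the genome covered.
#' @export
genome_coverage <- function(intervals, layout, widen = 0) {
  if (nrow(intervals) == 0L) return(0)
  units <- covered_units(intervals, layout, widen)
  sum(lengths(units)) / genome_size_mbp(layout)
}

# merged covered Mbp units per chromosome: named list of integer vectors
covered_units <- function(intervals, layout, widen = 0) {
  lm <- layout_mbp(layout)
  bad <- !(intervals$chrom %in% lm$chrom)
  if (any(bad)) stop("interval on unknown chromosome: ",
                     paste(unique(intervals$chrom[bad]), collapse = ", "))
  li <- lm[match(intervals$chrom, lm$chrom), ]
  s <- pmax(intervals$start_mbp - widen, li$start_mbp)
  e <- pmin(intervals$end_mbp + widen, li$end_mbp)
  if (any(intervals$start_mbp > intervals$end_mbp)) {
    stop("interval with start_mbp > end_mbp")
  }
  if (any(intervals$start_mbp < li$start_mbp | intervals$end_mbp > li$end_mbp)) {
    stop("interval outside its chromosome")
  }
  out <- list()
  for (ch in unique(intervals$chrom)) {
    i <- intervals$chrom == ch
    ir <- IRanges::reduce(IRanges::IRanges(start = s[i], end = e[i]))
    out[[ch]] <- as.integer(unlist(Map(seq.int, IRanges::start(ir),
                                       IRanges::end(ir))))
  }
  out
}

#' Exact binomial tail probability for co-location
#'
#' `P(K >= N)` for M genes each falling independently inside the covered
#' fraction p of the genome.
#'
#' @param m Number of candidate genes (M).
#' @param p Genome coverage fraction.
#' @param n Threshold count N (vectorised); `n = 0` gives 1.
#' @return Tail probability.
#' @examples
#' binomial_tail(3, 0.0293, 2)   # 0.0025 at 4 d.p.
#' @export
binomial_tail <- function(m, p, n) {
  if (m < 0 || m != round(m)) stop("m must be a non-negative integer")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (any(n < 0 | n > m)) stop("n must lie in 0..m")
  vapply(n, function(nn) {
    if (nn == 0) 1 else stats::pbinom(nn - 1, size = m, prob = p,
                                      lower.tail = FALSE)
  }, numeric(1))
}

#' Count candidate genes co-locating with QTL intervals
#'
#' A gene co-locates when its Mbp position lies inside any interval
#' (inclusive endpoints); each gene is counted at most once even if several
#' intervals contain it.
#'
#' @param genes Tibble with `name`, `chrom`, `mbp` (or `pos_bp`, converted).
#' @param intervals Tibble with `chrom`, `start_mbp`, `end_mbp`.
#' @return The input `genes` with a logical `in_qtl` column; the total is
#'   `sum(out$in_qtl)`.
#' @export
count_gene_overlaps <- function(genes, intervals) {
  genes <- tibble::as_tibble(genes)
  if (!"mbp" %in% names(genes)) {
    if (!"pos_bp" %in% names(genes)) stop("genes need an mbp or pos_bp column")
    genes$mbp <- as.integer(ceiling(genes$pos_bp / 1e6))
  }
  inside <- vapply(seq_len(nrow(genes)), function(i) {
    any(intervals$chrom == genes$chrom[i] &
          intervals$start_mbp <= genes$mbp[i] &
          intervals$end_mbp >= genes$mbp[i])
  }, logical(1))
  genes$in_qtl <- inside
  genes
}

#' Gene-density placement profile
#'
#' Converts a per-Mbp gene-count table into a normalised placement
#' probability over every Mbp unit of the genome. With `counts = NULL` the
#' profile is uniform.
#'
#' @param layout A [genome_layout()].
#' @param counts Optional tibble `chrom`, `mbp`, `weight` (e.g. gene counts
#'   per unit derived from an annotation).
#' @return Tibble `chrom`, `mbp`, `prob` summing to 1.
#' @export
gene_density_profile <- function(layout, counts = NULL) {
  lm <- layout_mbp(layout)
  grid <- purrr::map_dfr(seq_len(nrow(lm)), function(i) {
    tibble::tibble(chrom = lm$chrom[i],
                   mbp = seq.int(lm$start_mbp[i], lm$end_mbp[i]))
  })
  if (is.null(counts)) {
    grid$prob <- 1 / nrow(grid)
  } else {
    key <- paste(grid$chrom, grid$mbp)
    w <- stats::setNames(counts$weight, paste(counts$chrom, counts$mbp))
    grid$prob <- as.numeric(w[key])
    grid$prob[is.na(grid$prob)] <- 0
    if (any(grid$prob < 0)) stop("density weights must be non-negative")
    tot <- sum(grid$prob)
    if (tot <= 0) stop("density weights sum to zero")
    grid$prob <- grid$prob / tot
  }
  grid
}

#' Bootstrap null for candidate-gene co-location
#'
#' Each replicate places `m` genes sequentially on the 1 Mbp unit grid,
#' drawing units from the density profile and rejecting draws within
#' `min_sep` Mbp of an already accepted gene on the same chromosome (a
#' bounded retry budget per gene; replicates that exhaust it are redrawn
#' and counted in the diagnostics). The co-location count of each
#' replicate against the supplied intervals yields empirical tails
#' `P(K >= N)` for `N = 1..m` with Monte-Carlo standard errors.
#'
#' @param intervals Tibble with `chrom`, `start_mbp`, `end_mbp`.
#' @param m Number of genes to place per replicate.
#' @param layout A [genome_layout()].
#' @param density Optional [gene_density_profile()]; default uniform.
#' @param n_boot Number of bootstrap replicates.
#' @param min_sep Minimum separation (Mbp) between genes on one chromosome
#'   (default 100).
#' @param seed Integer seed.
#' @param widen Interval widening passed to the coverage arithmetic.
#' @param retry_budget Rejection attempts per gene before a replicate is
#'   restarted.
#' @return A `colocation_boot` tibble: `n`, `p_boot`, `se`, `p_binomial`;
#'   attributes carry `n_boot`, `seed`, and the replicate restart count.
#' @export
bootstrap_colocation <- function(intervals, m, layout, density = NULL,
                                 n_boot = 1e5, min_sep = 100, seed = 1,
                                 widen = 0, retry_budget = 1000) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  lm <- layout_mbp(layout)
  if (min_sep > 0) {
    cap <- sum(floor(lm$n_mbp / min_sep) + 1L)
    if (m > cap) stop("separation constraint infeasible: ", m,
                      " genes cannot be placed ", min_sep, " Mbp apart")
  }
  if (is.null(density)) density <- gene_density_profile(layout)
  units <- covered_units(intervals, layout, widen)
  unit_chrom <- density$chrom
  unit_mbp <- density$mbp
  covered <- logical(nrow(density))
  for (ch in names(units)) {
    covered[unit_chrom == ch & unit_mbp %in% units[[ch]]] <- TRUE
  }
  chrom_id <- match(unit_chrom, lm$chrom)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_units <- nrow(density)
  draw <- function(k) {
    sample.int(n_units, k, replace = TRUE, prob = density$prob)
  }

  k_obs <- integer(n_boot)
  n_restart <- 0L
  if (min_sep == 0) {
    # no spacing constraint: fully vectorised placement
    done <- 0L
    block <- 250000L
    while (done < n_boot) {
      nb <- min(block, n_boot - done)
      g <- matrix(draw(m * nb), nrow = m)
      k_obs[done + seq_len(nb)] <- colSums(matrix(covered[g], nrow = m))
      done <- done + nb
    }
  } else {
    # sequential placement, vectorised across replicates: gene j is redrawn
    # only in replicates where it violates the separation constraint
    placed <- matrix(0L, m, n_boot)
    valid_draw <- function(u, prev) {
      same <- prev[chrom_id[prev] == chrom_id[u]]
      length(same) == 0L || all(abs(unit_mbp[same] - unit_mbp[u]) >= min_sep)
    }
    for (j in seq_len(m)) {
      placed[j, ] <- draw(n_boot)
      if (j == 1L) next
      todo <- seq_len(n_boot)
      tries <- 0L
      repeat {
        ok <- vapply(todo, function(t) {
          valid_draw(placed[j, t], placed[seq_len(j - 1L), t])
        }, logical(1))
        todo <- todo[!ok]
        if (length(todo) == 0L || tries >= retry_budget) break
        placed[j, todo] <- draw(length(todo))
        tries <- tries + 1L
      }
      if (length(todo) > 0L) {
        # exhausted budget: restart those replicates from gene 1
        n_restart <- n_restart + length(todo)
        for (t in todo) {
          repeat {
            cand <- draw(m)
            ok <- TRUE
            for (jj in 2:m) {
              u <- cand[jj]
              prev <- cand[seq_len(jj - 1L)]
              same <- prev[chrom_id[prev] == chrom_id[u]]
              if (length(same) > 0L &&
                  any(abs(unit_mbp[same] - unit_mbp[u]) < min_sep)) {
                ok <- FALSE
                break
              }
            }
            if (ok) break
          }
          placed[, t] <- cand
        }
        break
      }
    }
    k_obs <- colSums(matrix(covered[placed], nrow = m))
  }

  p_cov <- genome_coverage(intervals, layout, widen)
  tails <- vapply(seq_len(m), function(nn) mean(k_obs >= nn), numeric(1))
  out <- tibble::tibble(
    n = seq_len(m),
    p_boot = tails,
    se = sqrt(tails * (1 - tails) / n_boot),
    p_binomial = binomial_tail(m, p_cov, seq_len(m))
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "n_restart") <- n_restart
  attr(out, "k_obs_mean") <- mean(k_obs)
  class(out) <- c("colocation_boot", class(out))
  out
}

#' Full co-location test for one trait
#'
#' Combines coverage, observed overlap count, binomial tails, and
#' (optionally) bootstrap tails into one report row set mirroring a
#' per-trait summary table.
#'
#' @param genes Tibble of candidate genes (`name`, `chrom`, `mbp`).
#' @param intervals QTL support intervals for the trait.
#' @param layout A [genome_layout()].
#' @param trait Label.
#' @param widen Interval widening in Mbp.
#' @param n_boot Bootstrap replicates; 0 skips the bootstrap.
#' @param density,min_sep,seed Passed to [bootstrap_colocation()].
#' @return A `colocation_test` object (list with `trait`, `m`, `p`,
#'   `k_obs`, `genes`, and a `tails` tibble).
#' @export
colocation_test <- function(genes, intervals, layout, trait = NA_character_,
                            widen = 0, n_boot = 0, density = NULL,
                            min_sep = 100, seed = 1) {
  genes <- count_gene_overlaps(genes, intervals)
  m <- nrow(genes)
  p <- genome_coverage(intervals, layout, widen)
  k_obs <- sum(genes$in_qtl)
  tails <- tibble::tibble(
    n = seq_len(m),
    p_binomial = binomial_tail(m, p, seq_len(m))
  )
  boot <- NULL
  if (n_boot > 0) {
    boot <- bootstrap_colocation(intervals, m, layout, density = density,
                                 n_boot = n_boot, min_sep = min_sep,
                                 seed = seed, widen = widen)
    tails$p_boot <- boot$p_boot
    tails$se_boot <- boot$se
  }
  structure(
    list(trait = trait, m = m, p = p, k_obs = k_obs,
         genes = genes, tails = tails, boot = boot),
    class = "colocation_test"
  )
}

#' @export
print.colocation_test <- function(x, ...) {
  cat("<colocation_test> trait ", x$trait, ": M = ", x$m,
      ", coverage p = ", signif(x$p, 3), ", observed K = ", x$k_obs, "\n",
      sep = "")
  print(x$tails)
  invisible(x)
}

#' Tidy a co-location test into table rows
#' @param x A `colocation_test`.
#' @param ... Unused.
#' @return Tibble with one row per tail threshold N.
#' @export
tidy.colocation_test <- function(x, ...) {
  out <- x$tails
  out$trait <- x$trait
  out$m <- x$m
  out$p <- x$p
  out$k_obs <- x$k_obs
  out$observed <- out$n == x$k_obs
  dplyr::relocate(out, "trait", "m", "p", "k_obs")
}

#' One-row summary of a co-location test
#' @param x A `colocation_test`.
#' @param ... Unused.
#' @return Tibble with the tail probability at the observed overlap.
#' @export
glance.colocation_test <- function(x, ...) {
  p_at_k <- if (x$k_obs >= 1) x$tails$p_binomial[x$k_obs] else 1
  boot_at_k <- if (!is.null(x$boot) && x$k_obs >= 1) {
    x$tails$p_boot[x$k_obs]
  } else NA_real_
  tibble::tibble(
    trait = x$trait, m = x$m, p = x$p, k_obs = x$k_obs,
    p_binomial = p_at_k, p_boot = boot_at_k
  )
}

#' Read candidate genes from TSV or GFF3
#'
#' TSV columns: `name`, `chrom`, and `mbp` or `pos_bp`. GFF3: gene
#' features; the position is the Mbp unit of the feature midpoint.
#'
#' @param path File path.
#' @return Tibble with `name`, `chrom`, `mbp`.
#' @export
read_genes <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- as.data.frame(S4Vectors::mcols(gr))
    nm <- if ("Name" %in% names(md)) md$Name else
      if ("ID" %in% names(md)) md$ID else as.character(seq_along(gr))
    mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
    return(tibble::tibble(
      name = as.character(nm),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      mbp = as.integer(ceiling(mid / 1e6))
    ))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"mbp" %in% names(df)) df$mbp <- as.integer(ceiling(df$pos_bp / 1e6))
  tibble::tibble(name = as.character(df$name), chrom = as.character(df$chrom),
                 mbp = as.integer(df$mbp))
}
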