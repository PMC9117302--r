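#' @title Single-marker QTL scans with permutation thresholds
#' @description
#' The scan statistic is a variance ratio: at each marker, lines homozygous
#' for either parental allele are split into the two marker classes and
#' `TS = n * ln(RSS_reduced / RSS_full)` compares the least-squares fit
#' with and without the marker-class effect (an optional covariate marker
#' class is present in both models). TS is an approximation of the
#' likelihood-ratio statistic and converts to the familiar LOD scale as
#' `LOD = TS / (2 ln 10)`. Genome-wide significance thresholds come from
#' permutations that reassociate phenotypes with genotypes and record the
#' genome-wide maximum TS (max-T resampling: one permutation of lines is
#' shared by all markers).
#' @name qtl_scan
NULL

#' Prepare per-line trait values
#'
#' Averages replicates within each (line, environment), then averages
#' across the selected environments per line. Selecting a subset of
#' environments reproduces separate-year analyses.
#'
#' @param pheno Phenotype tibble with columns `line`, `trait`, `env`,
#'   `value`.
#' @param trait Trait to extract.
#' @param environments `"means"` (all environments), or a character vector
#'   of environment labels.
#' @param min_env Minimum number of environments a line must have when
#'   averaging (default 1).
#' @return Tibble with columns `line`, `value`, `n_env`.
#' @export
prepare_trait_values <- function(pheno, trait, environments = "means",
                                 min_env = 1) {
  stopifnot(all(c("line", "trait", "env", "value") %in% names(pheno)))
  sub <- dplyr::filter(pheno, .data$trait == !!trait, is.finite(.data$value))
  if (!identical(environments, "means")) {
    sub <- dplyr::filter(sub, .data$env %in% environments)
  }
  if (nrow(sub) == 0L) stop("no phenotype records for trait ", trait)
  out <- sub |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("line", "env")) |>
    dplyr::summarise(value = mean(.data$value), n_env = dplyr::n(),
                     .by = "line") |>
    dplyr::filter(.data$n_env >= min_env)
  tibble::as_tibble(out)
}

#' Convert between the variance-ratio statistic and LOD
#'
#' `LOD = TS / (2 ln 10)`; at LOD 5 the statistic is 23.03.
#' @param ts,lod Numeric vectors.
#' @return Numeric vector.
#' @export
ts_to_lod <- function(ts) {
  if (any(ts < 0, na.rm = TRUE)) stop("ts must be non-negative")
  ts / (2 * log(10))
}

#' @rdname ts_to_lod
#' @export
lod_to_ts <- function(lod) {
  if (any(lod < 0, na.rm = TRUE)) stop("lod must be non-negative")
  lod * 2 * log(10)
}

#' Variance-ratio statistic at a single marker
#'
#' @param genotypes Phased calls (`A`/`B`/`H`/`NA`) for one marker.
#' @param values Numeric phenotype values over the same lines.
#' @param covariate Optional phased calls of a covariate marker; its class
#'   effect is present in both the full and the reduced model.
#' @param min_lines Minimum homozygous, phenotyped lines (default 20).
#' @return TS (non-negative scalar), or `NA` when a marker class is empty
#'   or too few lines remain.
#' @export
single_marker_ts <- function(genotypes, values, covariate = NULL,
                             min_lines = 20) {
  use <- genotypes %in% c("A", "B") & is.finite(values)
  if (!is.null(covariate)) use <- use & covariate %in% c("A", "B")
  n <- sum(use)
  if (n < min_lines) return(NA_real_)
  g <- genotypes[use]
  y <- values[use]
  if (length(unique(g)) < 2L) return(NA_real_)
  if (is.null(covariate)) {
    rss_full <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    rss_red <- sum((y - mean(y))^2)
  } else {
    cv <- covariate[use]
    x_full <- stats::model.matrix(~ cv + g)
    x_red <- stats::model.matrix(~ cv)
    rss_full <- sum(stats::lm.fit(x_full, y)$residuals^2)
    rss_red <- sum(stats::lm.fit(x_red, y)$residuals^2)
  }
  if (rss_full <= .Machine$double.eps * sum(y^2)) {
    stop("zero residual variance at marker; TS undefined")
  }
  max(n * log(rss_red / rss_full), 0)
}

# vectorised scan kernel: G markers x lines in {1,-1,0}; Y lines x k.
# returns TS matrix markers x k with NA where classes empty / n < min_lines
scan_kernel <- function(G, Y, min_lines = 20, min_class = 1) {
  ia <- (G == 1) * 1
  ib <- (G == -1) * 1
  na <- rowSums(ia)
  nb <- rowSums(ib)
  n <- na + nb
  sa <- ia %*% Y
  sb <- ib %*% Y
  s <- sa + sb
  q <- (ia + ib) %*% Y^2
  rss1 <- q - sa^2 / pmax(na, 1) - sb^2 / pmax(nb, 1)
  rss0 <- q - s^2 / pmax(n, 1)
  rss1 <- pmax(rss1, 0)
  ts <- n * log(rss0 / pmax(rss1, .Machine$double.xmin))
  ts[rss1 <= 0] <- Inf
  bad <- n < min_lines | na < min_class | nb < min_class
  ts[bad, ] <- NA_real_
  pmax(ts, 0)
}

#' Genome-wide single-marker scan
#'
#' Computes [single_marker_ts()] at every marker, in genome order. Lines
#' are matched between the genotype table and the value table by line id;
#' a covariate marker, when given, is excluded from being tested against
#' itself.
#'
#' @param geno A curated, phased marker genotype tibble.
#' @param values Output of [prepare_trait_values()] (columns `line`,
#'   `value`), or a named numeric vector.
#' @param covariate Optional `marker_id` used as covariate.
#' @param min_lines Minimum homozygous, phenotyped lines per marker.
#' @param trait,env Labels stored on the profile for reporting.
#' @return A `scan_profile` tibble: per marker `marker_id`, `chrom`,
#'   `pos_bp`, `mbp`, `n`, `mean_a`, `mean_b`, `ts`, `lod`.
#' @export
genome_scan <- function(geno, values, covariate = NULL, min_lines = 20,
                        trait = NA_character_, env = "means") {
  validate_marker_table(geno)
  if (is.data.frame(values)) {
    v <- stats::setNames(values$value, values$line)
  } else {
    v <- values
  }
  lines <- intersect(line_ids(geno), names(v)[is.finite(v)])
  if (length(lines) == 0L) stop("no lines shared between genotypes and values")
  y <- as.numeric(v[lines])
  cm <- calls_matrix(geno)[, lines, drop = FALSE]

  if (is.null(covariate)) {
    g <- matrix(0, nrow(cm), ncol(cm))
    g[cm == "A"] <- 1
    g[cm == "B"] <- -1
    ts <- as.numeric(scan_kernel(g, matrix(y, ncol = 1), min_lines))
  } else {
    if (!covariate %in% geno$marker_id) stop("unknown covariate marker: ", covariate)
    cov_calls <- cm[match(covariate, geno$marker_id), ]
    ts <- vapply(seq_len(nrow(cm)), function(i) {
      if (geno$marker_id[i] == covariate) return(NA_real_)
      tryCatch(
        single_marker_ts(cm[i, ], y, covariate = cov_calls,
                         min_lines = min_lines),
        error = function(e) NA_real_
      )
    }, numeric(1))
  }
  ia <- cm == "A"
  ib <- cm == "B"
  ymat <- matrix(y, nrow(cm), ncol(cm), byrow = TRUE)
  n_a <- rowSums(ia, na.rm = TRUE)
  n_b <- rowSums(ib, na.rm = TRUE)
  mean_a <- rowSums(ymat * ia, na.rm = TRUE) / pmax(n_a, 1)
  mean_b <- rowSums(ymat * ib, na.rm = TRUE) / pmax(n_b, 1)
  out <- tibble::tibble(
    marker_id = geno$marker_id,
    chrom = geno$chrom,
    pos_bp = geno$pos_bp,
    mbp = as.integer(ceiling(geno$pos_bp / 1e6)),
    n = n_a + n_b,
    mean_a = ifelse(n_a > 0, mean_a, NA_real_),
    mean_b = ifelse(n_b > 0, mean_b, NA_real_),
    ts = ts,
    lod = ts_to_lod(ts)
  )
  attr(out, "trait") <- trait
  attr(out, "env") <- env
  attr(out, "covariate") <- covariate
  class(out) <- c("scan_profile", class(out))
  out
}

#' Permutation-derived genome-wide TS thresholds
#'
#' Each permutation shuffles phenotype values across lines (genotypes
#' fixed, one shared permutation for all markers) and records the
#' genome-wide maximum TS; the threshold for level `alpha` is the empirical
#' `1 - alpha` quantile (order statistic) of the permutation maxima.
#'
#' @param geno A curated, phased marker genotype tibble.
#' @param values As in [genome_scan()].
#' @param n_perm Number of permutations (at least 100).
#' @param alphas Genome-wide error levels.
#' @param seed Integer seed; required for reproducibility.
#' @param covariate Optional covariate `marker_id` (slower path).
#' @param min_lines Minimum homozygous, phenotyped lines per marker.
#' @param chunk Permutations per matrix block (memory control).
#' @return A `perm_thresholds` object: tibble of `alpha`, `ts_threshold`,
#'   `lod_threshold`, with the permutation maxima in attribute `maxima`.
#' @export
permutation_thresholds <- function(geno, values, n_perm = 1000,
                                   alphas = c(0.05, 0.01, 0.005, 0.001),
                                   seed = 1, covariate = NULL,
                                   min_lines = 20, chunk = 250) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  validate_marker_table(geno)
  if (is.data.frame(values)) {
    v <- stats::setNames(values$value, values$line)
  } else {
    v <- values
  }
  lines <- intersect(line_ids(geno), names(v)[is.finite(v)])
  y <- as.numeric(v[lines])
  cm <- calls_matrix(geno)[, lines, drop = FALSE]
  n_lines <- length(y)

  maxima <- numeric(n_perm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(covariate)) {
    g <- matrix(0, nrow(cm), ncol(cm))
    g[cm == "A"] <- 1
    g[cm == "B"] <- -1
    done <- 0L
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      ymat <- vapply(seq_len(k), function(i) y[sample.int(n_lines)],
                     numeric(n_lines))
      ts <- scan_kernel(g, ymat, min_lines)
      maxima[done + seq_len(k)] <- apply(ts, 2, max, na.rm = TRUE)
      done <- done + k
    }
  } else {
    cov_calls <- cm[match(covariate, geno$marker_id), ]
    keep <- geno$marker_id != covariate
    for (p in seq_len(n_perm)) {
      yp <- y[sample.int(n_lines)]
      ts <- vapply(which(keep), function(i) {
        tryCatch(single_marker_ts(cm[i, ], yp, covariate = cov_calls,
                                  min_lines = min_lines),
                 error = function(e) NA_real_)
      }, numeric(1))
      maxima[p] <- max(ts, na.rm = TRUE)
    }
  }
  alphas <- sort(alphas, decreasing = TRUE)
  srt <- sort(maxima)
  thr <- srt[pmin(ceiling((1 - alphas) * n_perm), n_perm)]
  out <- tibble::tibble(
    alpha = alphas,
    ts_threshold = thr,
    lod_threshold = ts_to_lod(thr)
  )
  attr(out, "maxima") <- maxima
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("perm_thresholds", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
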