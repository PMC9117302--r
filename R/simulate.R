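#' @title Seeded RIL population simulator
#' @description
#' Simulates biparental recombinant inbred lines by explicit meiosis:
#' starting from the F1, each line is advanced by single-seed descent for
#' `generation - 1` selfing meioses. Per meiosis and chromosome, the
#' crossover count is Poisson with mean equal to the genetic length
#' (Haldane model, no interference) and crossover positions are uniform in
#' bp. Rearrangement heterozygotes recombine only where their pairing
#' allows: inside the declared recombining regions of a translocation, or
#' outside an inverted interval. Gametes carrying unbalanced translocation
#' products (zero or two copies of the translocated segment) survive with
#' configurable probabilities and are otherwise redrawn, which couples the
#' segregation of the two chromosomes (pseudo-linkage) and, under
#' asymmetric survival, distorts allele frequencies toward the carrier
#' parent. Phenotypes are additive QTL effects plus environment and
#' residual noise; data degradation emulates sequencing-based genotyping
#' (missingness, heterozygous calls, miscalls).
#' @name synthetic_data
NULL

#' Translocation specification for the simulator
#'
#' An unbalanced translocation: `donor_chrom[donor_start_bp..donor_end_bp]`
#' resides, in the carrier parent, on `recipient_chrom` at `insertion_bp`.
#' In a heterozygote, crossovers are confined to `recombining_regions`
#' (tibble `chrom`, `start_bp`, `end_bp`: the arms that pair in the meiotic
#' quadrivalent). A gamete inheriting zero copies of the segment
#' (deficiency) survives with probability `survival_def`; one with two
#' copies (duplication) with `survival_dup`. Equal small values give clean
#' pseudo-linkage; `survival_dup > survival_def` additionally distorts
#' allele frequencies toward the carrier.
#'
#' @param donor_chrom,donor_start_bp,donor_end_bp Segment of origin.
#' @param recipient_chrom,insertion_bp Where the carrier parent carries it.
#' @param carrier `"A"` or `"B"`.
#' @param recombining_regions Tibble of regions where the heterozygote
#'   recombines.
#' @param survival_def,survival_dup Survival probabilities in `[0, 1]`.
#' @return A `translocation_spec` list.
#' @export
translocation_spec <- function(donor_chrom, donor_start_bp, donor_end_bp,
                               recipient_chrom, insertion_bp,
                               carrier = "A",
                               recombining_regions,
                               survival_def = 0.05,
                               survival_dup = survival_def) {
  stopifnot(donor_start_bp <= donor_end_bp,
            survival_def >= 0, survival_def <= 1,
            survival_dup >= 0, survival_dup <= 1,
            carrier %in% c("A", "B"))
  structure(
    list(kind = "translocation",
         donor_chrom = donor_chrom, donor_start_bp = donor_start_bp,
         donor_end_bp = donor_end_bp, recipient_chrom = recipient_chrom,
         insertion_bp = insertion_bp, carrier = carrier,
         recombining_regions = tibble::as_tibble(recombining_regions),
         survival_def = survival_def, survival_dup = survival_dup),
    class = "translocation_spec"
  )
}

#' Pericentric inversion specification for the simulator
#'
#' Heterozygotes produce no viable crossovers inside the inverted interval;
#' crossovers drawn there are discarded (single-crossover products in a
#' pericentric inversion are unbalanced and lost).
#'
#' @param chrom Chromosome.
#' @param start_bp,end_bp Inverted interval.
#' @param carrier `"A"` or `"B"`.
#' @return An `inversion_spec` list.
#' @export
inversion_spec <- function(chrom, start_bp, end_bp, carrier = "A") {
  stopifnot(start_bp <= end_bp, carrier %in% c("A", "B"))
  structure(
    list(kind = "inversion", chrom = chrom, start_bp = start_bp,
         end_bp = end_bp, carrier = carrier),
    class = "inversion_spec"
  )
}

#' Simulation configuration
#'
#' @param layout A [genome_layout()].
#' @param n_lines Number of RILs.
#' @param generation Filial generation `k` of an F_k population (so
#'   `k - 1` meioses from the F1; deeper generations mean less residual
#'   heterozygosity).
#' @param marker_spacing_mbp Marker grid spacing; markers sit mid-unit at
#'   uniform spacing on every chromosome. Alternatively supply `positions`.
#' @param positions Optional tibble `chrom`, `pos_bp` of explicit marker
#'   positions (overrides the grid).
#' @param cm_per_mbp Recombination rate; genetic length of a chromosome is
#'   `cm_per_mbp * length_mbp / 100` Morgans.
#' @param rearrangements List of [translocation_spec()] /
#'   [inversion_spec()].
#' @param distortion Optional tibble `chrom`, `pos_bp`, `allele`, `weight`:
#'   gametes carrying `allele` at the region survive with probability
#'   `weight` (others always survive).
#' @param qtls Optional tibble `trait`, `chrom`, `pos_bp`, `effect`
#'   (additive allele effect; A-homozygotes sit at `+effect`, B at
#'   `-effect`) and optionally `h2` (per-QTL variance explained).
#' @param n_env,env_sd Number of environments and between-environment SD.
#' @param resid_sd Residual SD; when any QTL declares `h2`, the residual SD
#'   is derived from the realised genetic variance instead.
#' @param missing_rate,het_rate,miscall_rate Degradation rates in `[0, 1]`.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(layout, n_lines = 200, generation = 6,
                       marker_spacing_mbp = 2, positions = NULL,
                       cm_per_mbp = 1, rearrangements = list(),
                       distortion = NULL, qtls = NULL,
                       n_env = 1, env_sd = 0, resid_sd = 1,
                       missing_rate = 0, het_rate = 0, miscall_rate = 0,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  rates <- c(missing_rate, het_rate, miscall_rate)
  if (any(rates < 0 | rates > 1)) stop("degradation rates must lie in [0, 1]")
  if (generation < 2) stop("generation must be at least 2 (F2)")
  structure(
    list(layout = layout, n_lines = n_lines, generation = generation,
         marker_spacing_mbp = marker_spacing_mbp, positions = positions,
         cm_per_mbp = cm_per_mbp, rearrangements = rearrangements,
         distortion = distortion, qtls = qtls, n_env = n_env,
         env_sd = env_sd, resid_sd = resid_sd,
         missing_rate = missing_rate, het_rate = het_rate,
         miscall_rate = miscall_rate, seed = seed),
    class = "sim_config"
  )
}

sim_marker_map <- function(config) {
  if (!is.null(config$positions)) {
    pos <- tibble::as_tibble(config$positions)
  } else {
    lm <- layout_mbp(config$layout)
    pos <- purrr::map_dfr(seq_len(nrow(lm)), function(i) {
      u <- seq(lm$start_mbp[i], lm$end_mbp[i], by = config$marker_spacing_mbp)
      tibble::tibble(chrom = lm$chrom[i], pos_bp = (u - 0.5) * 1e6)
    })
  }
  pos$marker_id <- paste0(pos$chrom, "_", format(pos$pos_bp, scientific = FALSE,
                                                 trim = TRUE))
  pos[, c("marker_id", "chrom", "pos_bp")]
}

# index of the marker nearest to bp on chromosome ch
nearest_marker <- function(map, ch, bp) {
  i <- which(map$chrom == ch)
  if (length(i) == 0L) stop("no markers on chromosome ", ch)
  i[which.min(abs(map$pos_bp[i] - bp))]
}

# crossover filter for one chromosome of a heterozygous carrier
filter_crossovers <- function(xo, ch, rearrangements) {
  for (sp in rearrangements) {
    if (sp$kind == "inversion" && sp$chrom == ch) {
      xo <- xo[xo < sp$start_bp | xo > sp$end_bp]
    } else if (sp$kind == "translocation") {
      regs <- sp$recombining_regions
      involved <- ch %in% c(sp$donor_chrom, sp$recipient_chrom)
      if (involved) {
        regs <- regs[regs$chrom == ch, , drop = FALSE]
        if (nrow(regs) == 0L) {
          xo <- numeric(0)
        } else {
          keep <- rep(FALSE, length(xo))
          for (k in seq_len(nrow(regs))) {
            keep <- keep | (xo >= regs$start_bp[k] & xo <= regs$end_bp[k])
          }
          xo <- xo[keep]
        }
      }
    }
  }
  xo
}

#' Simulate a RIL population by explicit meiosis
#'
#' @param config A [sim_config()].
#' @return List with `geno` (the fully observed, error-free truth marker
#'   table, calls `A`/`B`/`H`), `map` (marker metadata), `pedigree`
#'   (per-line residual heterozygosity), `qtls` (planted QTLs snapped to
#'   their nearest marker), and the `config`.
#' @export
simulate_ril <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  map <- sim_marker_map(config)
  layout <- config$layout
  lm <- layout_mbp(layout)
  chroms <- lm$chrom
  chr_rows <- lapply(chroms, function(ch) which(map$chrom == ch))
  names(chr_rows) <- chroms
  chr_len <- stats::setNames(layout$end_bp[match(chroms, layout$chrom)] -
                               layout$start_bp[match(chroms, layout$chrom)] + 1,
                             chroms)
  chr_start <- stats::setNames(layout$start_bp[match(chroms, layout$chrom)],
                               chroms)
  morgans <- config$cm_per_mbp * (chr_len / 1e6) / 100

  # anchor markers for rearrangement zygosity / gamete balance checks
  tr_anchors <- lapply(config$rearrangements, function(sp) {
    if (sp$kind == "translocation") {
      list(
        recipient = nearest_marker(map, sp$recipient_chrom, sp$insertion_bp),
        donor = nearest_marker(map, sp$donor_chrom,
                               (sp$donor_start_bp + sp$donor_end_bp) / 2),
        carrier_code = if (sp$carrier == "A") 0L else 1L,
        survival_def = sp$survival_def, survival_dup = sp$survival_dup
      )
    } else {
      list(anchor = nearest_marker(map, sp$chrom,
                                   (sp$start_bp + sp$end_bp) / 2))
    }
  })
  dist_anchors <- NULL
  if (!is.null(config$distortion)) {
    d <- tibble::as_tibble(config$distortion)
    dist_anchors <- lapply(seq_len(nrow(d)), function(i) {
      list(idx = nearest_marker(map, d$chrom[i], d$pos_bp[i]),
           code = if (d$allele[i] == "A") 0L else 1L,
           weight = d$weight[i])
    })
  }

  n_mark <- nrow(map)
  specs <- config$rearrangements

  # per line: advance a single individual from the F1 by selfing
  n_self <- config$generation - 1L
  calls <- matrix(NA_character_, n_mark, config$n_lines)
  het_counts <- integer(config$n_lines)

  gamete_from <- function(h1, h2, active) {
    g <- integer(n_mark)
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      rows <- chr_rows[[ch]]
      if (length(rows) == 0L) next
      nxo <- stats::rpois(1, morgans[ci])
      xo <- if (nxo > 0) {
        stats::runif(nxo, chr_start[ch], chr_start[ch] + chr_len[ch])
      } else numeric(0)
      if (length(active) > 0L && length(xo) > 0L) {
        xo <- filter_crossovers(xo, ch, active)
      }
      start <- sample.int(2L, 1L) - 1L
      if (length(xo) == 0L) {
        g[rows] <- if (start == 0L) h1[rows] else h2[rows]
      } else {
        seg <- findInterval(map$pos_bp[rows], sort(xo))
        strand <- (start + seg) %% 2L
        g[rows] <- ifelse(strand == 0L, h1[rows], h2[rows])
      }
    }
    g
  }

  # heterozygosity anchors per rearrangement index
  het_for <- function(i, h1, h2) {
    a <- tr_anchors[[i]]
    if (specs[[i]]$kind == "translocation") {
      h1[a$recipient] != h2[a$recipient] || h1[a$donor] != h2[a$donor]
    } else {
      h1[a$anchor] != h2[a$anchor]
    }
  }

  draw_gamete <- function(h1, h2, active_idx) {
    active <- specs[active_idx]
    repeat {
      g <- gamete_from(h1, h2, active)
      ok <- TRUE
      for (i in active_idx) {
        if (specs[[i]]$kind != "translocation") next
        a <- tr_anchors[[i]]
        copies <- (g[a$recipient] == a$carrier_code) +
          (g[a$donor] != a$carrier_code)
        if (copies == 2L) {
          if (stats::runif(1) > a$survival_dup) ok <- FALSE
        } else if (copies == 0L) {
          if (stats::runif(1) > a$survival_def) ok <- FALSE
        }
        if (!ok) break
      }
      if (ok && !is.null(dist_anchors)) {
        for (a in dist_anchors) {
          if (g[a$idx] == a$code && stats::runif(1) > a$weight) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) return(g)
    }
  }

  for (l in seq_len(config$n_lines)) {
    h1 <- rep(0L, n_mark)   # F1: one haplotype from each parent
    h2 <- rep(1L, n_mark)
    for (gen in seq_len(n_self)) {
      active_idx <- which(vapply(seq_along(specs), het_for, logical(1),
                                 h1 = h1, h2 = h2))
      g1 <- draw_gamete(h1, h2, active_idx)
      g2 <- draw_gamete(h1, h2, active_idx)
      h1 <- g1
      h2 <- g2
    }
    het <- h1 != h2
    het_counts[l] <- sum(het)
    v <- ifelse(het, "H", ifelse(h1 == 0L, "A", "B"))
    calls[, l] <- v
  }
  colnames(calls) <- sprintf("L%03d", seq_len(config$n_lines))

  geno <- new_marker_table(map, calls)
  qtls <- NULL
  if (!is.null(config$qtls)) {
    q <- tibble::as_tibble(config$qtls)
    q$marker_id <- vapply(seq_len(nrow(q)), function(i) {
      map$marker_id[nearest_marker(map, q$chrom[i], q$pos_bp[i])]
    }, character(1))
    qtls <- q
  }
  list(
    geno = geno,
    map = map,
    pedigree = tibble::tibble(line = colnames(calls),
                              generation = config$generation,
                              n_het_calls = het_counts),
    qtls = qtls,
    config = config
  )
}

#' Simulate phenotypes from planted additive QTLs
#'
#' `value(line, env) = mean + sum(effect * score) + env_effect + residual`
#' with genotype score +1 (A), -1 (B), 0 (H). When a QTL declares `h2`,
#' the residual SD is set from the realised genetic variance so the QTL
#' explains that fraction of the per-observation variance.
#'
#' @param sim Output of [simulate_ril()] (or a truth marker table, with
#'   `qtls` and `config` supplied).
#' @param trait Trait to simulate; defaults to the first in the QTL table.
#'   A trait with no QTL rows yields pure noise (a null trait).
#' @param grand_mean Intercept.
#' @param seed Integer seed for the environment and residual draws;
#'   defaults to an offset of the population seed so that genotype and
#'   phenotype noise use distinct streams.
#' @return A phenotype tibble `line`, `trait`, `env`, `value`; attribute
#'   `truth` records the realised effects and residual SD.
#' @export
simulate_phenotypes <- function(sim, trait = NULL, grand_mean = 50,
                                seed = NULL) {
  config <- sim$config
  if (is.null(seed)) seed <- (config$seed + 1000003) %% .Machine$integer.max
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  geno <- sim$geno
  qtls <- sim$qtls
  if (is.null(trait)) {
    trait <- if (!is.null(qtls) && nrow(qtls) > 0) qtls$trait[1] else "null"
  }
  q <- if (!is.null(qtls)) qtls[qtls$trait == trait, , drop = FALSE] else NULL
  lines <- line_ids(geno)
  n <- length(lines)
  g_val <- rep(0, n)
  if (!is.null(q) && nrow(q) > 0) {
    cm <- calls_matrix(geno)
    for (i in seq_len(nrow(q))) {
      sc <- cm[match(q$marker_id[i], geno$marker_id), ]
      g_val <- g_val + q$effect[i] * (as.numeric(sc == "A") - as.numeric(sc == "B"))
    }
  }
  resid_sd <- config$resid_sd
  if (!is.null(q) && nrow(q) > 0 && "h2" %in% names(q) && any(!is.na(q$h2))) {
    h2 <- sum(q$h2, na.rm = TRUE)
    if (h2 <= 0 || h2 >= 1) stop("requested heritability infeasible")
    var_g <- stats::var(g_val)
    if (var_g <= 0) stop("requested heritability infeasible: no genetic variance")
    resid_sd <- sqrt(var_g * (1 - h2) / h2 - config$env_sd^2)
    if (is.na(resid_sd)) stop("requested heritability infeasible with env_sd")
  }
  env_labels <- sprintf("env%02d", seq_len(config$n_env))
  env_eff <- stats::rnorm(config$n_env, 0, config$env_sd)
  out <- purrr::map_dfr(seq_along(env_labels), function(e) {
    tibble::tibble(
      line = lines,
      trait = trait,
      env = env_labels[e],
      value = grand_mean + g_val + env_eff[e] +
        stats::rnorm(n, 0, resid_sd)
    )
  })
  attr(out, "truth") <- list(qtls = q, resid_sd = resid_sd,
                             genetic_values = stats::setNames(g_val, lines))
  out
}

#' Degrade a truth genotype table into GBS-like observations
#'
#' Independently per cell: with `missing_rate` the call becomes missing;
#' otherwise with `het_rate` it becomes `H`; otherwise with `miscall_rate`
#' a homozygous call flips to the opposite parent. The truth table is left
#' untouched for downstream comparison.
#'
#' @param geno Truth marker table.
#' @param missing_rate,het_rate,miscall_rate Rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return Observed marker table.
#' @export
degrade_calls <- function(geno, missing_rate = 0, het_rate = 0,
                          miscall_rate = 0, seed = 1) {
  rates <- c(missing_rate, het_rate, miscall_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cm <- calls_matrix(geno)
  nc <- length(cm)
  u_miss <- stats::runif(nc) < missing_rate
  u_het <- stats::runif(nc) < het_rate
  u_flip <- stats::runif(nc) < miscall_rate
  out <- cm
  flip <- !u_miss & !u_het & u_flip & (cm == "A" | cm == "B")
  out[flip & cm == "A"] <- "B"
  out[flip & cm == "B"] <- "A"
  out[!u_miss & u_het] <- "H"
  out[u_miss] <- NA_character_
  new_marker_table(geno[.meta_cols], out)
}
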