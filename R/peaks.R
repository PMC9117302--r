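#' Call QTL peaks with fall-off support intervals
#'
#' Per chromosome, iteratively: take the maximum-TS marker exceeding the
#' threshold (ties break to the lowest genomic coordinate); form the
#' heuristic support interval as the contiguous run of informative markers
#' around the peak whose TS stays at or above `falloff` times the peak
#' value; mask the interval plus `exclusion_mbp` on either side; repeat
#' until no marker exceeds the threshold. The allele effect is the full
#' difference between homozygous class means (the effect of homozygous
#' substitution); set `effect_scale = "half"` for the half-difference
#' convention.
#'
#' @param profile A `scan_profile` from [genome_scan()].
#' @param threshold TS threshold: a number, or a `perm_thresholds` object
#'   (combined with `alpha`).
#' @param alpha Level to pick from a `perm_thresholds` object.
#' @param falloff Fraction of the peak TS defining the support interval
#'   (default 0.80, i.e. a 20% fall-off).
#' @param exclusion_mbp Mask width added beyond each declared interval when
#'   searching for further peaks on the same chromosome (default 75).
#' @param population Population label used in QTL names.
#' @param effect_scale `"full"` or `"half"` difference of class means.
#' @return A `qtl_peaks` tibble: `qtl_name`, `trait`, `population`,
#'   `chrom`, `peak_marker`, `peak_mbp`, `peak_ts`, `peak_lod`,
#'   `start_mbp`, `end_mbp`, `high_parent`, `effect`, `ts_threshold`.
#' @export
call_peaks <- function(profile, threshold, alpha = 0.05, falloff = 0.80,
                       exclusion_mbp = 75, population = "pop",
                       effect_scale = c("full", "half")) {
  effect_scale <- match.arg(effect_scale)
  if (inherits(threshold, "perm_thresholds")) {
    i <- match(alpha, threshold$alpha)
    if (is.na(i)) stop("alpha ", alpha, " not present in thresholds")
    thr <- threshold$ts_threshold[i]
  } else {
    thr <- as.numeric(threshold)
  }
  trait <- attr(profile, "trait") %||% NA_character_
  peaks <- list()
  for (ch in unique(profile$chrom)) {
    sub <- profile[profile$chrom == ch & !is.na(profile$ts), ]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$pos_bp), ]
    masked <- rep(FALSE, nrow(sub))
    repeat {
      cand <- which(!masked & sub$ts > thr)
      if (length(cand) == 0L) break
      peak <- cand[which.max(sub$ts[cand])]  # first max = lowest coordinate
      cut <- falloff * sub$ts[peak]
      lo <- peak
      while (lo > 1L && !masked[lo - 1L] && sub$ts[lo - 1L] >= cut) lo <- lo - 1L
      hi <- peak
      while (hi < nrow(sub) && !masked[hi + 1L] && sub$ts[hi + 1L] >= cut) hi <- hi + 1L
      eff <- sub$mean_a[peak] - sub$mean_b[peak]
      if (effect_scale == "half") eff <- eff / 2
      peaks[[length(peaks) + 1L]] <- tibble::tibble(
        qtl_name = paste(trait, population, sub$mbp[peak], sep = "."),
        trait = trait,
        population = population,
        chrom = ch,
        peak_marker = sub$marker_id[peak],
        peak_mbp = sub$mbp[peak],
        peak_ts = sub$ts[peak],
        peak_lod = ts_to_lod(sub$ts[peak]),
        start_mbp = sub$mbp[lo],
        end_mbp = sub$mbp[hi],
        high_parent = ifelse(eff >= 0, "A", "B"),
        effect = abs(eff),
        ts_threshold = thr
      )
      masked <- masked |
        (sub$mbp >= sub$mbp[lo] - exclusion_mbp &
         sub$mbp <= sub$mbp[hi] + exclusion_mbp)
    }
  }
  out <- if (length(peaks) > 0L) dplyr::bind_rows(peaks) else tibble::tibble(
    qtl_name = character(), trait = character(), population = character(),
    chrom = character(), peak_marker = character(), peak_mbp = integer(),
    peak_ts = numeric(), peak_lod = numeric(), start_mbp = integer(),
    end_mbp = integer(), high_parent = character(), effect = numeric(),
    ts_threshold = numeric()
  )
  class(out) <- c("qtl_peaks", class(out))
  out
}

#' Export QTL peaks as a GFF3 track
#'
#' One feature per QTL: `seqid` = chromosome, type `QTL`, start/end = the
#' support interval expanded to bp (`(start_mbp - 1) * 1e6 + 1` to
#' `end_mbp * 1e6`), score = peak LOD, with `ID` of the form
#' `trait.population.peakMbp`.
#'
#' @param peaks A `qtl_peaks` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_qtl_gff <- function(peaks, path) {
  if (nrow(peaks) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(
      start = (peaks$start_mbp - 1) * 1e6 + 1,
      end = peaks$end_mbp * 1e6
    ),
    type = "QTL",
    score = round(peaks$peak_lod, 3),
    ID = peaks$qtl_name,
    Name = peaks$qtl_name,
    trait = peaks$trait,
    population = peaks$population,
    peak_mbp = peaks$peak_mbp,
    effect = peaks$effect,
    high_parent = peaks$high_parent
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read QTL intervals back from a GFF3 track
#'
#' Inverse of [export_qtl_gff()]; also accepts any GFF3 whose features
#' should be interpreted as Mbp intervals.
#'
#' @param path GFF3 file path.
#' @return Tibble with `chrom`, `start_mbp`, `end_mbp` and any `ID`,
#'   `trait`, `population`, `effect` attributes present.
#' @export
read_qtl_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(tibble::tibble(chrom = character(), start_mbp = integer(),
                          end_mbp = integer()))
  }
  md <- as.data.frame(S4Vectors::mcols(gr))
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_mbp = as.integer(ceiling(GenomicRanges::start(gr) / 1e6)),
    end_mbp = as.integer(ceiling(GenomicRanges::end(gr) / 1e6))
  )
  for (col in intersect(c("ID", "trait", "population", "peak_mbp",
                          "effect", "high_parent", "score"), names(md))) {
    out[[col]] <- md[[col]]
  }
  out
}

#' Write peaks to TSV
#' @param peaks A `qtl_peaks` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(peaks, path, progress = FALSE)
  invisible(path)
}
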