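#' Construct a physical genome layout
#'
#' A genome layout is the shared physical-coordinate backbone of every
#' analysis stage: an ordered set of chromosomes with base-pair lengths.
#' Chromosome segments can later be promoted to pseudo-chromosomes with
#' [split_segment()] (e.g. a translocated arm analysed as if it were a
#' separate chromosome) while preserving the original base-pair coordinates.
#'
#' Coordinates are 1-based throughout; megabase units are 1-based ceilings
#' (`ceiling(bp / 1e6)`), so bp 1 is unit 1 and the last bp of an n-Mbp
#' chromosome is unit n.
#'
#' @param chrom Character vector of unique chromosome names, or a data frame
#'   with columns `chrom` and `length_bp`.
#' @param length_bp Integer vector of chromosome lengths in bp (> 0).
#' @return A `genome_layout` tibble with columns `chrom`, `origin`
#'   (the pre-split chromosome a row derives from), `start_bp`, `end_bp`,
#'   and `length_bp`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(100e6, 80e6))
#' @export
genome_layout <- function(chrom, length_bp = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "length_bp") %in% names(df)))
    chrom <- df$chrom
    length_bp <- df$length_bp
  }
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  if (length(chrom) == 0L) stop("layout needs at least one chromosome")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(length_bp) != length(chrom)) stop("chrom and length_bp lengths differ")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("chromosome lengths must be positive")
  }
  out <- tibble::tibble(
    chrom = chrom,
    origin = chrom,
    start_bp = 1,
    end_bp = length_bp,
    length_bp = length_bp
  )
  class(out) <- c("genome_layout", class(out))
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x), " chromosomes, ",
      format(genome_size(x), big.mark = ","), " bp (",
      genome_size_mbp(x), " Mbp units)\n", sep = "")
  NextMethod()
}

#' Total genome size in bp
#'
#' Conserved under [split_segment()].
#' @param layout A [genome_layout()].
#' @return Total size in bp.
#' @export
genome_size <- function(layout) {
  sum(layout$length_bp)
}

#' Total genome size in whole megabase units
#'
#' Each original chromosome contributes `ceiling(length_bp / 1e6)` units;
#' splits do not change the unit count because original coordinates are
#' preserved on pseudo-chromosomes.
#' @param layout A [genome_layout()].
#' @return Integer number of 1 Mbp units.
#' @export
genome_size_mbp <- function(layout) {
  ends <- tapply(layout$end_bp, layout$origin, max)
  sum(ceiling(ends / 1e6))
}

#' Split a chromosome segment into a pseudo-chromosome
#'
#' Positions at or beyond `breakpoint_bp` on `chrom` are reassigned to a new
#' pseudo-chromosome named `new_name`; base-pair coordinates on the new
#' pseudo-chromosome are preserved from the source chromosome, so downstream
#' megabase arithmetic is unchanged. Typical use: analysing a translocated
#' distal segment as if it were a separate chromosome.
#'
#' @param layout A [genome_layout()].
#' @param chrom Name of the (possibly already split) chromosome to divide.
#' @param breakpoint_bp First bp belonging to the new pseudo-chromosome;
#'   must be strictly inside the chromosome segment.
#' @param new_name Name for the new pseudo-chromosome.
#' @return A new `genome_layout`; total size is conserved.
#' @examples
#' lay <- genome_layout("chr1A", 526e6)
#' split_segment(lay, "chr1A", 420017662, "chr1AC")
#' @export
split_segment <- function(layout, chrom, breakpoint_bp, new_name) {
  i <- match(chrom, layout$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  if (new_name %in% layout$chrom) stop("chromosome name already in use: ", new_name)
  row <- layout[i, ]
  if (breakpoint_bp <= row$start_bp || breakpoint_bp > row$end_bp) {
    stop("breakpoint must lie strictly inside ", chrom,
         " (", row$start_bp, "..", row$end_bp, ")")
  }
  left <- row
  left$end_bp <- breakpoint_bp - 1
  left$length_bp <- left$end_bp - left$start_bp + 1
  right <- row
  right$chrom <- new_name
  right$start_bp <- breakpoint_bp
  right$length_bp <- right$end_bp - right$start_bp + 1
  out <- dplyr::bind_rows(
    layout[seq_len(i - 1L), ],
    left, right,
    layout[i + seq_len(nrow(layout) - i), ]
  )
  class(out) <- c("genome_layout", class(out))
  out
}

#' Map physical positions to post-split chromosomes and Mbp units
#'
#' Resolves positions given in original-chromosome coordinates to the owning
#' (possibly pseudo-) chromosome after any splits, together with the 1-based
#' megabase unit `ceiling(bp / 1e6)`.
#'
#' @param layout A [genome_layout()].
#' @param positions Data frame with columns `chrom` (original or post-split
#'   name) and `pos_bp`.
#' @return `positions` with columns `chrom` (post-split owner) and `mbp`
#'   added/replaced; other columns pass through.
#' @export
locate_positions <- function(layout, positions) {
  stopifnot(is.data.frame(positions), all(c("chrom", "pos_bp") %in% names(positions)))
  chrom <- as.character(positions$chrom)
  bp <- positions$pos_bp
  owner <- rep(NA_character_, length(bp))
  for (i in seq_len(nrow(layout))) {
    hit <- (chrom == layout$origin[i] | chrom == layout$chrom[i]) &
      bp >= layout$start_bp[i] & bp <= layout$end_bp[i]
    owner[hit & is.na(owner)] <- layout$chrom[i]
  }
  if (anyNA(owner)) {
    bad <- which(is.na(owner))[1]
    stop("position out of range: ", chrom[bad], ":", bp[bad])
  }
  out <- tibble::as_tibble(positions)
  out$chrom <- owner
  out$mbp <- as.integer(ceiling(bp / 1e6))
  out
}

#' Megabase span of each layout row
#'
#' First and last Mbp units covered by each (possibly split) chromosome row.
#' @param layout A [genome_layout()].
#' @return Tibble with `chrom`, `start_mbp`, `end_mbp`, `n_mbp`.
#' @export
layout_mbp <- function(layout) {
  start_mbp <- as.integer(ceiling(layout$start_bp / 1e6))
  end_mbp <- as.integer(ceiling(layout$end_bp / 1e6))
  tibble::tibble(
    chrom = layout$chrom,
    start_mbp = start_mbp,
    end_mbp = end_mbp,
    n_mbp = end_mbp - start_mbp + 1L
  )
}

#' Read a genome layout from a file
#'
#' Accepts either a two-column tab-delimited file (`chrom`, `length_bp`,
#' header optional) or a GFF3 file whose `##sequence-region` header block
#' declares the chromosomes.
#'
#' @param path File path.
#' @return A [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  first <- readLines(path, n = 50L)
  seqreg <- grep("^##sequence-region", first, value = TRUE)
  if (length(seqreg) > 0) {
    parts <- strsplit(trimws(seqreg), "[ \t]+")
    return(genome_layout(
      chrom = vapply(parts, `[[`, "", 2L),
      length_bp = as.numeric(vapply(parts, `[[`, "", 4L))
    ))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length_bp"),
                          colClasses = "character")
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df$length_bp[1])))) {
    df <- df[-1, , drop = FALSE]  # header row
  }
  genome_layout(df$chrom, as.numeric(df$length_bp))
}

#' Write a genome layout to a two-column tab-delimited file
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(layout[, c("chrom", "length_bp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled hexaploid oat-style genome layout
#'
#' Twenty-one chromosomes named `chr{1..7}{A,C,D}` with synthetic lengths
#' summing to 10,272 Mbp (the cumulative pseudomolecule size used for genome
#' coverage arithmetic). Per-chromosome lengths are package defaults chosen
#' to be realistic in rank and scale, not measured assembly values; supply
#' your own layout for work against a real reference.
#'
#' @return A [genome_layout()] with 21 chromosomes.
#' @export
oat_layout <- function() {
  chrom <- paste0("chr", rep(1:7, each = 3), rep(c("A", "C", "D"), 7))
  mbp <- c(
    526, 470, 450,   # chr1A, chr1C, chr1D
    510, 540, 470,   # chr2*
    470, 535, 430,   # chr3*
    490, 510, 430,   # chr4*
    480, 545, 445,   # chr5*
    495, 550, 420,   # chr6*
    485, 535, 486    # chr7*
  )
  stopifnot(sum(mbp) == 10272)
  genome_layout(chrom, mbp * 1e6)
}

#' Small toy layout for examples and tests
#' @param n_chrom Number of chromosomes.
#' @param length_mbp Length of each chromosome in Mbp.
#' @return A [genome_layout()].
#' @export
toy_layout <- function(n_chrom = 2, length_mbp = 100) {
  genome_layout(paste0("chr", seq_len(n_chrom)),
                rep(length_mbp * 1e6, n_chrom))
}
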