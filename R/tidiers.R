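#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a genome scan profile
#' @param x A `scan_profile`.
#' @param ... Unused.
#' @return A plain tibble with trait/environment label columns added.
#' @export
tidy.scan_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$trait <- attr(x, "trait")
  out$env <- attr(x, "env")
  out
}

#' One-row summary of a genome scan
#' @param x A `scan_profile`.
#' @param ... Unused.
#' @return Tibble with the profile maximum and its location.
#' @export
glance.scan_profile <- function(x, ...) {
  i <- which.max(x$ts)
  tibble::tibble(
    trait = attr(x, "trait"),
    env = attr(x, "env"),
    n_markers = nrow(x),
    n_tested = sum(!is.na(x$ts)),
    max_ts = x$ts[i],
    max_lod = x$lod[i],
    peak_chrom = x$chrom[i],
    peak_mbp = x$mbp[i]
  )
}

#' Tidy permutation thresholds
#' @param x A `perm_thresholds`.
#' @param ... Unused.
#' @return Tibble of `alpha`, `ts_threshold`, `lod_threshold`.
#' @export
tidy.perm_thresholds <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("alpha", "ts_threshold", "lod_threshold")])
}

#' One-row summary of a permutation run
#' @param x A `perm_thresholds`.
#' @param ... Unused.
#' @return Tibble with permutation count, seed, and maxima summary.
#' @export
glance.perm_thresholds <- function(x, ...) {
  mx <- attr(x, "maxima")
  tibble::tibble(
    n_perm = attr(x, "n_perm"),
    seed = attr(x, "seed"),
    median_max_ts = stats::median(mx),
    q95_max_ts = stats::quantile(mx, 0.95, names = FALSE)
  )
}
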