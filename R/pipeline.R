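#' Run the full analysis pipeline from a configuration file
#'
#' Orchestrates curation, recombination landscape, QTL scans with
#' permutation thresholds, peak calling, and candidate-gene co-location
#' from a YAML configuration, writing stage outputs and a run manifest
#' (config snapshot, input digests, seed, output inventory) to `out_dir`.
#' Failure of one trait/environment combination is logged and does not
#' abort the others; the manifest is written last.
#'
#' Configuration fields (paths relative to the config file):
#' \describe{
#'   \item{layout}{genome layout file (required)}
#'   \item{genotypes / phenotypes}{input tables (required unless
#'     `simulate:` is given)}
#'   \item{parents}{optional two parent line ids for phasing}
#'   \item{simulate}{optional [sim_config()] fields; replaces file input}
#'   \item{curation}{[filter_markers()] thresholds}
#'   \item{landscape}{`window`, `step`, `run` (default true)}
#'   \item{scan}{`traits` (default: all), `environments`, `covariate`,
#'     `n_perm`, `alpha`}
#'   \item{peaks}{`falloff`, `exclusion_mbp`, `population`}
#'   \item{colocation}{`genes` path, `n_boot`, `min_sep`, `widen`}
#'   \item{seed}{integer; overridden by the `seed` argument}
#' }
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  base_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config: file not found: ", config)
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  req <- function(field) {
    if (is.null(config[[field]])) stop("config field missing: ", field)
    config[[field]]
  }
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) return(p)
    file.path(base_dir, p)
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  inputs <- character()
  outputs <- character()
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  layout_path <- resolve(req("layout"))
  if (!file.exists(layout_path)) stop("layout: file not found: ", layout_path)
  inputs <- c(inputs, layout_path)
  layout <- read_genome_layout(layout_path)
  log("layout: ", nrow(layout), " chromosomes")

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$layout <- layout
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    if (!is.null(sim_args$qtls)) {
      sim_args$qtls <- dplyr::bind_rows(sim_args$qtls)
    }
    sim <- simulate_ril(do.call(sim_config, sim_args))
    geno <- sim$geno
    pheno <- simulate_phenotypes(sim)
    log("simulated ", length(line_ids(geno)), " lines, ", nrow(geno),
        " markers")
  } else {
    geno_path <- resolve(req("genotypes"))
    pheno_path <- resolve(req("phenotypes"))
    if (!file.exists(geno_path)) stop("genotypes: file not found: ", geno_path)
    if (!file.exists(pheno_path)) stop("phenotypes: file not found: ", pheno_path)
    inputs <- c(inputs, geno_path, pheno_path)
    geno <- read_genotypes(geno_path)
    pheno <- read_phenotypes(pheno_path)
  }

  cur_args <- config$curation %||% list()
  geno <- do.call(filter_markers, c(list(geno), cur_args))
  if (!is.null(config$parents)) {
    geno <- phase_to_parents(geno, config$parents[[1]], config$parents[[2]])
  }
  rep0 <- attr(geno, "curation")
  geno <- sort_markers(geno, layout)
  attr(geno, "curation") <- rep0
  geno <- correct_phase_and_outliers(geno)
  geno <- impute_gbsi(geno)
  log("curation: ", nrow(geno), " markers retained")
  emit(geno, "genotypes_curated.tsv", write_genotypes)
  emit(curation_report(geno), "curation_report.tsv",
       function(x, p) readr::write_tsv(x, p, progress = FALSE))

  land <- config$landscape %||% list()
  anomalies <- NULL
  if (isTRUE(land$run %||% TRUE)) {
    rm <- recombination_matrix(geno, layout,
                               window = land$window %||% 16,
                               step = land$step %||% 10)
    emit(rm, "recombination_matrix.tsv", write_recomb_matrix)
    anomalies <- detect_anomalies(rm)
    emit(anomalies, "anomalies.tsv",
         function(x, p) readr::write_tsv(x, p, progress = FALSE))
    log("landscape: ", nrow(anomalies), " anomaly call(s)")
  }
  emit(distortion_profile(geno), "distortion_profile.tsv",
       function(x, p) readr::write_tsv(x, p, progress = FALSE))

  scan_cfg <- config$scan %||% list()
  traits <- scan_cfg$traits %||% unique(pheno$trait)
  alpha <- scan_cfg$alpha %||% 0.05
  all_peaks <- list()
  for (tr in traits) {
    res <- tryCatch({
      vals <- prepare_trait_values(pheno, tr,
                                   scan_cfg$environments %||% "means")
      prof <- genome_scan(geno, vals, covariate = scan_cfg$covariate,
                          trait = tr)
      thr <- permutation_thresholds(geno, vals,
                                    n_perm = scan_cfg$n_perm %||% 1000,
                                    seed = seed,
                                    covariate = scan_cfg$covariate)
      pk_cfg <- config$peaks %||% list()
      pk <- call_peaks(prof, thr, alpha = alpha,
                       falloff = pk_cfg$falloff %||% 0.80,
                       exclusion_mbp = pk_cfg$exclusion_mbp %||% 75,
                       population = pk_cfg$population %||% "pop")
      emit(tidy(prof), paste0("scan_", tr, ".tsv"),
           function(x, p) readr::write_tsv(x, p, progress = FALSE))
      emit(tidy(thr), paste0("thresholds_", tr, ".tsv"),
           function(x, p) readr::write_tsv(x, p, progress = FALSE))
      log("scan ", tr, ": ", nrow(pk), " peak(s) at alpha ", alpha)
      pk
    }, error = function(e) {
      log("scan ", tr, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) all_peaks[[tr]] <- res
  }
  peaks <- dplyr::bind_rows(all_peaks)
  emit(peaks, "peaks.tsv", write_peaks)
  emit(peaks, "peaks.gff3", export_qtl_gff)

  coloc_cfg <- config$colocation
  if (!is.null(coloc_cfg) && nrow(peaks) > 0) {
    genes_path <- resolve(coloc_cfg$genes)
    if (is.null(genes_path) || !file.exists(genes_path)) {
      stop("colocation.genes: file not found: ", genes_path)
    }
    inputs <- c(inputs, genes_path)
    genes <- read_genes(genes_path)
    coloc <- purrr::map_dfr(unique(peaks$trait), function(tr) {
      iv <- peaks[peaks$trait == tr,
                  c("chrom", "start_mbp", "end_mbp"), drop = FALSE]
      ct <- colocation_test(genes, iv, layout, trait = tr,
                            widen = coloc_cfg$widen %||% 0,
                            n_boot = coloc_cfg$n_boot %||% 0,
                            min_sep = coloc_cfg$min_sep %||% 100,
                            seed = seed)
      tidy(ct)
    })
    emit(coloc, "colocation.tsv",
         function(x, p) readr::write_tsv(x, p, progress = FALSE))
    log("colocation: ", nrow(coloc), " tail rows")
  }

  manifest <- list(
    seed = seed,
    config = config,
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(p) unname(tools::md5sum(p))),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))),
    log = log_lines
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
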