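test_that("identical seeds give byte-identical populations", {
  a <- small_ril(seed = 3, n_lines = 20, n_chrom = 2, length_mbp = 40)
  b <- small_ril(seed = 3, n_lines = 20, n_chrom = 2, length_mbp = 40)
  expect_identical(calls_matrix(a$geno), calls_matrix(b$geno))
  c <- small_ril(seed = 4, n_lines = 20, n_chrom = 2, length_mbp = 40)
  expect_false(identical(calls_matrix(a$geno), calls_matrix(c$geno)))
})

test_that("zero crossover rate yields whole-chromosome parental blocks", {
  sim <- small_ril(seed = 5, n_lines = 30, n_chrom = 3, length_mbp = 50,
                   cm_per_mbp = 0)
  cm <- calls_matrix(sim$geno)
  for (ch in unique(sim$geno$chrom)) {
    sub <- cm[sim$geno$chrom == ch, ]
    expect_true(all(apply(sub, 2, function(v) length(unique(v)) == 1L)))
  }
})

test_that("unlinked chromosomes segregate independently", {
  sim <- small_ril(seed = 6, n_lines = 300, n_chrom = 2, length_mbp = 80,
                   generation = 8)
  mr <- rilqtl:::marker_r_matrix(sim$geno)
  inter <- mr$r[sim$geno$chrom == "chr1", sim$geno$chrom == "chr2"]
  expect_lt(abs(mean(inter) - 0.5), 4 * sqrt(0.25 / 300))
})

test_that("adjacent-marker discordance follows the RIL mapping expectation", {
  # meiotic r for d Morgans (Haldane), accumulated over selfing to near
  # fixation: R = 2r / (1 + 2r)
  sim <- small_ril(seed = 7, n_lines = 500, n_chrom = 1, length_mbp = 100,
                   spacing = 5, generation = 9)
  mr <- rilqtl:::marker_r_matrix(sim$geno)
  n <- nrow(sim$geno)
  adj <- vapply(seq_len(n - 1), function(i) mr$r[i, i + 1], numeric(1))
  r_meio <- 0.5 * (1 - exp(-2 * 0.05))       # 5 Mbp at 1 cM/Mbp
  expected <- 2 * r_meio / (1 + 2 * r_meio)
  expect_lt(abs(mean(adj) - expected), 0.015)
})

test_that("selfing depth controls residual heterozygosity", {
  f3 <- small_ril(seed = 8, n_lines = 200, n_chrom = 1, length_mbp = 60,
                  generation = 3)
  f7 <- small_ril(seed = 8, n_lines = 200, n_chrom = 1, length_mbp = 60,
                  generation = 7)
  h3 <- mean(calls_matrix(f3$geno) == "H")
  h7 <- mean(calls_matrix(f7$geno) == "H")
  expect_lt(abs(h3 - 0.25), 0.05)      # (1/2)^2, noisy via linked loci
  expect_lt(abs(h7 - 0.015625), 0.01)  # (1/2)^6
  expect_equal(sum(f7$pedigree$n_het_calls),
               sum(calls_matrix(f7$geno) == "H"))
})

test_that("degradation hits its configured rates and keeps truth intact", {
  sim <- small_ril(seed = 9, n_lines = 100, n_chrom = 2, length_mbp = 60)
  truth <- sim$geno
  expect_identical(calls_matrix(degrade_calls(truth, 0, 0, 0, seed = 1)),
                   calls_matrix(truth))
  obs <- degrade_calls(truth, missing_rate = 0.3, het_rate = 0.05,
                       miscall_rate = 0.02, seed = 2)
  cm_t <- calls_matrix(truth)
  cm_o <- calls_matrix(obs)
  n <- length(cm_o)
  expect_lt(abs(mean(is.na(cm_o)) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # miscalls flip homozygous truth to the opposite parent
  flipped <- !is.na(cm_o) & cm_o != "H" & cm_t != "H" & cm_o != cm_t
  expect_gt(sum(flipped), 0)
  expect_true(all((cm_t == "A")[flipped] == (cm_o == "B")[flipped]))
  expect_error(degrade_calls(truth, missing_rate = 1.5), "\\[0, 1\\]")
})

test_that("phenotypes follow the additive QTL model", {
  lay <- toy_layout(1, 60)
  qtls <- tibble::tibble(trait = "T", chrom = "chr1", pos_bp = 30e6,
                         effect = 1.5)
  sim <- simulate_ril(sim_config(lay, n_lines = 100, generation = 7,
                                 marker_spacing_mbp = 5, qtls = qtls,
                                 resid_sd = 0, seed = 10))
  ph <- simulate_phenotypes(sim, "T")
  sc <- calls_matrix(sim$geno)[match(sim$qtls$marker_id,
                                     sim$geno$marker_id), ]
  v <- stats::setNames(ph$value, ph$line)
  hom <- sc %in% c("A", "B")
  cls <- split(v[names(sc)][hom], sc[hom])
  # zero noise: two-valued by class, difference = 2 * effect
  expect_equal(unique(round(cls$A, 10)), 51.5)
  expect_equal(mean(cls$A) - mean(cls$B), 3)

  # a trait with no QTL rows is a pure-noise null
  sim$config$resid_sd <- 1
  ph0 <- simulate_phenotypes(sim, "null_trait")
  expect_equal(length(unique(ph0$value)), nrow(ph0))

  # infeasible heritability is refused
  q2 <- dplyr::mutate(qtls, h2 = 1.2)
  sim2 <- sim
  sim2$qtls <- dplyr::mutate(sim2$qtls, h2 = 1.2)
  expect_error(simulate_phenotypes(sim2, "T"), "infeasible")
})

test_that("planted effects are recovered without bias across replicates", {
  lay <- toy_layout(1, 80)
  est <- vapply(1:12, function(r) {
    sim <- simulate_ril(sim_config(
      lay, n_lines = 150, generation = 6, marker_spacing_mbp = 4,
      qtls = tibble::tibble(trait = "T", chrom = "chr1", pos_bp = 40e6,
                            effect = 1, h2 = 0.2),
      seed = 600 + r))
    ph <- simulate_phenotypes(sim, "T")
    v <- prepare_trait_values(ph, "T")
    sc <- calls_matrix(sim$geno)[match(sim$qtls$marker_id,
                                       sim$geno$marker_id), ]
    vv <- stats::setNames(v$value, v$line)[names(sc)]
    mean(vv[sc == "A"]) - mean(vv[sc == "B"])
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 2), 3 * se)   # class difference = 2 * effect
})

test_that("a coupled translocation produces pseudo-linkage between its chromosomes", {
  lay <- toy_layout(2, 120)
  tr <- translocation_spec(
    "chr2", 90e6, 120e6, "chr1", 119.5e6, carrier = "A",
    recombining_regions = tibble::tibble(chrom = c("chr1", "chr2"),
                                         start_bp = c(1, 1),
                                         end_bp = c(40e6, 30e6)),
    survival_def = 0, survival_dup = 0)
  sim <- simulate_ril(sim_config(lay, n_lines = 120, generation = 6,
                                 marker_spacing_mbp = 4, cm_per_mbp = 2,
                                 rearrangements = list(tr), seed = 11))
  mr <- rilqtl:::marker_r_matrix(sim$geno)
  g <- sim$geno
  pos <- g$pos_bp
  core_i <- g$chrom == "chr1" & pos > 60e6
  core_j <- g$chrom == "chr2" & pos > 50e6
  expect_lt(mean(mr$r[core_i, core_j], na.rm = TRUE), 0.05)
  # the recombining arms still exchange freely with the other chromosome
  free_i <- g$chrom == "chr1" & pos < 30e6
  expect_gt(mean(mr$r[free_i, core_j], na.rm = TRUE), 0.3)
})

test_that("asymmetric unbalanced-gamete survival distorts toward the carrier", {
  lay <- toy_layout(2, 100)
  freqs <- vapply(1:6, function(r) {
    tr <- translocation_spec(
      "chr2", 80e6, 100e6, "chr1", 99.5e6, carrier = "A",
      recombining_regions = tibble::tibble(chrom = c("chr1", "chr2"),
                                           start_bp = c(1, 1),
                                           end_bp = c(30e6, 20e6)),
      survival_def = 0, survival_dup = 0.5)
    sim <- simulate_ril(sim_config(lay, n_lines = 80, generation = 6,
                                   marker_spacing_mbp = 5,
                                   rearrangements = list(tr),
                                   seed = 700 + r))
    d <- distortion_profile(sim$geno)
    near <- d$chrom == "chr1" & d$pos_bp > 80e6
    mean(d$freq_a[near])
  }, numeric(1))
  # sign test: carrier-allele excess at the insertion-linked region
  expect_true(all(freqs > 0.5))
})

test_that("a pericentric inversion suppresses recombination inside its interval", {
  lay <- toy_layout(1, 150)
  inv <- inversion_spec("chr1", 1, 135e6, carrier = "A")
  sim <- simulate_ril(sim_config(lay, n_lines = 150, generation = 6,
                                 marker_spacing_mbp = 3,
                                 rearrangements = list(inv), seed = 12))
  mr <- rilqtl:::marker_r_matrix(sim$geno)
  pos <- sim$geno$pos_bp
  inside <- pos < 130e6
  far_apart <- abs(outer(pos[inside], pos[inside], "-")) > 60e6
  expect_lt(mean(mr$r[inside, inside][far_apart], na.rm = TRUE), 0.03)
  # the distal tip still recombines against the suppressed block
  tip <- pos > 140e6
  expect_gt(mean(mr$r[tip, pos < 60e6], na.rm = TRUE), 0.2)
})

test_that("per-region viability weights distort allele frequencies directionally", {
  lay <- toy_layout(1, 60)
  dist <- tibble::tibble(chrom = "chr1", pos_bp = 30e6, allele = "B",
                         weight = 0.3)
  sim <- simulate_ril(sim_config(lay, n_lines = 150, generation = 6,
                                 marker_spacing_mbp = 5, distortion = dist,
                                 seed = 13))
  d <- distortion_profile(sim$geno)
  mid <- which.min(abs(d$pos_bp - 30e6))
  expect_gt(d$freq_a[mid], 0.6)
})
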