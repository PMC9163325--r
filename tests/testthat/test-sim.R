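test_that("zero map length gives fully linked markers, with a warning", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_bp = 1e6,
                    map_lengths_morgans = 0, n_markers_per_chrom = 10,
                    n_f2 = 40, seed = 1)
  expect_warning(g <- simulate_f2(cfg), "fully linked")
  expect_true(all(g$geno %in% 0:2))
  per_ind_range <- apply(g$geno, 1, function(x) length(unique(x)))
  expect_true(all(per_ind_range == 1L))  # no recombinants anywhere
})

test_that("single-marker genotype frequencies follow the Mendelian 1:2:1", {
  cfg <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 1,
                    n_f2 = 10000, seed = 2)
  g <- simulate_f2(cfg)
  frq <- tabulate(g$geno + 1L, 3L) / 10000
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
  expect_true(all(abs(frq - c(0.25, 0.5, 0.25)) < 3 * se))

  ## chi-square goodness of fit rarely rejected at alpha = 0.001
  pvals <- vapply(1:100, function(s) {
    gs <- simulate_f2(sim_config(n_chromosomes = 1, n_markers_per_chrom = 1,
                                 n_f2 = 10000, seed = 100 + s))
    obs <- tabulate(gs$geno + 1L, 3L)
    suppressWarnings(stats::chisq.test(obs, p = c(.25, .5, .25))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("two linked markers recombine at the Haldane fraction", {
  ## markers 0.1 Morgan apart: c = (1 - exp(-0.2)) / 2 ~ 0.0906;
  ## for F2 genotype codes cor(g1, g2) = 1 - 2c, so c_hat = (1 - r) / 2
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_bp = 1e7,
                    map_lengths_morgans = 0.1, n_markers_per_chrom = 2,
                    n_f2 = 10000, seed = 3)
  g <- simulate_f2(cfg)
  c_hat <- (1 - stats::cor(g$geno[, 1], g$geno[, 2])) / 2
  c_true <- (1 - exp(-0.2)) / 2
  expect_lt(abs(c_hat - c_true), 0.008)
})

test_that("seeded generation is bit-reproducible", {
  cfg <- sim_config(n_chromosomes = 2, n_markers_per_chrom = 120, n_f2 = 60,
                    mean_depth = 50,
                    qtls = data.frame(chrom = 1, pos_bp = 5e7, a = 0.4, d = 0),
                    heritability_target = 0.4, seed = 99)
  a <- simulate_bsa_dataset(cfg)
  b <- simulate_bsa_dataset(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$variants, b$variants)
  expect_identical(a$phenotypes$ratio, b$phenotypes$ratio)
  expect_identical(a$bulks, b$bulks)
})

test_that("phenotype model: pure noise, slope recovery and config contradictions", {
  ## no QTLs, target 0: phenotype variance is the residual variance
  cfg0 <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 5, n_f2 = 5000,
                     heritability_target = 0, resid_sd = 0.35,
                     block_effect_sd = 0, seed = 4)
  g0 <- simulate_f2(cfg0)
  p0 <- simulate_phenotypes(g0, cfg0, seed = 5)
  expect_lt(abs(stats::var(p0$log_ratio) - 0.35^2), 0.01)

  ## one additive QTL: OLS on the genotype code recovers the slope a
  cfgq <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 5, n_f2 = 4000,
                     qtls = data.frame(chrom = 1, pos_bp = 7.5e7, a = 0.3,
                                       d = 0),
                     heritability_target = 0.5, block_effect_sd = 0, seed = 6)
  gq <- simulate_f2(cfgq)
  pq <- simulate_phenotypes(gq, cfgq, seed = 7)
  slope <- unname(stats::coef(stats::lm(pq$log_ratio ~
                                          gq$geno[, gq$qtls$marker[1]]))[2])
  expect_lt(abs(slope - 0.3), 0.03)

  ## contradictions are rejected
  cfg_bad <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 5, n_f2 = 50,
                        qtls = data.frame(chrom = 1, pos_bp = 7.5e7, a = 0.3,
                                          d = 0),
                        heritability_target = 0, seed = 8)
  gb <- simulate_f2(cfg_bad)
  expect_error(simulate_phenotypes(gb, cfg_bad), "contradicts")
  cfg_bad2 <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 5,
                         n_f2 = 50, heritability_target = 0.5, seed = 8)
  gb2 <- simulate_f2(cfg_bad2)
  expect_error(simulate_phenotypes(gb2, cfg_bad2), "no genetic variance")
})

test_that("pooled reads follow the binomial depth model", {
  cfg <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 2000, n_f2 = 10,
                    mean_depth = 887, depth_dispersion = 0,
                    missing_rate = 0, multiallelic_rate = 0, seed = 9)
  ## every individual heterozygous: true pooled frequency is exactly 0.5
  g <- make_geno(matrix(1L, nrow = 10, ncol = 2000))
  vt <- simulate_bulk_reads(g, rownames(g$geno)[1:5], rownames(g$geno)[6:10],
                            cfg, seed = 10)
  f <- vt$alt_depth_low / (vt$alt_depth_low + vt$ref_depth_low)
  expect_lt(abs(mean(f) - 0.5), 0.002)
  expect_lt(abs(stats::sd(f) - sqrt(0.25 / 887)), 0.1 * sqrt(0.25 / 887))

  ## a bulk fixed for the high-parent allele: alternate frequency 1
  gfix <- make_geno(matrix(2L, nrow = 4, ncol = 50))
  vfix <- simulate_bulk_reads(gfix, rownames(gfix$geno)[1:2],
                              rownames(gfix$geno)[3:4], cfg, seed = 11)
  expect_true(all(vfix$ref_depth_low == 0))
  expect_true(all(vfix$alt_depth_low ==
                    vfix$alt_depth_low + vfix$ref_depth_low))

  ## missingness is injected at the configured rate
  cfg_m <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 1000,
                      n_f2 = 10, mean_depth = 50, missing_rate = 0.5,
                      multiallelic_rate = 0, seed = 12)
  vm <- simulate_bulk_reads(g, rownames(g$geno)[1:5], rownames(g$geno)[6:10],
                            cfg_m, seed = 13)
  n_missing <- sum(is.na(vm$alt_depth_low[1:1000]))
  expect_lt(abs(n_missing - 500), 3 * sqrt(1000 * 0.25))

  ## bulk validation
  expect_error(simulate_bulk_reads(g, character(), rownames(g$geno)[1:2],
                                   cfg), "non-empty")
  expect_error(simulate_bulk_reads(g, rownames(g$geno)[1:2],
                                   rownames(g$geno)[2:3], cfg), "disjoint")
})

test_that("bulk allele frequencies separate at the QTL and not elsewhere", {
  signs_ok <- vapply(1:10, function(s) {
    cfg <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 200,
                      n_f2 = 200, mean_depth = 100,
                      qtls = data.frame(chrom = 1, pos_bp = 7.5e7, a = 0.6,
                                        d = 0),
                      heritability_target = 0.5, missing_rate = 0,
                      multiallelic_rate = 0, seed = 200 + s)
    sim <- simulate_bsa_dataset(cfg)
    qm <- sim$qtls$marker[1]
    fL <- sim$variants$alt_depth_low[qm] /
      (sim$variants$alt_depth_low[qm] + sim$variants$ref_depth_low[qm])
    fH <- sim$variants$alt_depth_high[qm] /
      (sim$variants$alt_depth_high[qm] + sim$variants$ref_depth_high[qm])
    fH > 0.5 && fL < 0.5
  }, logical(1))
  expect_true(all(signs_ok))

  ## on a chromosome unlinked to the QTL the expected bulk frequency is 0.5;
  ## single-genome means drift with the bulk's shared meioses, so average
  ## over seeds
  dev <- vapply(1:6, function(s) {
    cfg <- sim_config(n_chromosomes = 2, n_markers_per_chrom = 150,
                      n_f2 = 200, mean_depth = 200,
                      qtls = data.frame(chrom = 1, pos_bp = 7.5e7, a = 0.6,
                                        d = 0),
                      heritability_target = 0.5, missing_rate = 0,
                      multiallelic_rate = 0, seed = 300 + s)
    sim <- simulate_bsa_dataset(cfg)
    on2 <- sim$variants$chrom == "chr2"
    fH2 <- sim$variants$alt_depth_high[on2] /
      (sim$variants$alt_depth_high[on2] + sim$variants$ref_depth_high[on2])
    mean(fH2) - 0.5
  }, numeric(1))
  expect_true(all(abs(dev) < 0.2))
  expect_lt(abs(mean(dev)), 0.06)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(heritability_target = 1.2), "heritability")
  expect_error(sim_config(missing_rate = -0.1), "fractions")
  expect_error(sim_config(n_chromosomes = 1, chrom_lengths_bp = 1e6,
                          qtls = data.frame(chrom = 1, pos_bp = 2e6, a = 1,
                                            d = 0)),
               "outside")
  expect_error(sim_config(n_f2 = 10, block_sizes = c(4, 4)), "sum to n_f2")
})
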