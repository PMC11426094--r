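test_that("pedigree simulation respects structure and determinism", {
  # no matings: founders only
  cfg0 <- sim_config(n_founders = 5, n_generations = 0, n_snps = 1, seed = 1)
  p0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(p0), 5L)
  expect_true(all(is.na(p0$sire)) && all(is.na(p0$dam)))

  # 4 founders + 2 matings x 2 offspring = 8 records
  cfg1 <- sim_config(n_founders = 4, n_generations = 1, n_matings = 2,
                     n_offspring = 2, n_snps = 1, seed = 2)
  p1 <- simulate_pedigree(cfg1)
  expect_equal(nrow(p1), 8L)
  expect_true(all(p1$generation[5:8] == 1L))
  expect_true(all(p1$sire[5:8] %in% p1$id[p1$sex == "M" & p1$generation == 0]))

  # identical config => byte-identical outputs through the whole pipeline
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_matings = 10,
                    n_offspring = 2, n_snps = 10, seed = 33)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$ped, s2$ped)
  expect_identical(s1$gm$codes, s2$gm$codes)
  expect_identical(s1$pheno, s2$pheno)
})

test_that("founder genotypes follow the HWD genotype distribution", {
  # hwd_f = 0, p1 = 0.5: heterozygote fraction ~ 0.5
  cfg <- sim_config(n_founders = 10000, n_generations = 0, n_snps = 1,
                    maf_range = c(0.5, 0.5), hwd_f = 0, seed = 5)
  gm <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  p12 <- mean(gm$codes == 1L)
  expect_lt(abs(p12 - 0.5), 4 * sqrt(0.25 / 10000))

  # hwd_f = 0.999... -> essentially no heterozygotes; exactly 0 at f -> 1
  cfg2 <- sim_config(n_founders = 5000, n_generations = 0, n_snps = 1,
                     maf_range = c(0.3, 0.3), hwd_f = 0.9999999, seed = 6)
  gm2 <- simulate_genotypes(simulate_pedigree(cfg2), cfg2)
  expect_equal(sum(gm2$codes == 1L), 0L)

  # with hwd_f = 0 a chi-square HWE test is non-significant at alpha=0.01
  # for at least 98% of replicate SNPs
  cfg3 <- sim_config(n_founders = 800, n_generations = 0, n_snps = 300,
                     hwd_f = 0, seed = 7)
  gm3 <- simulate_genotypes(simulate_pedigree(cfg3), cfg3)
  pvals <- apply(gm3$codes, 2L, function(g) {
    n <- c(sum(g == 2), sum(g == 1), sum(g == 0))
    p <- (2 * n[1] + n[2]) / (2 * sum(n))
    e <- sum(n) * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stats::pchisq(sum((n - e)^2 / e), df = 1, lower.tail = FALSE)
  })
  expect_gte(mean(pvals > 0.01), 0.98)
})

test_that("gene drop reproduces Mendelian daughter fractions from an rr sire", {
  # offspring of a homozygous recessive sire and a random dam are rr with
  # probability q (the recessive allele frequency among dams)
  q <- 0.3
  cfg <- sim_config(n_founders = 3000, n_generations = 1, n_matings = 12000,
                    n_offspring = 1, n_snps = 1, seed = 8,
                    causal_rec = data.frame(snp = 1, q = q, ni = -5))
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  off <- which(ped$generation == 1L)
  sire_code <- gm$codes[match(ped$sire[off], ped$id), 1L]
  off_rr_sire <- gm$codes[off[sire_code == 0L], 1L]  # rr = 0 copies of allele 1
  expect_gt(length(off_rr_sire), 400)
  frac_rr <- mean(off_rr_sire == 0L)
  expect_lt(abs(frac_rr - q), 4 * sqrt(q * (1 - q) / length(off_rr_sire)))

  # gene drop conserves the founder allele frequency in expectation
  p1_founder <- mean(gm$codes[ped$generation == 0L, 1L]) / 2
  p1_off <- mean(gm$codes[off, 1L]) / 2
  expect_lt(abs(p1_off - p1_founder), 0.02)
})

test_that("phenotype model obeys its noise-free and variance limits", {
  # sigma_a2 ~ 0, sigma_e2 ~ 0, single causal SNP: y = mu + g(genotype)
  cfg <- sim_config(n_founders = 50, n_generations = 0, n_snps = 3,
                    sigma_a2 = 1e-12, sigma_e2 = 1e-12, mu = 10,
                    causal_add = data.frame(snp = 2, alpha = 0.5), seed = 9)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  fx <- true_effects(cfg)
  ph <- simulate_phenotypes(ped, gm, fx, cfg)
  g_of <- c(0, 0.5, 1)[gm$codes[, 2] + 1L]  # (g22, g12, g11) = (0, .5, 1)
  expect_equal(ph$y, 10 + g_of, tolerance = 1e-5)

  # no causal SNPs: var(y) ~ sigma_a2 + sigma_e2
  cfg2 <- sim_config(n_founders = 4000, n_generations = 0, n_snps = 1,
                     sigma_a2 = 4, sigma_e2 = 6, seed = 10)
  ped2 <- simulate_pedigree(cfg2)
  gm2 <- simulate_genotypes(ped2, cfg2)
  ph2 <- simulate_phenotypes(ped2, gm2, true_effects(cfg2), cfg2)
  expect_lt(abs(var(ph2$y) - 10) / 10, 0.1)
})

test_that("polygenic values of full sibs covary by half the additive variance", {
  # brute-force Monte-Carlo over 10^4 independent full-sib pairs
  K <- 10000L
  ped <- sib_pedigree(K)
  cfg <- sim_config(n_founders = 2L * K, n_generations = 1, n_snps = 1,
                    sigma_a2 = 1, sigma_e2 = 1, seed = 12)
  gm <- list(codes = matrix(0L, nrow(ped), 1,
                            dimnames = list(ped$id, "s1")),
             map = data.frame(snp = "s1", chrom = "1", pos = 1L,
                              allele1 = "A", allele2 = "B"))
  class(gm) <- "genotype_matrix"
  ph <- simulate_phenotypes(ped, gm, true_effects(cfg), cfg)
  a <- ph$a_true[match(paste0("o", seq_len(2L * K)), ph$id)]
  a1 <- a[seq(1, 2L * K, 2)]; a2 <- a[seq(2, 2L * K, 2)]
  cv <- cov(a1, a2)
  expect_lt(abs(cv - 0.5), 4 / sqrt(K))  # cov SE ~ sqrt((1+cov^2)/K)
})

test_that("PTA is the exact pedigree BLUP and shrinks to zero as heritability vanishes", {
  cfg <- sim_config(n_founders = 30, n_generations = 2, n_matings = 30,
                    n_offspring = 1, n_snps = 2, seed = 13)
  sim <- simulate_dataset(cfg)
  A <- build_A(sim$ped)
  n <- nrow(sim$ped)
  orc <- exact_fit(sim$pheno$y, matrix(1, n, 1), diag(n), A,
                   cfg$sigma_a2, cfg$sigma_e2)
  expect_equal(2 * sim$pheno$pta, unname(orc$a_hat), tolerance = 1e-8)

  cfg0 <- sim_config(n_founders = 30, n_generations = 1, n_matings = 20,
                     n_offspring = 1, n_snps = 1, sigma_a2 = 1e-9,
                     sigma_e2 = 10, seed = 14)
  sim0 <- simulate_dataset(cfg0)
  expect_lt(max(abs(sim0$pheno$pta)), 1e-6)
})

test_that("simulated data round-trips through the disk format", {
  cfg <- sim_config(n_founders = 10, n_generations = 1, n_matings = 5,
                    n_offspring = 2, n_snps = 6, seed = 15,
                    causal_rec = data.frame(snp = 3, q = 0.3, ni = -4))
  sim <- simulate_dataset(cfg)
  sim$gm$codes[2, 4] <- NA  # exercise the missing-code path
  d <- withr::local_tempdir()
  paths <- write_sim_data(sim, d)
  gm2 <- read_genotypes(file.path(d, "genotypes.tsv"), "tsv",
                        file.path(d, "snp_map.tsv"))
  expect_identical(gm2$codes, sim$gm$codes)
  expect_equal(gm2$map, sim$gm$map)
  ped2 <- read_pedigree(file.path(d, "pedigree.csv"))
  expect_equal(ped2$id, sim$ped$id)
  ph2 <- read_phenotypes(file.path(d, "phenotypes.csv"))
  expect_equal(ph2$y, sim$pheno$y)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$causal[[1]]$g22, -4)
})
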