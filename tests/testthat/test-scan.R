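make_scan_sim <- function() {
  cfg <- sim_config(n_founders = 1000, n_generations = 1, n_matings = 1000,
                    n_offspring = 1, n_snps = 60, seed = 61,
                    causal_add = data.frame(snp = 10, alpha = 2.5),
                    causal_rec = data.frame(snp = 20, q = 0.3, ni = -8))
  simulate_dataset(cfg)
}

test_that("scan detects a strong causal SNP at the top additive rank", {
  sim <- make_scan_sim()
  sc <- agls_scan(sim$gm, sim$pheno)
  top <- rank_top(sc, 1, "additive")
  expect_equal(top$snp, sim$gm$map$snp[10])
  # scan rows re-verify against direct module calls (no orchestration drift)
  ph <- adjust_phenotypes(sim$pheno)
  common <- intersect(ph$id, rownames(sim$gm$codes))
  r <- sc$results[sc$results$snp == "snp0010", ]
  fit <- agls_fit(ph$y_star[match(common, ph$id)],
                  sim$gm$codes[common, "snp0010"])
  expect_equal(r$alpha, additive_decomposition(fit)$alpha, tolerance = 1e-12)
  expect_equal(r$log10p_add, additive_contrast(fit)$log10_inv_p, tolerance = 1e-12)
  expect_equal(r$delta, dominance_contrast(fit)$L, tolerance = 1e-12)
  # NI row of the engineered recessive SNP is close to its programmed value
  r20 <- sc$results[sc$results$snp == "snp0020", ]
  expect_lt(abs(r20$NI - (-8)), 1.5)
  expect_equal(r20$recessive_allele, 2L)
})

test_that("a duplicated causal column gives identical statistics and the null scan stays null", {
  sim <- make_scan_sim()
  gm <- sim$gm
  dup <- gm$codes[, 10, drop = FALSE]
  colnames(dup) <- "snp_dup"
  codes2 <- cbind(gm$codes, dup)
  map2 <- rbind(gm$map, data.frame(snp = "snp_dup", chrom = "1",
                                   pos = max(gm$map$pos) + 10000L,
                                   allele1 = "A", allele2 = "B"))
  sc2 <- agls_scan(genotype_matrix(codes2, map2), sim$pheno)
  a <- sc2$results[sc2$results$snp == "snp0010", ]
  b <- sc2$results[sc2$results$snp == "snp_dup", ]
  expect_equal(a$log10p_add, b$log10p_add)
  expect_equal(a$alpha, b$alpha)

  # null panel at the fixed 1e-8 threshold: no significant SNPs
  cfg0 <- sim_config(n_founders = 500, n_generations = 1, n_matings = 500,
                     n_offspring = 1, n_snps = 200, seed = 62)
  sim0 <- simulate_dataset(cfg0)
  sc0 <- agls_scan(sim0$gm, sim0$pheno, fixed_log10p = 8)
  expect_equal(sum(sc0$results$sig_add, na.rm = TRUE), 0L)
  expect_equal(sum(sc0$results$sig_dom, na.rm = TRUE), 0L)
})

test_that("scan output is invariant to cow and SNP input order", {
  sim <- make_scan_sim()
  sc1 <- agls_scan(sim$gm, sim$pheno)
  perm_c <- sample(nrow(sim$gm$codes))
  perm_s <- sample(ncol(sim$gm$codes))
  gm_p <- genotype_matrix(sim$gm$codes[perm_c, perm_s],
                          sim$gm$map[perm_s, ])
  ph_p <- sim$pheno[sample(nrow(sim$pheno)), ]
  sc2 <- agls_scan(gm_p, ph_p)
  expect_equal(sc1$results, sc2$results, tolerance = 1e-12)
})

test_that("rank_top orders by significance with a positional tie-break", {
  r <- data.frame(snp = c("a", "b", "c", "d"), chrom = c("2", "1", "1", "1"),
                  pos = c(5L, 9L, 1L, 3L),
                  log10p_add = c(7, 7, 9, NA),
                  log10p_dom = c(1, 2, 3, 4))
  top <- rank_top(r, 10, "additive")
  expect_equal(top$snp, c("c", "b", "a"))  # 9 first; tie 7-7 by (chrom, pos)
  expect_equal(top$rank, 1:3)
  top1 <- rank_top(r, 2, "additive")
  expect_equal(nrow(top1), 2L)
})

test_that("gene annotation distinguishes in/upstream/downstream and intergenic", {
  iv <- data.frame(chrom = "6",
                   start = c(86859000L, 87100000L, 90000000L),
                   end = c(87000000L, 87200000L, 90100000L),
                   name = c("SLC4A4", "GC", "FAR"),
                   strand = c("+", "-", NA), stringsAsFactors = FALSE)
  rows <- data.frame(chrom = "6",
                     pos = c(86900000L, 87005000L, 89000000L, 90140000L, 86820000L),
                     stringsAsFactors = FALSE)
  ann <- annotate_genes(rows, iv, window = 50000)
  expect_equal(ann$gene[1], "SLC4A4"); expect_equal(ann$gene_flag[1], "in")
  # 5 kb past the end of a '+' gene: downstream
  expect_equal(ann$gene[2], "SLC4A4"); expect_equal(ann$gene_flag[2], "d")
  # between two genes but outside the window: unannotated
  expect_equal(ann$gene[3], "")
  # past a strandless gene: coordinate-order flag with strandless marker
  expect_equal(ann$gene_flag[4], "d*")
  # upstream of a '+' gene
  expect_equal(ann$gene_flag[5], "u")

  # two genes both within the window: hyphenated intergenic label
  ann2 <- annotate_genes(data.frame(chrom = "6", pos = 87050000L), iv,
                         window = 1e6)
  expect_equal(ann2$gene, "SLC4A4-GC")
})

test_that("flanking report records nearest insignificant SNPs and mean distance", {
  r <- data.frame(snp = paste0("s", 1:7), chrom = "1",
                  pos = c(1000L, 2000L, 3000L, 10000L, 33545L, 40000L, 41000L),
                  log10p_dom = c(1, 9, 1, 10, 2, 9, 1),
                  log10p_add = 0)
  fl <- flanking_significance(r, "dominance", log10p_threshold = 8)
  expect_equal(nrow(fl$flanks), 3L)
  # engineered distances: (1000,1000), (7000,23545), (7455 right-side=1000)
  expect_equal(fl$flanks$left_dist, c(1000L, 7000L, 6455L))
  expect_equal(fl$flanks$right_dist, c(1000L, 23545L, 1000L))
  expect_equal(fl$mean_distance, mean(c(1000, 1000, 7000, 23545, 6455, 1000)))

  # all significant: empty report
  r2 <- data.frame(snp = c("a", "b"), chrom = "1", pos = c(1L, 2L),
                   log10p_dom = c(9, 9), log10p_add = 0)
  fl2 <- flanking_significance(r2, "dominance", log10p_threshold = 8)
  expect_equal(nrow(fl2$flanks), 0L)
})

test_that("LD correlation behaves at the identity, independence and noisy-copy limits", {
  set.seed(63)
  n <- 10000
  a <- rbinom(n, 2, 0.4)
  b <- rbinom(n, 2, 0.4)
  gm <- make_gm(cbind(a, b, a))
  expect_equal(ld_r(gm, "s1", "s1")$r, 1)
  expect_lt(abs(ld_r(gm, "s1", "s2")$r), 0.05)
  # copy with 5% of entries replaced by fresh draws: E[r] ~ 0.95
  swapped <- a
  idx <- sample(n, round(0.05 * n))
  swapped[idx] <- rbinom(length(idx), 2, 0.4)
  gm2 <- make_gm(cbind(a, swapped))
  expect_lt(abs(ld_r(gm2, "s1", "s2")$r - 0.95), 0.03)
  # zero variance: NA
  gm3 <- make_gm(cbind(a, rep(1L, n)))
  expect_true(is.na(ld_r(gm3, "s1", "s2")$r))
})

test_that("manhattan export writes cumulative coordinates and round-trips", {
  r <- data.frame(snp = c("a", "b", "c"), chrom = c("1", "2", "2"),
                  pos = c(100L, 50L, 80L), log10p_add = c(1, 2, 3),
                  log10p_dom = c(0.5, 1, 1.5))
  d <- withr::local_tempdir()
  md <- manhattan_export(r, file.path(d, "m.tsv"), "additive")
  expect_true(all(diff(md$cum_pos) > 0))
  expect_equal(md$cum_pos, c(100, 150, 180))
  back <- read.delim(file.path(d, "m.tsv"))
  expect_equal(back$log10_inv_p, md$log10_inv_p)

  # empty rows: header-only file
  r0 <- r[0, ]
  manhattan_export(r0, file.path(d, "m0.tsv"), "additive")
  expect_equal(nrow(read.delim(file.path(d, "m0.tsv"))), 0L)
})

test_that("write_scan produces the standard output files", {
  sim <- make_scan_sim()
  sc <- agls_scan(sim$gm, sim$pheno)
  d <- withr::local_tempdir()
  write_scan(sc, d, n_top = 20)
  expect_true(all(file.exists(file.path(d, c("additive.tsv", "dominance.tsv",
                                             "flanks.tsv", "manhattan.tsv",
                                             "summary.json")))))
  s <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(s$n_snps, sc$n_snps)
  add <- read.delim(file.path(d, "additive.tsv"))
  expect_equal(nrow(add), 20L)
})
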