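fit_from <- function(g11, g12, g22, counts) {
  structure(list(ghat = c(g11 = g11, g12 = g12, g22 = g22),
                 counts = c(n11 = counts[1], n12 = counts[2], n22 = counts[3]),
                 n = sum(counts), k = sum(counts > 0), v2 = 1,
                 df = sum(counts) - sum(counts > 0)),
            class = "agls_fit")
}

hwe_counts <- function(p1, n = 10000) {
  round(n * c(p1^2, 2 * p1 * (1 - p1), (1 - p1)^2))
}

test_that("allelic decomposition matches the symmetric worked case", {
  fit <- fit_from(1, 0, -1, hwe_counts(0.5))
  ad <- additive_decomposition(fit)
  expect_equal(ad$mu, 0)
  expect_equal(ad$a1, 0.5)
  expect_equal(ad$a2, -0.5)
  expect_equal(ad$alpha, 1)
})

test_that("decomposition identities hold on random fits", {
  set.seed(51)
  for (i in 1:25) {
    cts <- as.integer(rmultinom(1, 500, runif(3, 0.1, 1))) + 1L
    g <- rnorm(3)
    fit <- fit_from(g[1], g[2], g[3], cts)
    fr <- snp_frequencies(counts = cts)
    ad <- additive_decomposition(fit, fr)
    dd <- dominance_decomposition(fit, ad, fr)
    # zero-sum allelic effects (forced by the definitions)
    expect_lt(abs(fr$p1 * ad$a1 + fr$p2 * ad$a2), 1e-12)
    # alpha = a1 - a2 = mu1 - mu2 and equals the additive contrast value
    expect_equal(ad$alpha, ad$mu1 - ad$mu2, tolerance = 1e-12)
    expect_equal(ad$alpha, additive_contrast(fit, fr)$L, tolerance = 1e-10)
    # frequency-weighted dominance deviations sum to zero
    expect_lt(abs(fr$P11 * dd$d11 + fr$P12 * dd$d12 + fr$P22 * dd$d22), 1e-10)
    # both delta formulas agree
    expect_equal(dd$delta, g[2] - (g[1] + g[3]) / 2, tolerance = 1e-12)
    # reconstruction: mu + a_i + a_j + d_ij = g_ij for all three genotypes
    expect_equal(ad$mu + 2 * ad$a1 + dd$d11, g[1], tolerance = 1e-12)
    expect_equal(ad$mu + ad$a1 + ad$a2 + dd$d12, g[2], tolerance = 1e-12)
    expect_equal(ad$mu + 2 * ad$a2 + dd$d22, g[3], tolerance = 1e-12)
    # scale equivariance
    fit2 <- fit_from(2 * g[1], 2 * g[2], 2 * g[3], cts)
    ad2 <- additive_decomposition(fit2, fr)
    dd2 <- dominance_decomposition(fit2, ad2, fr)
    expect_equal(ad2$alpha, 2 * ad$alpha, tolerance = 1e-12)
    expect_equal(dd2$d12, 2 * dd$d12, tolerance = 1e-12)
  }
})

test_that("purely additive and purely dominant cases decompose cleanly", {
  fr <- snp_frequencies(counts = hwe_counts(0.5))
  fit <- fit_from(1, 0, -1, hwe_counts(0.5))
  dd <- dominance_decomposition(fit, fr = fr)
  expect_equal(c(dd$d11, dd$d12, dd$d22), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(dd$delta, 0)

  fit2 <- fit_from(0, 1, 0, hwe_counts(0.5))
  dd2 <- dominance_decomposition(fit2, fr = fr)
  expect_equal(dd2$delta, 1)
})

test_that("dominance classification follows the deviation rules", {
  mk_dd <- function(d) structure(list(d11 = d[1], d12 = d[2], d22 = d[3],
                                      delta = d[2] - (d[1] + d[3]) / 2),
                                 class = "dominance_decomposition")
  fit <- fit_from(1, 0.9, -1, hwe_counts(0.4))
  expect_equal(classify_dominance(mk_dd(c(-0.1, 0.2, -0.1)), fit)$classification,
               "overdominance")
  expect_equal(classify_dominance(mk_dd(c(-0.2, 0.0, 0.2)), fit)$classification,
               "partial")
  # heterozygote equal to one homozygote: complete dominance, and the
  # tolerance takes precedence over the strict orderings
  expect_equal(classify_dominance(mk_dd(c(-0.2, 0.199, 0.2)), fit)$classification,
               "complete")
  # allele whose homozygote mean is nearer the heterozygote is dominant
  cl <- classify_dominance(mk_dd(c(-0.1, 0.2, -0.1)), fit)
  expect_equal(cl$dominant_allele, 1L)
  expect_equal(cl$recessive_allele, 2L)
  fit_flip <- fit_from(-1, 0.9, 1, hwe_counts(0.4))
  expect_equal(classify_dominance(mk_dd(c(-0.1, 0.2, -0.1)), fit_flip)$dominant_allele, 2L)
})

test_that("negative impact is the recessive-mean shortfall on the original scale", {
  ni <- negative_impact(y_rr = 5.65, y_rd = 11.27, y_dd = 12.29)
  expect_equal(ni$NI, -6.13, tolerance = 1e-9)
  ni2 <- negative_impact(6.25, 11.00, 12.26)
  expect_equal(ni2$NI, -5.38, tolerance = 1e-9)
  expect_equal(negative_impact(7, 7, 7)$NI, 0)
  expect_warning(ni3 <- negative_impact(NA, 11, 12), "undefined")
  expect_true(is.na(ni3$NI))
})

test_that("negative impact from data uses original phenotypes and the designated allele", {
  set.seed(52)
  codes <- c(rep(0L, 10), rep(1L, 20), rep(2L, 70))
  y <- c(rep(5, 10), rep(11, 20), rep(12, 70)) + rnorm(100, 0, 1e-9)
  gm <- make_gm(matrix(codes, ncol = 1))
  ph <- data.frame(id = rownames(gm$codes), y = y, pta = rnorm(100))
  ni <- negative_impact_at(gm, ph, "s1", recessive_allele = 2L)
  expect_equal(ni$NI, 5 - (11 + 12) / 2, tolerance = 1e-6)
  expect_equal(ni$f_rr, 0.1)
})

test_that("complementary allelic effect follows the zero-sum identity", {
  expect_equal(complement_allelic_effect(0.137, 0.673), -0.282, tolerance = 0.005)
  # inverse of itself
  ae <- 0.42; f <- 0.31
  expect_equal(complement_allelic_effect(complement_allelic_effect(ae, f), 1 - f),
               ae, tolerance = 1e-12)
})
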