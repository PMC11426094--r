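#' Allelic means, allelic effects and the average effect of gene
#' substitution
#'
#' Decomposes fitted genotype-class values into the allelic means
#' mu1 = P11.1 g11 + 0.5 P12.1 g12 and mu2 = 0.5 P12.2 g12 + P22.2 g22
#' (conditional genotype frequencies, so the decomposition is valid under
#' Hardy-Weinberg disequilibrium), the population mean mu = p1 mu1 +
#' p2 mu2, allelic effects a_i = mu_i - mu, and the average effect of
#' gene substitution alpha = a1 - a2 = mu1 - mu2. The frequency-weighted
#' allelic effects satisfy p1 a1 + p2 a2 = 0 exactly.
#'
#' @param fit an [agls_fit()] with all classes carrying weight defined.
#' @param fr a [snp_frequencies()]; defaults to the fit's own counts.
#' @return object of class `additive_decomposition`: mu1, mu2, mu, a1,
#'   a2, alpha, and positive/negative allele labels (allele index 1/2)
#'   with their effects and frequencies. When a1 = a2 = 0 the labels fall
#'   back to allele order and `null_effect` is TRUE.
#' @export
additive_decomposition <- function(fit, fr = snp_frequencies(counts = fit$counts)) {
  if (fr$p1 <= 0 || fr$p2 <= 0) stop("monomorphic SNP: allelic decomposition undefined")
  g <- unname(fit$ghat)  # positional: (g11, g12, g22)
  gz <- ifelse(is.na(g), 0, g)  # empty classes have zero conditional frequency
  cz <- function(x) ifelse(is.na(x), 0, x)
  mu1 <- cz(fr$P11.1) * gz[1] + 0.5 * cz(fr$P12.1) * gz[2]
  mu2 <- 0.5 * cz(fr$P12.2) * gz[2] + cz(fr$P22.2) * gz[3]
  mu <- fr$p1 * mu1 + fr$p2 * mu2
  a1 <- mu1 - mu; a2 <- mu2 - mu
  alpha <- a1 - a2
  null_effect <- isTRUE(all.equal(a1, 0)) && isTRUE(all.equal(a2, 0))
  if (null_effect || a1 > a2) {
    pos <- 1L; neg <- 2L
  } else {
    pos <- 2L; neg <- 1L
  }
  eff <- c(a1, a2); frq <- c(fr$p1, fr$p2)
  structure(list(mu1 = unname(mu1), mu2 = unname(mu2), mu = unname(mu),
                 a1 = unname(a1), a2 = unname(a2), alpha = unname(alpha),
                 allele_pos = pos, ae_pos = unname(eff[pos]), f_pos = frq[pos],
                 allele_neg = neg, ae_neg = unname(eff[neg]), f_neg = frq[neg],
                 null_effect = null_effect),
            class = "additive_decomposition")
}

#' @export
print.additive_decomposition <- function(x, ...) {
  cat(sprintf("alpha (avg effect of gene substitution) = %.4f\n", x$alpha))
  cat(sprintf("allelic means mu1 = %.4f, mu2 = %.4f; population mean mu = %.4f\n",
              x$mu1, x$mu2, x$mu))
  cat(sprintf("allelic effects a1 = %.4f, a2 = %.4f (p1 a1 + p2 a2 = 0)\n",
              x$a1, x$a2))
  invisible(x)
}

#' Negative allelic effect from the positive one
#'
#' The zero-sum identity p+ a+ + p- a- = 0 gives the effect of the
#' other allele from one allelic effect and its frequency:
#' a- = -a+ f+ / (1 - f+).
#'
#' @param ae allelic effect of one allele (months).
#' @param f frequency of that allele, in (0, 1).
#' @return allelic effect of the alternative allele.
#' @export
complement_allelic_effect <- function(ae, f) {
  stopifnot(all(f > 0), all(f < 1))
  -ae * f / (1 - f)
}

#' Dominance deviations and the dominance effect
#'
#' d_ij = g_ij - mu - a_i - a_j, and delta = d12 - (d11 + d22)/2, which
#' equals g12 - (g11 + g22)/2 identically; both forms are computed and
#' checked for agreement. The frequency-weighted deviations satisfy
#' P11 d11 + P12 d12 + P22 d22 = 0.
#'
#' @param fit an [agls_fit()] with all three classes observed.
#' @param add an [additive_decomposition()] of the same fit.
#' @param fr a [snp_frequencies()]; defaults to the fit's counts.
#' @return object of class `dominance_decomposition`: d11, d12, d22,
#'   delta; NA (with warning) when the heterozygote class is empty.
#' @export
dominance_decomposition <- function(fit, add = additive_decomposition(fit, fr),
                                    fr = snp_frequencies(counts = fit$counts)) {
  g <- unname(fit$ghat)  # positional: (g11, g12, g22)
  if (is.na(g[2])) {
    warning("empty heterozygote class: dominance deviations undefined")
    return(structure(list(d11 = NA_real_, d12 = NA_real_, d22 = NA_real_,
                          delta = NA_real_), class = "dominance_decomposition"))
  }
  d11 <- g[1] - add$mu - 2 * add$a1
  d12 <- g[2] - add$mu - add$a1 - add$a2
  d22 <- g[3] - add$mu - 2 * add$a2
  delta <- d12 - (d11 + d22) / 2
  delta2 <- g[2] - (g[1] + g[3]) / 2
  if (is.finite(delta) && is.finite(delta2) &&
      abs(delta - delta2) > 1e-8 * max(1, abs(delta))) {
    warning("dominance-effect identities disagree beyond numerical tolerance")
  }
  structure(list(d11 = unname(d11), d12 = unname(d12), d22 = unname(d22),
                 delta = unname(delta)),
            class = "dominance_decomposition")
}

#' @export
print.dominance_decomposition <- function(x, ...) {
  cat(sprintf("dominance deviations d11 = %.4f, d12 = %.4f, d22 = %.4f\n",
              x$d11, x$d12, x$d22))
  cat(sprintf("dominance effect delta = %.4f\n", x$delta))
  invisible(x)
}

#' Classify the degree of dominance and assign allele roles
#'
#' Using dominance deviations: complete dominance when d12 equals d11 or
#' d22 within a relative tolerance (tol * |d11 - d22|; sampling noise
#' means exact equality never happens, so the tolerance takes precedence
#' over the strict orderings); overdominance when |d12| exceeds both
#' |d11| and |d22|; partial dominance when d12 lies strictly between d11
#' and d22. The dominant allele is the one whose homozygote mean is
#' nearer the heterozygote mean; the other allele is recessive.
#'
#' @param dd a [dominance_decomposition()].
#' @param fit the [agls_fit()] the deviations came from (for allele roles).
#' @param tol relative tolerance for the complete-dominance equality.
#' @return list: classification ("overdominance", "partial", "complete",
#'   or "unclassified"), dominant_allele and recessive_allele (1 or 2).
#' @export
classify_dominance <- function(dd, fit, tol = 0.05) {
  d <- c(dd$d11, dd$d12, dd$d22)
  if (anyNA(d)) return(list(classification = NA_character_,
                            dominant_allele = NA_integer_,
                            recessive_allele = NA_integer_))
  span <- abs(d[1] - d[3])
  cls <- if (abs(d[2] - d[1]) <= tol * span || abs(d[2] - d[3]) <= tol * span) {
    "complete"
  } else if (abs(d[2]) > abs(d[1]) && abs(d[2]) > abs(d[3])) {
    "overdominance"
  } else if ((d[1] < d[2] && d[2] < d[3]) || (d[1] > d[2] && d[2] > d[3])) {
    "partial"
  } else {
    "unclassified"
  }
  g <- unname(fit$ghat)
  # dominant allele: its homozygote is the one the heterozygote resembles
  dom <- if (abs(g[1] - g[2]) <= abs(g[3] - g[2])) 1L else 2L
  list(classification = cls, dominant_allele = dom,
       recessive_allele = 3L - dom)
}

#' Negative impact of a homozygous recessive genotype
#'
#' NI = y_rr - (y_rd + y_dd)/2, where the class means are genotypic
#' averages of the ORIGINAL phenotypic values (months), not of the
#' polygenic-adjusted y*.
#'
#' @param y_rr,y_rd,y_dd genotype-class means of the original phenotype
#'   for the homozygous recessive, heterozygous, and homozygous dominant
#'   classes.
#' @param f_rr,f_rd,f_dd optional genotype frequencies, carried through.
#' @return object of class `ni_result` with the means, frequencies and NI;
#'   NI is NA (with warning) when the recessive class mean is missing.
#' @export
negative_impact <- function(y_rr, y_rd, y_dd, f_rr = NA_real_, f_rd = NA_real_,
                            f_dd = NA_real_) {
  if (is.na(y_rr)) {
    warning("no homozygous recessive cows: NI undefined")
    ni <- NA_real_
  } else {
    ni <- y_rr - (y_rd + y_dd) / 2
  }
  structure(list(y_rr = y_rr, y_rd = y_rd, y_dd = y_dd,
                 f_rr = f_rr, f_rd = f_rd, f_dd = f_dd, NI = ni),
            class = "ni_result")
}

#' @export
print.ni_result <- function(x, ...) {
  cat(sprintf("genotype means (months): rr = %.3f, rD = %.3f, DD = %.3f\n",
              x$y_rr, x$y_rd, x$y_dd))
  cat(sprintf("negative impact NI = %.3f months\n", x$NI))
  invisible(x)
}

#' Negative impact computed from data
#'
#' Convenience wrapper: genotype-class means of the original phenotype y
#' at one SNP, with the recessive allele designated (1 or 2), then
#' [negative_impact()].
#'
#' @param gm a [genotype_matrix()].
#' @param ph phenotype data.frame (id, y); ids matched to `gm` rows.
#' @param snp SNP id.
#' @param recessive_allele 1 or 2.
#' @return an `ni_result`.
#' @export
negative_impact_at <- function(gm, ph, snp, recessive_allele) {
  stopifnot(recessive_allele %in% c(1L, 2L))
  idx <- match(ph$id, rownames(gm$codes))
  ok <- !is.na(idx)
  codes <- gm$codes[idx[ok], snp]
  y <- ph$y[ok]
  keep <- !is.na(codes)
  codes <- codes[keep]; y <- y[keep]
  # code = copies of allele 1; rr class is 2 copies of the recessive allele
  rr_code <- if (recessive_allele == 1L) 2L else 0L
  dd_code <- 2L - rr_code
  m <- function(code) if (any(codes == code)) mean(y[codes == code]) else NA_real_
  f <- function(code) mean(codes == code)
  negative_impact(m(rr_code), m(1L), m(dd_code),
                  f(rr_code), f(1L), f(dd_code))
}
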