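#' Polygenic adjustment of phenotypes
#'
#' The approximate-GLS adjustment replaces the polygenic term by twice the
#' predicted transmitting ability: y* = y - 2 PTA. Cows without a PTA are
#' dropped with a warning giving the count.
#'
#' @param ph phenotype data.frame with columns id, y, pta.
#' @return data.frame with columns id, y, pta, y_star.
#' @export
adjust_phenotypes <- function(ph) {
  miss <- is.na(ph$pta) | is.na(ph$y)
  if (any(miss)) {
    warning("excluded ", sum(miss), " cow(s) with missing phenotype or PTA")
    ph <- ph[!miss, , drop = FALSE]
  }
  ph$y_star <- ph$y - 2 * ph$pta
  ph
}

#' Per-SNP genotype-class means fit
#'
#' The cell-means realization of the single-SNP fixed-effect fit on the
#' polygenic-adjusted phenotype: the estimate for each genotype class is
#' its class mean of y*, which reproduces every estimable contrast of the
#' rank-deficient (intercept + indicators) least-squares solution. The
#' residual variance is v^2 = RSS / (n - k) with k the number of
#' non-empty classes.
#'
#' @param y_star numeric vector of adjusted phenotypes.
#' @param codes genotype codes (0/1/2 = copies of allele 1; NA dropped
#'   together with the cow).
#' @return object of class `agls_fit`: ghat (g11, g12, g22; NA for empty
#'   classes), counts (n11, n12, n22), n, k, v2, df.
#' @export
agls_fit <- function(y_star, codes) {
  ok <- !is.na(y_star) & !is.na(codes)
  y <- y_star[ok]; g <- codes[ok]
  cls <- c(2L, 1L, 0L)  # 11, 12, 22
  counts <- vapply(cls, function(c) sum(g == c), integer(1))
  names(counts) <- c("n11", "n12", "n22")
  k <- sum(counts > 0L)
  n <- sum(counts)
  if (k < 2L) stop("monomorphic SNP: fewer than 2 genotype classes observed")
  if (n <= k) stop("insufficient observations: n <= number of genotype classes")
  ghat <- vapply(cls, function(c) if (any(g == c)) mean(y[g == c]) else NA_real_,
                 numeric(1))
  names(ghat) <- c("g11", "g12", "g22")
  fitted <- ghat[match(g, cls)]
  rss <- sum((y - fitted)^2)
  v2 <- rss / (n - k)
  structure(list(ghat = ghat, counts = counts, n = n, k = k,
                 v2 = v2, df = n - k, rss = rss),
            class = "agls_fit")
}

#' @export
print.agls_fit <- function(x, ...) {
  cat("Genotype-class means fit (AGLS)\n")
  print(data.frame(class = c("A1A1", "A1A2", "A2A2"),
                   mean = unname(x$ghat), n = unname(x$counts)))
  cat(sprintf("n = %d, k = %d, v^2 = %.6g (df = %d)\n", x$n, x$k, x$v2, x$df))
  invisible(x)
}

#' @export
coef.agls_fit <- function(object, ...) object$ghat

contrast_result <- function(kind, s, L, se, t, df, log10_inv_p) {
  structure(list(kind = kind, s = s, L = L, se = se, t = t, df = df,
                 log10_inv_p = log10_inv_p),
            class = "agls_contrast")
}

#' @export
print.agls_contrast <- function(x, ...) {
  cat(sprintf("%s contrast: L = %.6g (se %.6g), t = %.4g, log10(1/p) = %.4g\n",
              x$kind, x$L, x$se, x$t, x$log10_inv_p))
  invisible(x)
}

#' Additive contrast test
#'
#' Tests the average effect of gene substitution with contrast
#' coefficients s_a = (P11/p1, 0.5 P12 (p2 - p1)/(p1 p2), -P22/p2) on the
#' fitted genotype-class means. The coefficients remain valid under
#' Hardy-Weinberg disequilibrium and reduce to (p1, p2 - p1, -p2) under
#' HWE. var(L) = v^2 * sum(s_c^2 / n_c); the two-sided p-value uses a t
#' reference with n - k degrees of freedom. A perfect fit (v^2 = 0 with
#' L != 0) is reported as log10(1/p) = Inf.
#'
#' @param fit an [agls_fit()].
#' @param fr a [snp_frequencies()] object; by default recomputed from the
#'   fit's own class counts (self-consistent complete-case frequencies).
#' @return object of class `agls_contrast`.
#' @export
additive_contrast <- function(fit, fr = snp_frequencies(counts = fit$counts)) {
  if (fr$p1 <= 0 || fr$p2 <= 0) stop("additive contrast undefined for a monomorphic SNP")
  s <- c(fr$P11 / fr$p1,
         0.5 * fr$P12 * (fr$p2 - fr$p1) / (fr$p1 * fr$p2),
         -fr$P22 / fr$p2)
  contrast_t(fit, s, "additive")
}

#' Dominance contrast test
#'
#' Tests the dominance effect delta = g12 - (g11 + g22)/2 with
#' coefficients s_d = (-0.5, 1, -0.5); var(L) = v^2 (0.25/n11 + 1/n12 +
#' 0.25/n22). Requires all three genotype classes; otherwise the test is
#' undefined and NA is returned with a warning.
#'
#' @inheritParams additive_contrast
#' @return object of class `agls_contrast` (fields NA when undefined).
#' @export
dominance_contrast <- function(fit) {
  if (any(fit$counts == 0L)) {
    warning("dominance contrast undefined: empty genotype class")
    return(contrast_result("dominance", c(-0.5, 1, -0.5), NA_real_, NA_real_,
                           NA_real_, fit$df, NA_real_))
  }
  contrast_t(fit, c(-0.5, 1, -0.5), "dominance")
}

# shared t machinery; s must be 0 on empty classes
contrast_t <- function(fit, s, kind) {
  use <- fit$counts > 0L
  if (any(abs(s[!use]) > 1e-12)) {
    stop(kind, " contrast places weight on an empty genotype class")
  }
  g <- ifelse(use, fit$ghat, 0)
  L <- sum(s * g)
  varL <- fit$v2 * sum(s[use]^2 / fit$counts[use])
  if (varL == 0) {
    # exact fit: infinite-significance sentinel unless the contrast is null
    t <- if (abs(L) < 1e-300) 0 else Inf
    lp <- if (t == 0) 0 else Inf
    return(contrast_result(kind, s, L, 0, t, fit$df, lp))
  }
  se <- sqrt(varL)
  t <- abs(L) / se
  contrast_result(kind, s, L, se, t, fit$df, log10_inv_p(t, fit$df))
}

#' Significance on the log10(1/p) scale
#'
#' Two-sided p-value of a |t| statistic, returned as -log10(p), computed
#' on the log scale so extreme statistics (log10(1/p) ~ 50) stay finite
#' and accurate.
#'
#' @param t non-negative t statistic (|t|).
#' @param df degrees of freedom (>= 1).
#' @return log10(1/p); 0 when t = 0, Inf when t = Inf.
#' @export
log10_inv_p <- function(t, df) {
  stopifnot(all(df >= 1))
  lp <- stats::pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE) + log(2)
  -lp / log(10)
}

#' Genome-wide significance threshold
#'
#' Bonferroni correction alpha/m by default; a fixed log10(1/p) cutoff
#' (e.g. 8, i.e. p = 1e-8) overrides it when supplied.
#'
#' @param m number of tests (SNPs).
#' @param alpha genome-wide false-positive rate (default 0.05).
#' @param fixed_log10p optional fixed -log10 p cutoff.
#' @return p-value threshold (numeric scalar).
#' @export
significance_threshold <- function(m, alpha = 0.05, fixed_log10p = NULL) {
  stopifnot(m >= 1)
  if (!is.null(fixed_log10p)) return(10^(-fixed_log10p))
  alpha / m
}
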