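#' Genome scan with AGLS additive and dominance tests
#'
#' For every SNP passing the MAF filter: complete-case frequencies,
#' genotype-class means fit on y* = y - 2 PTA, additive and dominance
#' contrast t-tests, allelic-effect and dominance-deviation
#' decompositions, dominance classification, and the negative impact of
#' the homozygous recessive genotype (class means of the original y;
#' computed when all three genotype classes are observed). Rows are
#' ordered by (chromosome, position).
#'
#' @param gm a [genotype_matrix()].
#' @param ph phenotype data.frame (id, y, pta); cows are joined to the
#'   genotype rows by id and unmatched cows dropped with a message.
#' @param maf MAF filter threshold (default 0.05); NULL to skip.
#' @param alpha genome-wide false positive rate for the Bonferroni
#'   threshold (default 0.05).
#' @param fixed_log10p optional fixed log10(1/p) significance cutoff
#'   overriding Bonferroni (e.g. 8).
#' @param dominance_tol relative tolerance for the complete-dominance
#'   call (see [classify_dominance()]).
#' @return object of class `agls_scan`: `results` data.frame (one row per
#'   SNP), `threshold` (p scale), `log10p_threshold`, `n_cows`, `n_snps`,
#'   `settings`.
#' @export
agls_scan <- function(gm, ph, maf = 0.05, alpha = 0.05, fixed_log10p = NULL,
                      dominance_tol = 0.05) {
  ph <- adjust_phenotypes(ph)
  common <- intersect(ph$id, rownames(gm$codes))
  if (length(common) == 0L) stop("no cows shared between genotype and phenotype tables")
  dropped <- nrow(ph) - length(common)
  if (dropped > 0L) message("agls_scan: ", dropped, " phenotyped cow(s) have no genotypes")
  ph <- ph[match(common, ph$id), , drop = FALSE]
  if (!is.null(maf)) gm <- filter_maf(gm, maf)
  codes <- gm$codes[common, , drop = FALSE]
  m <- ncol(codes)
  if (m == 0L) stop("no SNPs left after filtering")
  thr <- significance_threshold(m, alpha, fixed_log10p)
  lthr <- -log10(thr)

  st <- scan_stats(codes, ph$y_star, ph$y)
  res <- vector("list", m)
  for (j in seq_len(m)) {
    res[[j]] <- scan_one(st, j, gm$map[j, ], dominance_tol, lthr)
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  structure(list(results = results, threshold = thr, log10p_threshold = lthr,
                 n_cows = length(common), n_snps = m,
                 settings = list(maf = maf, alpha = alpha,
                                 fixed_log10p = fixed_log10p,
                                 dominance_tol = dominance_tol)),
            class = "agls_scan")
}

# vectorized per-class sufficient statistics for all SNPs at once
scan_stats <- function(codes, y_star, y_raw) {
  out <- list(n = matrix(0, ncol(codes), 3), sum = matrix(0, ncol(codes), 3),
              sum2 = matrix(0, ncol(codes), 3), ysum = matrix(0, ncol(codes), 3))
  for (c in c(2L, 1L, 0L)) {
    idx <- 3L - c  # 1 = class 11, 2 = 12, 3 = 22
    mask <- !is.na(codes) & codes == c
    out$n[, idx] <- colSums(mask)
    out$sum[, idx] <- colSums(y_star * mask)
    out$sum2[, idx] <- colSums(y_star^2 * mask)
    out$ysum[, idx] <- colSums(y_raw * mask)
  }
  out
}

scan_one <- function(st, j, maprow, dominance_tol, lthr) {
  counts <- st$n[j, ]
  n <- sum(counts)
  k <- sum(counts > 0L)
  ghat <- ifelse(counts > 0L, st$sum[j, ] / pmax(counts, 1L), NA_real_)
  names(ghat) <- c("g11", "g12", "g22")
  names(counts) <- c("n11", "n12", "n22")
  rss <- sum(st$sum2[j, ]) - sum(ifelse(counts > 0L, counts * ghat^2, 0))
  rss <- max(rss, 0)
  blank <- data.frame(snp = maprow$snp, chrom = maprow$chrom, pos = maprow$pos,
                      n = n, n11 = counts[1L], n12 = counts[2L], n22 = counts[3L],
                      stringsAsFactors = FALSE)
  if (k < 2L || n <= k) {
    na <- rep(NA_real_, 1)
    return(cbind(blank, data.frame(
      p1 = na, alpha = na, ae_pos = na, f_pos = na, allele_pos = NA_integer_,
      ae_neg = na, f_neg = na, allele_neg = NA_integer_,
      log10p_add = na, sig_add = NA,
      delta = na, g11 = ghat[1L], g12 = ghat[2L], g22 = ghat[3L],
      d11 = na, d12 = na, d22 = na, classification = NA_character_,
      dominant_allele = NA_integer_, recessive_allele = NA_integer_,
      y_rr = na, y_rd = na, y_dd = na, NI = na, log10p_dom = na, sig_dom = NA,
      stringsAsFactors = FALSE)))
  }
  fit <- structure(list(ghat = ghat, counts = counts, n = n, k = k,
                        v2 = rss / (n - k), df = n - k, rss = rss),
                   class = "agls_fit")
  fr <- snp_frequencies(counts = counts)
  ca <- additive_contrast(fit, fr)
  add <- additive_decomposition(fit, fr)
  if (all(counts > 0L)) {
    cd <- dominance_contrast(fit)
    dd <- dominance_decomposition(fit, add, fr)
    cl <- classify_dominance(dd, fit, dominance_tol)
    # original-phenotype class means, oriented by the recessive allele
    ymeans <- st$ysum[j, ] / counts
    rr_idx <- if (cl$recessive_allele == 1L) 1L else 3L
    ni <- ymeans[rr_idx] - (ymeans[2L] + ymeans[4L - rr_idx]) / 2
    y_rr <- ymeans[rr_idx]; y_rd <- ymeans[2L]; y_dd <- ymeans[4L - rr_idx]
    l10d <- cd$log10_inv_p; delta <- cd$L
    dom_al <- cl$dominant_allele; rec_al <- cl$recessive_allele
    klass <- cl$classification
    d <- c(dd$d11, dd$d12, dd$d22)
  } else {
    delta <- NA_real_; l10d <- NA_real_; ni <- NA_real_
    y_rr <- y_rd <- y_dd <- NA_real_
    dom_al <- rec_al <- NA_integer_; klass <- NA_character_
    d <- rep(NA_real_, 3)
  }
  cbind(blank, data.frame(
    p1 = fr$p1, alpha = add$alpha, ae_pos = add$ae_pos, f_pos = add$f_pos,
    allele_pos = add$allele_pos, ae_neg = add$ae_neg, f_neg = add$f_neg,
    allele_neg = add$allele_neg,
    log10p_add = ca$log10_inv_p, sig_add = ca$log10_inv_p >= lthr,
    delta = delta, g11 = ghat[1L], g12 = ghat[2L], g22 = ghat[3L],
    d11 = d[1L], d12 = d[2L], d22 = d[3L], classification = klass,
    dominant_allele = dom_al, recessive_allele = rec_al,
    y_rr = y_rr, y_rd = y_rd, y_dd = y_dd, NI = ni,
    log10p_dom = l10d, sig_dom = if (is.na(l10d)) NA else l10d >= lthr,
    stringsAsFactors = FALSE))
}

#' @export
print.agls_scan <- function(x, ...) {
  cat("AGLS genome scan:", x$n_snps, "SNPs,", x$n_cows, "cows\n")
  cat(sprintf("significance threshold: log10(1/p) >= %.3f\n", x$log10p_threshold))
  cat("significant additive effects:", sum(x$results$sig_add, na.rm = TRUE), "\n")
  cat("significant dominance effects:", sum(x$results$sig_dom, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.agls_scan <- function(object, n_top = 10L, ...) {
  r <- object$results
  out <- list(n_snps = object$n_snps, n_cows = object$n_cows,
              log10p_threshold = object$log10p_threshold,
              n_sig_add = sum(r$sig_add, na.rm = TRUE),
              n_sig_dom = sum(r$sig_dom, na.rm = TRUE),
              top_additive = rank_top(object, n = n_top, by = "additive"),
              top_dominance = rank_top(object, n = n_top, by = "dominance"))
  class(out) <- "summary.agls_scan"
  out
}

#' @export
print.summary.agls_scan <- function(x, ...) {
  cat(sprintf("AGLS scan: %d SNPs, %d cows; threshold log10(1/p) >= %.3f\n",
              x$n_snps, x$n_cows, x$log10p_threshold))
  cat(sprintf("significant: %d additive, %d dominance\n", x$n_sig_add, x$n_sig_dom))
  cat("\ntop additive effects:\n")
  print(x$top_additive[, c("snp", "chrom", "pos", "alpha", "log10p_add")])
  cat("\ntop dominance effects:\n")
  print(x$top_dominance[, c("snp", "chrom", "pos", "delta", "NI", "log10p_dom")])
  invisible(x)
}

#' Manhattan plot of a scan
#'
#' @param x an [agls_scan()] object.
#' @param by "additive" or "dominance".
#' @param ... passed to [graphics::plot()].
#' @export
plot.agls_scan <- function(x, by = c("additive", "dominance"), ...) {
  by <- match.arg(by)
  md <- manhattan_data(x, by)
  col <- c("grey30", "steelblue")[1 + chrom_rank(md$chrom) %% 2]
  graphics::plot(md$cum_pos, md$log10_inv_p, pch = 16, cex = 0.5, col = col,
                 xlab = "genome position", ylab = "log10(1/p)",
                 main = paste(by, "effects"), ...)
  graphics::abline(h = x$log10p_threshold, lty = 2, col = "red")
  invisible(md)
}

#' Rank the top effects of a scan
#'
#' Descending log10(1/p); ties (and the overall ordering of equal values)
#' broken deterministically by (chromosome, position). SNPs whose test is
#' undefined (NA) are excluded.
#'
#' @param scan an `agls_scan` (or its `results` data.frame).
#' @param n number of rows to keep (the full eligible panel if fewer).
#' @param by "additive" or "dominance".
#' @return the ranked subset of the results with a `rank` column.
#' @export
rank_top <- function(scan, n = 300L, by = c("additive", "dominance")) {
  by <- match.arg(by)
  r <- if (inherits(scan, "agls_scan")) scan$results else scan
  stat <- if (by == "additive") r$log10p_add else r$log10p_dom
  keep <- !is.na(stat)
  r <- r[keep, , drop = FALSE]
  stat <- stat[keep]
  ord <- order(-stat, chrom_rank(r$chrom), r$pos)
  r <- r[ord, , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  utils::head(r, n)
}

#' Annotate scan rows with candidate genes
#'
#' A SNP inside an interval gets the gene name and flag "in". Otherwise,
#' when two flanking genes are both within `window`, the label is the
#' hyphenated intergenic pair "left-right"; else the nearest interval
#' within `window` labels the SNP with flag "u" (upstream) or "d"
#' (downstream), decided by the gene's strand when present and by
#' coordinate order (with flag suffix "*", strandless) otherwise.
#'
#' @param rows scan results data.frame (needs chrom, pos).
#' @param intervals gene intervals from [read_gene_intervals()]
#'   (BED convention: 0-based half-open).
#' @param window maximum distance (bp) for a gene label (default 1 Mb).
#' @return `rows` with columns `gene` and `gene_flag` added.
#' @export
annotate_genes <- function(rows, intervals, window = 1e6) {
  rows$gene <- ""
  rows$gene_flag <- ""
  for (i in seq_len(nrow(rows))) {
    iv <- intervals[intervals$chrom == rows$chrom[i], , drop = FALSE]
    if (nrow(iv) == 0L) next
    pos0 <- rows$pos[i] - 1L  # SNP map is 1-based; compare on 0-based scale
    inside <- which(iv$start <= pos0 & pos0 < iv$end)
    if (length(inside)) {
      rows$gene[i] <- iv$name[inside[1L]]
      rows$gene_flag[i] <- "in"
      next
    }
    left <- which(iv$end <= pos0)
    right <- which(iv$start > pos0)
    dl <- if (length(left)) pos0 - max(iv$end[left]) else Inf
    dr <- if (length(right)) min(iv$start[right]) - pos0 else Inf
    if (dl <= window && dr <= window) {
      lg <- iv$name[left[which.max(iv$end[left])]]
      rg <- iv$name[right[which.min(iv$start[right])]]
      rows$gene[i] <- paste0(lg, "-", rg)
      rows$gene_flag[i] <- "between"
      next
    }
    if (min(dl, dr) > window) next
    if (dl <= dr) {
      gidx <- left[which.max(iv$end[left])]
      after <- TRUE
    } else {
      gidx <- right[which.min(iv$start[right])]
      after <- FALSE
    }
    strand <- iv$strand[gidx]
    rows$gene[i] <- iv$name[gidx]
    if (!is.na(strand) && strand %in% c("+", "-")) {
      # downstream = past the gene in its transcription direction
      down <- (after && strand == "+") || (!after && strand == "-")
      rows$gene_flag[i] <- if (down) "d" else "u"
    } else {
      rows$gene_flag[i] <- paste0(if (after) "d" else "u", "*")
    }
  }
  rows
}

#' Flanking-SNP significance report
#'
#' For each significant SNP, the nearest flanking SNP on each side (same
#' chromosome) whose statistic falls below the threshold, with distances
#' in bp; one-sided records at chromosome edges. The mean distance over
#' all recorded flanks summarizes the panel's fine-mapping resolution.
#'
#' @param scan an `agls_scan` or its results data.frame.
#' @param by "additive" or "dominance".
#' @param log10p_threshold significance cutoff on the log10(1/p) scale;
#'   defaults to the scan's own threshold.
#' @return list: `flanks` data.frame (snp, chrom, pos, left/right flank
#'   ids and distances) and `mean_distance` (bp, over non-missing flanks).
#' @export
flanking_significance <- function(scan, by = c("additive", "dominance"),
                                  log10p_threshold = NULL) {
  by <- match.arg(by)
  r <- if (inherits(scan, "agls_scan")) scan$results else scan
  if (is.null(log10p_threshold)) {
    log10p_threshold <- if (inherits(scan, "agls_scan")) scan$log10p_threshold else
      stop("log10p_threshold required when passing a bare data.frame")
  }
  stat <- if (by == "additive") r$log10p_add else r$log10p_dom
  ord <- order(chrom_rank(r$chrom), r$pos)
  r <- r[ord, , drop = FALSE]; stat <- stat[ord]
  sig <- !is.na(stat) & stat >= log10p_threshold
  out <- list()
  for (i in which(sig)) {
    same <- r$chrom == r$chrom[i]
    insig <- same & !sig & !is.na(stat)
    lefts <- which(insig & r$pos < r$pos[i])
    rights <- which(insig & r$pos > r$pos[i])
    li <- if (length(lefts)) lefts[which.max(r$pos[lefts])] else NA_integer_
    ri <- if (length(rights)) rights[which.min(r$pos[rights])] else NA_integer_
    if (is.na(li) && is.na(ri)) next  # no insignificant flank anywhere
    out[[length(out) + 1L]] <- data.frame(
      snp = r$snp[i], chrom = r$chrom[i], pos = r$pos[i],
      left_snp = if (is.na(li)) NA_character_ else r$snp[li],
      left_dist = if (is.na(li)) NA_integer_ else r$pos[i] - r$pos[li],
      right_snp = if (is.na(ri)) NA_character_ else r$snp[ri],
      right_dist = if (is.na(ri)) NA_integer_ else r$pos[ri] - r$pos[i],
      stringsAsFactors = FALSE)
  }
  flanks <- if (length(out)) do.call(rbind, out) else
    data.frame(snp = character(), chrom = character(), pos = integer(),
               left_snp = character(), left_dist = integer(),
               right_snp = character(), right_dist = integer(),
               stringsAsFactors = FALSE)
  dists <- c(flanks$left_dist, flanks$right_dist)
  list(flanks = flanks, mean_distance = mean(dists, na.rm = TRUE))
}

#' Linkage disequilibrium between two SNPs
#'
#' Pearson correlation of genotype codes over cows with both SNPs
#' non-missing.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_i,snp_j SNP ids.
#' @return list(r, r2, n); r is NA when either SNP has zero variance.
#' @export
ld_r <- function(gm, snp_i, snp_j) {
  a <- gm$codes[, snp_i]; b <- gm$codes[, snp_j]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) stop("fewer than 2 cows with both SNPs non-missing")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    return(list(r = NA_real_, r2 = NA_real_, n = length(a)))
  }
  r <- stats::cor(a, b)
  list(r = r, r2 = r^2, n = length(a))
}

manhattan_data <- function(scan, by = c("additive", "dominance")) {
  by <- match.arg(by)
  r <- if (inherits(scan, "agls_scan")) scan$results else scan
  ord <- order(chrom_rank(r$chrom), r$pos)
  r <- r[ord, , drop = FALSE]
  chroms <- unique(r$chrom)
  offset <- 0
  cum <- numeric(nrow(r))
  for (ch in chroms) {
    idx <- r$chrom == ch
    cum[idx] <- offset + r$pos[idx]
    offset <- offset + max(r$pos[idx])
  }
  data.frame(chrom = r$chrom, pos = r$pos, cum_pos = cum,
             test = rep(by, nrow(r)),
             log10_inv_p = if (by == "additive") r$log10p_add else r$log10p_dom,
             stringsAsFactors = FALSE)
}

#' Export Manhattan-plot data as TSV
#'
#' Writes (chrom, pos, cum_pos, test, log10_inv_p) with a cumulative
#' genome coordinate; chromosomes ordered numerically (1-29, 30, 31,
#' then non-numeric labels).
#'
#' @param scan an `agls_scan` or results data.frame.
#' @param path output TSV.
#' @param by "additive", "dominance", or "both".
#' @return invisibly, the exported data.frame.
#' @export
manhattan_export <- function(scan, path, by = c("additive", "dominance", "both")) {
  by <- match.arg(by)
  md <- if (by == "both") {
    rbind(manhattan_data(scan, "additive"), manhattan_data(scan, "dominance"))
  } else {
    manhattan_data(scan, by)
  }
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(md)
}

#' Write the standard scan output files
#'
#' `additive.tsv` and `dominance.tsv` (ranked effect tables),
#' `flanks.tsv`, `manhattan.tsv` and `summary.json` in `dir`.
#'
#' @param scan an `agls_scan`.
#' @param dir output directory.
#' @param n_top rows in the ranked tables.
#' @return invisibly, the file paths.
#' @export
write_scan <- function(scan, dir, n_top = 300L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  add_cols <- c("rank", "snp", "chrom", "pos", "alpha", "allele_pos", "ae_pos",
                "f_pos", "allele_neg", "ae_neg", "f_neg", "log10p_add")
  dom_cols <- c("rank", "snp", "chrom", "pos", "y_dd", "y_rd", "y_rr",
                "delta", "NI", "classification", "log10p_dom")
  ta <- rank_top(scan, n_top, "additive")
  td <- rank_top(scan, n_top, "dominance")
  utils::write.table(ta[, intersect(add_cols, names(ta))],
                     file.path(dir, "additive.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(td[, intersect(dom_cols, names(td))],
                     file.path(dir, "dominance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fl <- flanking_significance(scan, "dominance")
  utils::write.table(fl$flanks, file.path(dir, "flanks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manhattan_export(scan, file.path(dir, "manhattan.tsv"), "both")
  jsonlite::write_json(list(n_snps = scan$n_snps, n_cows = scan$n_cows,
                            log10p_threshold = scan$log10p_threshold,
                            n_sig_add = sum(scan$results$sig_add, na.rm = TRUE),
                            n_sig_dom = sum(scan$results$sig_dom, na.rm = TRUE),
                            mean_flank_distance = fl$mean_distance,
                            settings = scan$settings),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file.path(dir, c("additive.tsv", "dominance.tsv", "flanks.tsv",
                             "manhattan.tsv", "summary.json")))
}
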