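#' Genotype matrix container
#'
#' Holds cow-by-SNP genotype codes (0/1/2 = copies of allele 1, NA =
#' missing) together with the SNP map. SNPs are stored sorted by
#' (chromosome, position); chromosome labels that look numeric
#' (including "30" and "31") sort numerically, others after.
#'
#' @param codes integer/numeric matrix, rows = cows, columns = SNPs.
#'   Row and column names are the cow and SNP ids (taken from `map` when
#'   absent).
#' @param map data.frame with columns `snp`, `chrom`, `pos`, `allele1`,
#'   `allele2`, one row per column of `codes`.
#' @return object of class `genotype_matrix`: list(codes, map).
#' @export
genotype_matrix <- function(codes, map) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp", "chrom", "pos", "allele1", "allele2")
  if (!all(need %in% names(map))) {
    stop("SNP map must have columns: ", paste(need, collapse = ", "))
  }
  map$snp <- as.character(map$snp)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != ncol(codes)) stop("map rows must match genotype columns")
  if (anyDuplicated(map$snp)) stop("duplicated SNP ids in map")
  if (is.null(rownames(codes))) rownames(codes) <- paste0("cow", seq_len(nrow(codes)))
  if (anyDuplicated(rownames(codes))) stop("duplicated cow ids")
  colnames(codes) <- map$snp
  if (any(map$pos < 1L, na.rm = TRUE)) stop("SNP positions must be >= 1")
  bad <- codes[!is.na(codes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  ord <- order(chrom_rank(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  codes <- codes[, ord, drop = FALSE]
  structure(list(codes = codes, map = map), class = "genotype_matrix")
}

chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  mx <- if (all(is.na(num))) 0 else max(num, na.rm = TRUE)
  lab <- sort(unique(chrom[is.na(num)]))
  # non-numeric labels ordered lexicographically after numeric ones
  ifelse(is.na(num), mx + match(chrom, lab), num)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$codes), "cows x", ncol(x$codes), "SNPs\n")
  cat("chromosomes:", paste(unique(x$map$chrom), collapse = " "), "\n")
  miss <- mean(is.na(x$codes))
  cat(sprintf("missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Read genotypes from TSV or VCF
#'
#' TSV format (as written by [write_genotypes()]): first column `id`,
#' remaining columns one per SNP, codes 0/1/2 counting copies of allele 1
#' of the accompanying map, '.' for missing; `map_path` points to the SNP
#' map TSV (`snp, chrom, pos, allele1, allele2`). VCF: codes count copies
#' of REF (allele 1 = REF, allele 2 = ALT); non-biallelic records are
#' skipped with a warning giving the count.
#'
#' @param path genotype file.
#' @param format "tsv" or "vcf".
#' @param map_path SNP map TSV (required for `format = "tsv"`).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), map_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (is.null(map_path)) stop("map_path is required for TSV genotypes")
    g <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c(".", "NA"), colClasses = "character")
    map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
    ids <- g[[1L]]
    codes <- as.matrix(g[, -1L, drop = FALSE])
    codes <- matrix(suppressWarnings(as.integer(codes)), nrow = nrow(g),
                    dimnames = list(ids, colnames(g)[-1L]))
    if (!setequal(colnames(codes), map$snp)) {
      stop("SNP ids in genotype TSV do not match the map")
    }
    codes <- codes[, map$snp, drop = FALSE]
    genotype_matrix(codes, map)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(vcf)
    n_skip <- sum(!bi)
    if (n_skip > 0L) {
      warning("skipped ", n_skip, " non-biallelic VCF record(s)")
      vcf <- vcf[bi, ]
    }
    fix <- vcfR::getFIX(vcf)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    # copies of REF from the two allele fields, phase-agnostic
    a <- substr(gt, 1L, 1L)
    b <- substr(gt, 3L, 3L)
    codes <- (a == "0") + (b == "0")
    codes[a == "." | b == "." | is.na(gt)] <- NA
    codes <- t(codes)  # cows x SNPs
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    if (anyDuplicated(ids)) stop("duplicated SNP ids in VCF")
    map <- data.frame(snp = ids, chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      allele1 = fix[, "REF"], allele2 = fix[, "ALT"],
                      stringsAsFactors = FALSE)
    colnames(codes) <- ids
    genotype_matrix(codes, map)
  }
}

#' Write genotypes and SNP map as TSV
#'
#' @param gm a [genotype_matrix()].
#' @param geno_path output TSV for codes ('.' = missing).
#' @param map_path output TSV for the SNP map.
#' @export
write_genotypes <- function(gm, geno_path, map_path) {
  codes <- gm$codes
  out <- data.frame(id = rownames(codes), codes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tmp <- as.matrix(format(codes))
  tmp[is.na(codes)] <- "."
  out[, -1L] <- tmp
  utils::write.table(out, geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(geno_path, map_path))
}

#' Read a phenotype table
#'
#' CSV with columns `id`, `y` (yield deviation, months) and optionally
#' `pta` (predicted transmitting ability, months).
#'
#' @param path CSV file.
#' @return data.frame with columns id, y, pta.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty phenotype file: ", path)
  if (!all(c("id", "y") %in% names(df))) stop("phenotype file needs columns id, y")
  if (anyDuplicated(df$id)) stop("duplicated cow ids in phenotype file")
  if (!all(is.finite(df$y))) stop("non-finite phenotypic values")
  if (is.null(df$pta)) df$pta <- NA_real_
  df[, c("id", "y", "pta")]
}

#' Read gene intervals from BED
#'
#' Standard BED conventions: 0-based half-open `[start, end)`, optional
#' name/score/strand columns. Returned coordinates keep the BED
#' convention; `bed_to_1based()` converts to inclusive 1-based.
#'
#' @param path BED file (3-6 columns, tab/space separated, no header).
#' @return data.frame with chrom, start, end, name, strand.
#' @export
read_gene_intervals <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least chrom, start, end")
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    name = if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_,
                    strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("BED intervals must satisfy start < end")
  out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
}

#' @rdname read_gene_intervals
#' @param intervals data.frame from [read_gene_intervals()].
#' @export
bed_to_1based <- function(intervals) {
  intervals$start <- intervals$start + 1L
  intervals
}

#' Per-SNP allele and genotype frequencies
#'
#' Frequencies are computed from the observed non-missing genotype counts
#' with no Hardy-Weinberg assumption. The conditional genotype
#' frequencies (P11/p1, P12/p1, P12/p2, P22/p2) used by the allelic-mean
#' decomposition are NA when the conditioning allele is absent.
#'
#' @param gm a [genotype_matrix()], or NULL when `counts` given.
#' @param snp SNP id.
#' @param counts alternative direct entry: integer vector
#'   `c(n11, n12, n22)` of genotype counts (codes 2, 1, 0).
#' @return object of class `snp_freq`: counts, genotype frequencies
#'   P11/P12/P22, allele frequencies p1/p2, conditionals P11.1, P12.1,
#'   P12.2, P22.2, and n_obs.
#' @export
snp_frequencies <- function(gm = NULL, snp = NULL, counts = NULL) {
  if (is.null(counts)) {
    codes <- gm$codes[, snp]
    codes <- codes[!is.na(codes)]
    if (length(codes) == 0L) stop("SNP ", snp, " has no non-missing genotypes")
    counts <- c(n11 = sum(codes == 2L), n12 = sum(codes == 1L),
                n22 = sum(codes == 0L))
  }
  counts <- as.integer(counts)
  n <- sum(counts)
  if (n == 0L) stop("no observations")
  P11 <- counts[1L] / n; P12 <- counts[2L] / n; P22 <- counts[3L] / n
  p1 <- P11 + P12 / 2
  p2 <- 1 - p1
  cond <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(n_obs = n, n11 = counts[1L], n12 = counts[2L], n22 = counts[3L],
                 P11 = P11, P12 = P12, P22 = P22, p1 = p1, p2 = p2,
                 P11.1 = cond(P11, p1), P12.1 = cond(P12, p1),
                 P12.2 = cond(P12, p2), P22.2 = cond(P22, p2)),
            class = "snp_freq")
}

#' @export
print.snp_freq <- function(x, ...) {
  cat(sprintf("n=%d  counts (11,12,22) = (%d,%d,%d)\n", x$n_obs, x$n11, x$n12, x$n22))
  cat(sprintf("p1=%.4f p2=%.4f  P11=%.4f P12=%.4f P22=%.4f\n",
              x$p1, x$p2, x$P11, x$P12, x$P22))
  invisible(x)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with min(p1, p2) >= threshold, computed from the observed
#' non-missing genotypes; the boundary is inclusive. SNP order is
#' preserved; a message reports the number removed.
#'
#' @param gm a [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]` (default 0.05).
#' @return filtered [genotype_matrix()].
#' @export
filter_maf <- function(gm, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  codes <- gm$codes
  n_obs <- colSums(!is.na(codes))
  s <- colSums(codes, na.rm = TRUE)
  p1 <- ifelse(n_obs > 0, s / (2 * n_obs), NA_real_)
  maf <- pmin(p1, 1 - p1)
  keep <- !is.na(maf) & maf >= threshold
  removed <- sum(!keep)
  if (removed > 0L) message("filter_maf: removed ", removed, " of ", length(keep), " SNPs")
  structure(list(codes = codes[, keep, drop = FALSE],
                 map = {m <- gm$map[keep, , drop = FALSE]; rownames(m) <- NULL; m}),
            class = "genotype_matrix")
}
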