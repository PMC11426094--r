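# shared fixture builders (all data generated in code)

# genotype_matrix from a bare code matrix on one chromosome
make_gm <- function(codes, chrom = "1", pos = NULL, allele1 = "A", allele2 = "B") {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  colnames(codes) <- paste0("s", seq_len(m))
  if (is.null(rownames(codes))) rownames(codes) <- paste0("c", seq_len(nrow(codes)))
  map <- data.frame(snp = colnames(codes), chrom = rep_len(chrom, m),
                    pos = pos, allele1 = rep_len(allele1, m),
                    allele2 = rep_len(allele2, m), stringsAsFactors = FALSE)
  genotype_matrix(codes, map)
}

# K independent full-sib families: 2K founders, K matings, offspring each
sib_pedigree <- function(K, n_offspring = 2L) {
  fid <- paste0("f", seq_len(2L * K))
  oid <- paste0("o", seq_len(K * n_offspring))
  sire <- rep(fid[seq_len(K) * 2L - 1L], each = n_offspring)
  dam <- rep(fid[seq_len(K) * 2L], each = n_offspring)
  pedigree(c(fid, oid), c(rep(NA, 2L * K), sire), c(rep(NA, 2L * K), dam))
}

# minimal uncompressed VCF text with given genotype strings
write_test_vcf <- function(path, gts, ids, chrom, pos, ref, alt, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(ids), function(i) {
    paste(c(chrom[i], pos[i], ids[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gts[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}
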