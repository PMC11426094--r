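#' Recessive-genotype screening panel
#'
#' A panel is a data.frame with one row per SNP: `snp`, `recessive_allele`
#' (1 or 2, i.e. which mapped allele is recessive), `ni` (negative impact,
#' months; must be < 0 for inclusion) and `q` (recessive allele
#' frequency).
#'
#' @param snp SNP ids.
#' @param recessive_allele integer 1/2 per SNP.
#' @param ni negative impact (months, < 0).
#' @param q recessive allele frequency in (0, 1).
#' @return data.frame of class `recessive_panel`.
#' @export
recessive_panel <- function(snp, recessive_allele, ni, q) {
  stopifnot(all(recessive_allele %in% c(1L, 2L)), all(q > 0), all(q < 1))
  if (any(ni >= 0)) stop("screening panel requires NI < 0 for every SNP")
  structure(data.frame(snp = as.character(snp),
                       recessive_allele = as.integer(recessive_allele),
                       ni = ni, q = q, stringsAsFactors = FALSE),
            class = c("recessive_panel", "data.frame"))
}

#' Build a screening panel from scan results
#'
#' Takes the significant dominance effects with negative NI from an
#' [agls_scan()] result.
#'
#' @param scan an `agls_scan`.
#' @param ni_max inclusion cutoff: NI must be <= ni_max (default -3
#'   months, the "sharply negative" range).
#' @return a [recessive_panel()].
#' @export
panel_from_scan <- function(scan, ni_max = -3) {
  r <- scan$results
  keep <- !is.na(r$sig_dom) & r$sig_dom & !is.na(r$NI) & r$NI <= ni_max
  if (!any(keep)) stop("no significant dominance effects with NI <= ", ni_max)
  r <- r[keep, , drop = FALSE]
  q <- ifelse(r$recessive_allele == 1L, r$p1, 1 - r$p1)
  recessive_panel(r$snp, r$recessive_allele, r$NI, q)
}

#' Heifer cull list
#'
#' Cows homozygous recessive at one or more panel SNPs, with the
#' triggering SNPs per cow. Cows with a missing genotype at a panel SNP
#' (and no rr call elsewhere) are flagged "undetermined", not culled.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [recessive_panel()]; its SNPs must be present in `gm`.
#' @return data.frame (id, status = "cull"/"undetermined", triggers =
#'   comma-separated SNP ids); empty when no cow is affected.
#' @export
heifer_cull_list <- function(gm, panel) {
  miss_snp <- setdiff(panel$snp, colnames(gm$codes))
  if (length(miss_snp)) stop("panel SNPs absent from genotypes: ",
                             paste(miss_snp, collapse = ", "))
  codes <- gm$codes[, panel$snp, drop = FALSE]
  rr_code <- ifelse(panel$recessive_allele == 1L, 2L, 0L)
  rr <- sweep(codes, 2L, rr_code, `==`)
  has_rr <- apply(rr, 1L, function(x) any(x, na.rm = TRUE))
  has_na <- rowSums(is.na(codes)) > 0L
  rows <- which(has_rr | has_na)
  if (!length(rows)) {
    return(data.frame(id = character(), status = character(),
                      triggers = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    id = rownames(codes)[rows],
    status = ifelse(has_rr[rows], "cull", "undetermined"),
    triggers = vapply(rows, function(i) {
      trig <- panel$snp[which(rr[i, ])]
      if (length(trig)) paste(trig, collapse = ",") else
        paste(panel$snp[is.na(codes[i, ])], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Expected fraction of homozygous recessive daughters
#'
#' Mendelian expectations at one SNP. In random-dam mode (dam allele
#' frequency `q`, dams assumed in HWE and not selected at the SNP): an rr
#' sire transmits r with probability 1, so a fraction q of daughters is
#' rr; an rD sire transmits r with probability 1/2, giving q/2; a DD sire
#' gives 0. In dam-class mode the standard Punnett fractions apply.
#'
#' @param sire_class "DD", "rD" or "rr".
#' @param q recessive allele frequency among dams (random-dam mode).
#' @param dam_class optional "DD", "rD" or "rr" (class mode; overrides q).
#' @return probability that a daughter is homozygous recessive.
#' @export
expected_rr_fraction <- function(sire_class, q = NULL, dam_class = NULL) {
  sire_class <- match.arg(sire_class, c("DD", "rD", "rr"))
  p_sire <- switch(sire_class, rr = 1, rD = 0.5, DD = 0)
  if (!is.null(dam_class)) {
    dam_class <- match.arg(dam_class, c("DD", "rD", "rr"))
    p_dam <- switch(dam_class, rr = 1, rD = 0.5, DD = 0)
    return(p_sire * p_dam)
  }
  stopifnot(!is.null(q), q >= 0, q <= 1)
  p_sire * q
}

#' Offspring genotype-class distribution for a mating
#'
#' Punnett probabilities of (DD, rD, rr) offspring for given parental
#' genotype classes.
#'
#' @param sire_class,dam_class "DD", "rD" or "rr".
#' @return named numeric vector (DD, rD, rr) summing to 1.
#' @export
offspring_class_probs <- function(sire_class, dam_class) {
  pr <- function(cl) switch(match.arg(cl, c("DD", "rD", "rr")),
                            rr = 1, rD = 0.5, DD = 0)
  ps <- pr(sire_class); pd <- pr(dam_class)
  c(DD = (1 - ps) * (1 - pd), rD = ps * (1 - pd) + (1 - ps) * pd, rr = ps * pd)
}

#' SNP-guided mating decision
#'
#' Under the heifer-culling assumption, rr dams do not exist in the
#' breeding population (an rr dam is an error). The allowed pairs are
#' exactly those that cannot produce an rr daughter: DD x DD, DD x rD,
#' rD x DD and rr x DD.
#'
#' @param sire_class,dam_class "DD", "rD" or "rr" (dam_class != "rr").
#' @return list of class `mating_decision`: sire_class, dam_class,
#'   allowed (logical), expected_rr (probability).
#' @export
allowed_matings <- function(sire_class, dam_class) {
  sire_class <- match.arg(sire_class, c("DD", "rD", "rr"))
  dam_class <- match.arg(dam_class, c("DD", "rD", "rr"))
  if (dam_class == "rr") {
    stop("rr dam violates the heifer-culling assumption (recessive heifers are culled)")
  }
  p <- unname(offspring_class_probs(sire_class, dam_class)["rr"])
  structure(list(sire_class = sire_class, dam_class = dam_class,
                 allowed = p == 0, expected_rr = p),
            class = "mating_decision")
}

#' @export
print.mating_decision <- function(x, ...) {
  cat(sprintf("%s x %s: %s (expected rr daughters: %.4f)\n", x$sire_class,
              x$dam_class, if (x$allowed) "allowed" else "disallowed",
              x$expected_rr))
  invisible(x)
}

#' Multi-SNP mating feasibility (experimental)
#'
#' A pair is allowed iff it is allowed at every panel SNP (per-SNP AND).
#' Genotype classes are derived from the parents' codes and each SNP's
#' recessive allele; a missing genotype makes the pair "undetermined".
#'
#' @param sire_codes,dam_codes named genotype-code vectors (names = SNP
#'   ids) for one sire and one dam.
#' @param panel a [recessive_panel()].
#' @return list: allowed (TRUE/FALSE/NA), per_snp data.frame.
#' @export
mating_feasible <- function(sire_codes, dam_codes, panel) {
  cls <- function(code, rec) {
    if (is.na(code)) return(NA_character_)
    nr <- if (rec == 1L) code else 2L - code  # copies of the recessive allele
    c("DD", "rD", "rr")[nr + 1L]
  }
  per <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    sc <- cls(sire_codes[[panel$snp[i]]], panel$recessive_allele[i])
    dc <- cls(dam_codes[[panel$snp[i]]], panel$recessive_allele[i])
    ok <- if (is.na(sc) || is.na(dc)) NA else if (dc == "rr") FALSE else
      allowed_matings(sc, dc)$allowed
    data.frame(snp = panel$snp[i], sire_class = sc, dam_class = dc,
               allowed = ok, stringsAsFactors = FALSE)
  }))
  allowed <- if (anyNA(per$allowed)) {
    if (any(!per$allowed, na.rm = TRUE)) FALSE else NA
  } else {
    all(per$allowed)
  }
  list(allowed = allowed, per_snp = per)
}

#' Reference screening panel for productive life in U.S. Holsteins
#'
#' The published panel of SNPs with rare, sharply negative homozygous
#' recessive genotypes for productive life, shipped with the package as
#' a plain-text table of reported genotype-class means, frequencies and
#' negative impacts. By default the two Chr04 SNPs — the only
#' heterozygous-advantage cases, whose use is left to the breeder — are
#' excluded, leaving the 12 recommended culling SNPs.
#'
#' @param include_chr4 include the two Chr04 SNPs (default FALSE).
#' @return list: `panel` (a [recessive_panel()]; recessive allele frequency
#'   q = f_rD/2 + f_rr from the reported genotype frequencies) and
#'   `table` (the full reported table).
#' @export
holstein_recessive_panel <- function(include_chr4 = FALSE) {
  path <- system.file("extdata", "holstein_pl_recessive_snps.tsv",
                      package = "aglscan", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  keep <- if (include_chr4) rep(TRUE, nrow(tab)) else tab$chrom != 4
  sub <- tab[keep, , drop = FALSE]
  q <- sub$f_rd / 2 + sub$f_rr
  # the table reports alleles by nucleotide; allele index 2 = recessive by
  # convention of the shipped map (allele1 = dominant nucleotide)
  pan <- recessive_panel(sub$snp, rep(2L, nrow(sub)), sub$ni, q)
  list(panel = pan, table = tab)
}
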