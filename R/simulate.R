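#' Simulation configuration
#'
#' Parameters of the pedigree / genotype / phenotype generator. Defaults
#' describe a dairy-cattle-like quantitative trait measured in months
#' (low heritability ~ 0.08, phenotypic SD ~ 7.7 months, trait mean ~ 12
#' months), biallelic SNPs with MAF >= 0.05, causal additive effects of
#' a few tenths of a month, and rare sharply negative recessive
#' genotypes.
#'
#' @param n_founders founders (generation 0).
#' @param n_generations generations bred after the founders.
#' @param n_matings sire x dam pairs per generation.
#' @param n_offspring offspring per mating. The default of 1 reflects
#'   dairy practice (one calf per dam per season), giving a
#'   paternal/maternal half-sib structure with few full sibs; raising it
#'   creates sib-dense designs under which the AGLS additive test grows
#'   conservative (see the methods vignette).
#' @param n_snps SNPs simulated.
#' @param maf_range minor-allele-frequency interval for founder SNPs,
#'   within (0, 0.5]; the allele-1 frequency is a draw from this interval
#'   assigned to either allele with equal probability (so p1 covers
#'   (maf, 1 - maf)).
#' @param hwd_f founder within-locus inbreeding coefficient f in `[0, 1)`
#'   controlling departure from Hardy-Weinberg proportions:
#'   P11 = p1^2 + f p1 p2, P12 = 2 p1 p2 (1 - f), P22 = p2^2 + f p1 p2.
#' @param mu trait mean (months).
#' @param sigma_a2,sigma_e2 additive and residual variances (months^2).
#' @param causal_add data.frame(snp, alpha) with an optional `delta`
#'   column: SNP column index, target average effect of gene substitution
#'   and (optionally) a dominance effect, in months. Genotypic values are
#'   (2 alpha, alpha + delta, 0), so delta is exact by construction and
#'   alpha is exact under HWE when delta = 0 (with dominance, the average
#'   effect also carries the frequency-weighted delta term).
#' @param causal_rec data.frame(snp, q, ni): SNP column index, recessive
#'   allele (allele 2) frequency, and target negative impact (months);
#'   genotypic values (0, 0, ni).
#' @param pta_mode "exact_blup" (PTA = pedigree BLUP / 2) or "noisy"
#'   (adds N(0, pta_tau^2) to emulate routine-evaluation approximation).
#' @param pta_tau SD of the noisy-mode PTA perturbation (months).
#' @param seed integer seed; stages use fixed offsets from it so each
#'   stage is individually reproducible. NULL = use the current RNG state.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200L, n_generations = 2L,
                       n_matings = 200L, n_offspring = 1L,
                       n_snps = 100L, maf_range = c(0.05, 0.5), hwd_f = 0,
                       mu = 11.98, sigma_a2 = 5, sigma_e2 = 55,
                       causal_add = NULL, causal_rec = NULL,
                       pta_mode = c("exact_blup", "noisy"), pta_tau = 0.5,
                       seed = NULL) {
  pta_mode <- match.arg(pta_mode)
  stopifnot(n_founders >= 2, n_generations >= 0, n_snps >= 1,
            sigma_a2 > 0, sigma_e2 > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], hwd_f >= 0, hwd_f < 1)
  for (df in list(causal_add, causal_rec)) {
    if (!is.null(df) && any(df$snp > n_snps)) stop("causal SNP index exceeds n_snps")
  }
  if (!is.null(causal_rec) && any(causal_rec$q <= 0 | causal_rec$q >= 1)) {
    stop("recessive allele frequency must be in (0, 1)")
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_matings = as.integer(n_matings),
                 n_offspring = as.integer(n_offspring),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 hwd_f = hwd_f, mu = mu,
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 causal_add = causal_add, causal_rec = causal_rec,
                 pta_mode = pta_mode, pta_tau = pta_tau, seed = seed),
            class = "sim_config")
}

seed_stage <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed) %% 2000000000L + offset)
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents and random sex; each
#' later generation is produced by `n_matings` random sire x dam pairs
#' drawn (with replacement across matings) from the previous generation,
#' each with `n_offspring` offspring. At least one male and one female
#' per generation are guaranteed so the structure is always feasible
#' when `n_founders >= 2`.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] with a `sex` column ("M"/"F").
#' @export
simulate_pedigree <- function(config) {
  seed_stage(config, 0L)
  n0 <- config$n_founders
  id <- paste0("G0_", seq_len(n0))
  sex <- assign_sex(n0)
  sire <- rep(NA_character_, n0); dam <- rep(NA_character_, n0)
  gen <- rep(0L, n0)
  prev_ids <- id; prev_sex <- sex
  for (g in seq_len(config$n_generations)) {
    sires <- prev_ids[prev_sex == "M"]
    dams <- prev_ids[prev_sex == "F"]
    if (length(sires) == 0L || length(dams) == 0L) {
      stop("impossible family structure: no available sires or dams in generation ", g - 1L)
    }
    ms <- sample(sires, config$n_matings, replace = TRUE)
    md <- sample(dams, config$n_matings, replace = TRUE)
    n_new <- config$n_matings * config$n_offspring
    new_id <- paste0("G", g, "_", seq_len(n_new))
    new_sex <- assign_sex(n_new)
    id <- c(id, new_id)
    sire <- c(sire, rep(ms, each = config$n_offspring))
    dam <- c(dam, rep(md, each = config$n_offspring))
    sex <- c(sex, new_sex)
    gen <- c(gen, rep(g, n_new))
    prev_ids <- new_id; prev_sex <- new_sex
  }
  ped <- pedigree(id, sire, dam, gen)
  ped$sex <- sex
  ped
}

# random sexes with both present whenever n >= 2
assign_sex <- function(n) {
  if (n == 1L) return(sample(c("M", "F"), 1L))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  if (!any(sex == "M")) sex[sample.int(n, 1L)] <- "M"
  if (!any(sex == "F")) sex[sample.int(n, 1L)] <- "F"
  sex
}

#' True genotypic values of causal SNPs
#'
#' Builds the per-SNP genotypic-value table implied by the causal-effect
#' configuration: additive/dominance SNPs get (g11, g12, g22) =
#' (2 alpha, alpha + delta, 0) and recessive SNPs (0, 0, NI) with allele
#' 2 as the recessive allele; non-causal SNPs are (0, 0, 0).
#'
#' @param config a [sim_config()].
#' @return list of class `true_effects`: `g` (n_snps x 3 matrix, columns
#'   g11/g12/g22), `recessive_allele` (2 for recessive SNPs, NA else).
#' @export
true_effects <- function(config) {
  g <- matrix(0, config$n_snps, 3, dimnames = list(NULL, c("g11", "g12", "g22")))
  rec <- rep(NA_integer_, config$n_snps)
  if (!is.null(config$causal_add)) {
    for (i in seq_len(nrow(config$causal_add))) {
      j <- config$causal_add$snp[i]
      delta <- if (is.null(config$causal_add$delta)) 0 else config$causal_add$delta[i]
      g[j, ] <- g[j, ] + c(2, 1, 0) * config$causal_add$alpha[i] + c(0, delta, 0)
    }
  }
  if (!is.null(config$causal_rec)) {
    for (i in seq_len(nrow(config$causal_rec))) {
      j <- config$causal_rec$snp[i]
      g[j, "g22"] <- g[j, "g22"] + config$causal_rec$ni[i]
      rec[j] <- 2L
    }
  }
  structure(list(g = g, recessive_allele = rec), class = "true_effects")
}

#' Simulate genotypes by gene drop
#'
#' Founder genotypes are drawn per SNP from the possibly-HWD genotype
#' distribution (see [sim_config()]); descendants receive one allele
#' from each parent, independently across SNPs (no linkage). Recessive
#' causal SNPs are drawn at their configured allele-2 frequency q (i.e.
#' p1 = 1 - q); additive causal SNPs use the regular MAF draw. Codes
#' count copies of allele 1.
#'
#' @param ped a [pedigree()] (topologically ordered).
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] over all pedigree individuals, map on a
#'   single synthetic chromosome with 10 kb SNP spacing.
#' @export
simulate_genotypes <- function(ped, config) {
  seed_stage(config, 1L)
  m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  flip <- stats::runif(m) < 0.5
  p1 <- ifelse(flip, 1 - maf, maf)
  if (!is.null(config$causal_rec)) {
    p1[config$causal_rec$snp] <- 1 - config$causal_rec$q
  }
  f <- config$hwd_f
  p2 <- 1 - p1
  P11 <- p1^2 + f * p1 * p2
  P12 <- 2 * p1 * p2 * (1 - f)
  P22 <- p2^2 + f * p1 * p2
  pi <- parent_indices(ped)
  n <- nrow(ped)
  codes <- matrix(NA_integer_, n, m)
  founders <- which(ped$generation == 0L)
  for (j in seq_len(m)) {
    codes[founders, j] <- sample(c(2L, 1L, 0L), length(founders), replace = TRUE,
                                 prob = c(P11[j], P12[j], P22[j]))
  }
  # gene drop generation by generation, vectorized over individuals x SNPs
  for (g in sort(unique(ped$generation[ped$generation > 0L]))) {
    rows <- which(ped$generation == g)
    S <- codes[pi$sire[rows], , drop = FALSE]
    D <- codes[pi$dam[rows], , drop = FALSE]
    from_s <- (S == 2L) + (S == 1L) * matrix(stats::rbinom(length(S), 1L, 0.5),
                                             nrow(S), ncol(S))
    from_d <- (D == 2L) + (D == 1L) * matrix(stats::rbinom(length(D), 1L, 0.5),
                                             nrow(D), ncol(D))
    codes[rows, ] <- from_s + from_d
  }
  map <- data.frame(snp = sprintf("snp%04d", seq_len(m)), chrom = "1",
                    pos = seq_len(m) * 10000L,
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  rownames(codes) <- ped$id
  genotype_matrix(codes, map)
}

#' Simulate phenotypes under the additive polygenic model
#'
#' y_i = mu + sum over causal SNPs of g(genotype_i) + a_i + e_i with
#' a ~ MVN(0, sigma_a2 A) generated recursively down the pedigree
#' (founders N(0, sigma_a2); offspring mid-parent average plus a
#' Mendelian-sampling deviation with variance
#' 0.5 sigma_a2 (1 - (F_s + F_d)/2)), and e_i ~ N(0, sigma_e2). The true
#' polygenic values are kept for oracle tests.
#'
#' @param ped a [pedigree()].
#' @param gm genotypes from [simulate_genotypes()].
#' @param fx a [true_effects()].
#' @param config a [sim_config()].
#' @return data.frame (id, y, pta = NA, a_true, g_true, e) for every
#'   pedigree individual.
#' @export
simulate_phenotypes <- function(ped, gm, fx, config) {
  seed_stage(config, 2L)
  pi <- parent_indices(ped)
  n <- nrow(ped)
  Fv <- inbreeding(ped)
  a <- numeric(n)
  for (g in sort(unique(ped$generation))) {
    rows <- which(ped$generation == g)
    if (g == 0L) {
      a[rows] <- stats::rnorm(length(rows), 0, sqrt(config$sigma_a2))
    } else {
      s <- pi$sire[rows]; d <- pi$dam[rows]
      if (any(s == 0L) || any(d == 0L)) {
        stop("internal ordering error: non-founder with unknown parent polygenic value")
      }
      msv <- 0.5 * config$sigma_a2 * (1 - (Fv[s] + Fv[d]) / 2)
      a[rows] <- 0.5 * (a[s] + a[d]) + stats::rnorm(length(rows), 0, sqrt(msv))
    }
  }
  codes <- gm$codes[ped$id, , drop = FALSE]
  # genotypic value: column j contributes g[j, 3 - code]
  gv <- numeric(n)
  for (j in which(rowSums(abs(fx$g)) > 0)) {
    cj <- codes[, gm$map$snp[j]]
    gj <- fx$g[j, ]
    gv <- gv + ifelse(is.na(cj), 0, gj[3L - cj])
  }
  e <- stats::rnorm(n, 0, sqrt(config$sigma_e2))
  data.frame(id = ped$id, y = config$mu + gv + a + e, pta = NA_real_,
             a_true = a, g_true = gv, e = e, stringsAsFactors = FALSE)
}

#' Pedigree BLUP and PTA
#'
#' Solves Henderson's mixed model equations for the animal model with a
#' common mean (pedigree only, no SNPs), using the sparse inverse of the
#' additive relationship matrix, and stores PTA = a_hat / 2 so that
#' 2 * PTA reproduces the polygenic BLUP exactly in `exact_blup` mode.
#' `noisy` mode adds N(0, pta_tau^2) to the PTA to emulate the
#' approximation in estimates from routine genetic evaluation.
#'
#' @param ped a [pedigree()].
#' @param ph phenotype data.frame (id, y) for a subset (or all) of the
#'   pedigree; ids must be unique and present in the pedigree.
#' @param config a [sim_config()] (variance components, pta_mode, seed).
#' @return `ph` with the `pta` column filled for phenotyped cows.
#' @export
compute_pta <- function(ped, ph, config) {
  if (anyDuplicated(ph$id)) stop("duplicated ids in phenotype table")
  idx <- match(ph$id, ped$id)
  if (anyNA(idx)) stop("phenotyped cow absent from pedigree")
  n_obs <- nrow(ph)
  q <- nrow(ped)
  Ainv <- a_inverse(ped)
  Z <- Matrix::sparseMatrix(i = seq_len(n_obs), j = idx, x = 1, dims = c(n_obs, q))
  lambda <- config$sigma_e2 / config$sigma_a2
  ZtZ <- Matrix::crossprod(Z)
  z1 <- Matrix::colSums(Z)
  # assemble the MME coefficient matrix fully sparse (mean + animal blocks)
  top <- cbind(Matrix::sparseMatrix(i = 1L, j = 1L, x = n_obs, dims = c(1L, 1L)),
               Matrix::Matrix(matrix(z1, 1L, q), sparse = TRUE))
  bot <- cbind(Matrix::Matrix(matrix(z1, q, 1L), sparse = TRUE),
               ZtZ + lambda * Ainv)
  C <- rbind(top, bot)
  rhs <- c(sum(ph$y), as.numeric(Matrix::crossprod(Z, ph$y)))
  sol <- as.numeric(Matrix::solve(C, rhs))
  a_hat <- sol[-1L]
  pta <- a_hat[idx] / 2
  if (config$pta_mode == "noisy") {
    seed_stage(config, 3L)
    pta <- pta + stats::rnorm(n_obs, 0, config$pta_tau)
  }
  ph$pta <- pta
  ph
}

#' Simulate a complete dataset
#'
#' Pedigree, genotypes, true effects, phenotypes and PTA in one call.
#'
#' @param config a [sim_config()].
#' @return list of class `agls_sim`: ped, gm, effects, pheno, config.
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  gm <- simulate_genotypes(ped, config)
  fx <- true_effects(config)
  ph <- simulate_phenotypes(ped, gm, fx, config)
  ph <- compute_pta(ped, ph, config)
  structure(list(ped = ped, gm = gm, effects = fx, pheno = ph, config = config),
            class = "agls_sim")
}

#' @export
print.agls_sim <- function(x, ...) {
  cat("simulated dataset:", nrow(x$ped), "individuals,",
      ncol(x$gm$codes), "SNPs,", x$config$n_generations, "bred generation(s)\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Genotype TSV + SNP map TSV, pedigree CSV, phenotype CSV, and a truth
#' JSON (causal genotypic values, variance components, seed).
#'
#' @param sim an `agls_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genotypes.tsv", "snp_map.tsv", "pedigree.csv",
                            "phenotypes.csv", "truth.json"))
  write_genotypes(sim$gm, paths[1L], paths[2L])
  utils::write.csv(sim$ped[, c("id", "sire", "dam")], paths[3L],
                   row.names = FALSE, na = "")
  utils::write.csv(sim$pheno[, c("id", "y", "pta")], paths[4L], row.names = FALSE)
  causal <- which(rowSums(abs(sim$effects$g)) > 0)
  truth <- list(causal = lapply(causal, function(j) {
    list(snp = sim$gm$map$snp[j], g11 = sim$effects$g[j, 1],
         g12 = sim$effects$g[j, 2], g22 = sim$effects$g[j, 3])
  }),
  sigma_a2 = sim$config$sigma_a2, sigma_e2 = sim$config$sigma_e2,
  mu = sim$config$mu, seed = sim$config$seed)
  jsonlite::write_json(truth, paths[5L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
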