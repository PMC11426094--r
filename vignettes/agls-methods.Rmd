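---
title: "AGLS association testing for additive and dominance effects: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AGLS association testing for additive and dominance effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aglscan)
```

## The problem and the model

Longevity traits in dairy cattle — productive life (PL), the months a cow
stays in the milking herd from first calving to exit — are recorded on very
large pedigreed populations. Testing each SNP in such a population with a
full mixed model is prohibitive: the single-SNP model is

$$\mathbf{y} = \mu\mathbf{1} + \mathbf{X_g}\,\mathbf{g} + \mathbf{Z}\mathbf{a} + \mathbf{e},
\qquad \mathrm{var}(\mathbf{y}) = \sigma_a^2\,\mathbf{Z A Z'} + \sigma_e^2\,\mathbf{I},$$

with $\mathbf{y}$ the yield deviations (phenotypes pre-adjusted for fixed
non-genetic effects), $\mathbf{g} = (g_{11}, g_{12}, g_{22})'$ the genotypic
values of the three SNP genotype classes, $\mathbf{a}$ the additive polygenic
values with pedigree relationship matrix $\mathbf{A}$, and independent
residuals. Estimating $\mathbf{g}$ exactly requires either the generalized
least squares (GLS) solution through $\mathbf{V}^{-1}$ or Henderson's mixed
model equations (MME), per SNP.

The *approximate GLS* (AGLS) approach sidesteps both: routine genetic
evaluation already produces predicted transmitting abilities (PTA), and
$\tilde{\mathbf{a}} = 2\,\mathrm{PTA}$ approximates the polygenic BLUP
$\hat{\mathbf{a}}$. Substituting it gives an ordinary least-squares problem
on the adjusted phenotype $\mathbf{y}^* = \mathbf{y} - \mathbf{Z}\tilde{\mathbf{a}}$:

$$\hat{\mathbf{b}} = (\mathbf{X}'\mathbf{X})^-\,\mathbf{X}'\mathbf{y}^*.$$

When $\tilde{\mathbf{a}}$ equals the exact joint-MME BLUP, this identity is
exact — the package's `oracle` solvers (`build_A()`, `exact_fit()`) verify it
to 1e-8 in the test suite. With PTA from a pedigree-only evaluation it is an
approximation whose statistical behaviour the simulation suite quantifies.

### Cell-means parameterization

The design $\mathbf{X} = (\mathbf{1}, \mathbf{X_g})$ is rank-deficient (the
intercept is the sum of the class indicators). `agls_fit()` therefore fits
the genotype-class means directly — a full-rank reparameterization whose
estimable contrasts coincide with any generalized-inverse solution of the
original design. The tests check this against a Moore–Penrose pseudo-inverse
oracle on random instances: both the contrast estimates and their variances
agree to 1e-10. The residual variance is $v^2 = \mathrm{RSS}/(n-k)$ with $k$
the number of non-empty classes.

### Contrast tests

Additive and dominance effects are tested with contrast t-statistics
$t = |\mathbf{s}\hat{\mathbf{g}}| / \sqrt{v^2 \sum_c s_c^2/n_c}$:

* **additive**: $\mathbf{s}_a = (P_{11}/p_1,\; 0.5 P_{12}(p_2-p_1)/(p_1 p_2),\; -P_{22}/p_2)$,
  valid under Hardy–Weinberg *disequilibrium* and reducing to
  $(p_1, p_2 - p_1, -p_2)$ under HWE. Its value is the average effect of
  gene substitution $\alpha$.
* **dominance**: $\mathbf{s}_d = (-0.5, 1, -0.5)$, whose value is
  $\delta = g_{12} - (g_{11}+g_{22})/2$. (Some write-ups print the last
  coefficient with a positive sign; the definition of $\delta$ fixes it as
  $-0.5$, which is what the variance form
  $0.25/n_{11} + 1/n_{12} + 0.25/n_{22}$ implies.)

P-values use a t reference with $n-k$ degrees of freedom — at the sample
sizes this method targets it is indistinguishable from normal; the reference
is computed on the log scale so significances around $\log_{10}(1/p) = 50$
remain accurate (checked against an arbitrary-precision incomplete-beta
oracle). A perfect fit ($v^2 = 0$ with a non-null contrast) is reported as an
infinite-significance sentinel rather than a division error.

Genome-wide significance defaults to Bonferroni $\alpha/m$; a fixed
$\log_{10}(1/p) \ge 8$ cutoff (i.e. $p \le 10^{-8}$) is available as the
replication profile used in large Holstein analyses. Note the two do not
coincide: $0.05/75{,}282 \approx 6.6\times 10^{-7}$, which is more lenient
than $10^{-8}$; both modes are kept and the choice is the caller's.

### Effect decomposition

For each SNP the fitted class means decompose into allelic means
$\mu_1 = P_{11.1} g_{11} + 0.5 P_{12.1} g_{12}$,
$\mu_2 = 0.5 P_{12.2} g_{12} + P_{22.2} g_{22}$ (conditional frequencies
$P_{ij.i} = P_{ij}/p_i$, so no HWE assumption), the population mean
$\mu = p_1\mu_1 + p_2\mu_2$, allelic effects $a_i = \mu_i - \mu$ (zero-sum:
$p_1 a_1 + p_2 a_2 = 0$), the average effect of gene substitution
$\alpha = a_1 - a_2$, and dominance deviations
$d_{ij} = g_{ij} - \mu - a_i - a_j$ (frequency-weighted zero-sum). The
reconstruction $g_{ij} = \mu + a_i + a_j + d_{ij}$ is exact and tested.

Degree of dominance is classified from the deviations: *overdominance* when
$|d_{12}|$ exceeds both homozygote deviations, *partial* when $d_{12}$ lies
strictly between them, *complete* when $d_{12}$ equals one of them. Sampling
noise makes exact equality impossible, so "equal" means within a relative
tolerance (default $0.05\,|d_{11}-d_{22}|$, configurable), and the tolerance
check takes precedence over the strict orderings. The three rules do not
partition every configuration: when a strong additive component places
$d_{12}$ outside the homozygote range without exceeding both in magnitude
(e.g. a rare recessive with a large $\alpha$), the SNP is reported
"unclassified" rather than forced into a category. The dominant allele is
the one whose homozygote mean the heterozygote resembles.

### Negative impact and breeding rules

For rare, sharply negative homozygous recessive genotypes the practically
relevant quantity is on the *original* phenotype scale:
$\mathrm{NI} = \bar y_{rr} - (\bar y_{rD} + \bar y_{DD})/2$ in months. This
deliberately differs from $\delta$, which lives on the polygenic-adjusted
scale; both are reported side by side and are not numerically interchangeable.

The breeding module turns a screening panel (SNP, recessive allele, NI,
allele frequency q) into decisions: `heifer_cull_list()` flags cows
homozygous recessive at any panel SNP (missing genotypes flag the cow
"undetermined" rather than culling on incomplete evidence);
`expected_rr_fraction()` gives the Mendelian expectations (an rr sire on
random dams produces a fraction q of rr daughters; a carrier sire q/2 — at
the largest reported q = 0.097 those are ~10% and ~5%); `allowed_matings()`
implements the rule set under the culling assumption (no rr dams): exactly
DD×DD, DD×rD, rD×DD and rr×DD are allowed, because none can produce an rr
daughter. Multi-SNP feasibility (`mating_feasible()`) is the per-SNP
conjunction and is flagged experimental — no published algorithm exists for
the joint problem. The shipped Holstein panel excludes the two Chr04
heterozygous-advantage SNPs by default (their use is a breeder's judgement
call); `include_chr4 = TRUE` adds them.

## The synthetic-data generator

No public dataset accompanies this method — the motivating data are held by
a breeding-industry consortium — so the package ships a generator whose
output has exactly the structure the analysis assumes:

* **Pedigree** (`simulate_pedigree()`): founder generation plus discrete
  generations of random sire × dam matings. The default is **one offspring
  per mating**, reflecting dairy practice (one calf per dam per season):
  the resulting population is half-sib structured with few full sibs.
* **Genotypes** (`simulate_genotypes()`): founder allele-1 frequencies drawn
  uniformly with MAF in [0.05, 0.5] (assigned to either allele), genotypes
  from $P_{11} = p_1^2 + f p_1 p_2$, $P_{12} = 2p_1p_2(1-f)$,
  $P_{22} = p_2^2 + f p_1 p_2$ with the within-locus inbreeding coefficient
  $f$ controlling Hardy–Weinberg departure; descendants by Mendelian gene
  drop, independent across SNPs (no linkage map — the analysis is
  single-SNP; LD demonstrations use duplicated/perturbed columns instead).
* **Phenotypes** (`simulate_phenotypes()`): polygenic values by the
  recursive algorithm ($a_i = \tfrac12 a_s + \tfrac12 a_d + $ Mendelian
  deviation with variance $\tfrac12\sigma_a^2(1 - (F_s+F_d)/2)$, inbreeding
  from the pedigree), plus causal genotypic values and iid residuals.
  Defaults $\sigma_a^2 = 5$, $\sigma_e^2 = 55$ months² give heritability
  0.083 and phenotypic SD ≈ 7.7 months — low-heritability longevity-like
  values — around a trait mean of 11.98 months.
* **PTA** (`compute_pta()`): the exact pedigree-only BLUP from Henderson's
  MME (sparse $\mathbf{A}^{-1}$ by Henderson's rules with inbreeding), halved,
  so $2\,\mathrm{PTA}$ reproduces $\hat{\mathbf{a}}$ exactly; a `noisy` mode
  adds a N(0, τ²) perturbation to emulate the approximation in routine
  evaluations. The accuracy of real routine evaluations is not publicly
  calibrated, so τ is an honest free knob (default 0.5 months).
* **Causal effects**: additive SNPs get genotypic values
  $(2\alpha, \alpha + \delta, 0)$ (effect sizes of ±0.1–0.6 months mirror
  the reported range of top additive effects); recessive SNPs get
  $(0, 0, \mathrm{NI})$ with allele-2 frequencies around 0.07–0.10, giving
  rr genotype frequencies of ~0.005–0.01 and NI of −3 to −6 months, the
  reported range for sharply negative recessive genotypes.

What the generator does **not** emulate: linkage/recombination maps and
LD-induced clustering of signals, selection across generations, genotyping
error and imputation error, non-genetic herd structure beyond what yield
deviations already remove. Passing tests therefore validate the estimator's
algebra and sampling behaviour, not robustness to those real-data features.

## Numerical choices and problem sizes

* MAF filter boundary is inclusive (min(p1, p2) ≥ 0.05); frequencies always
  come from complete cases per SNP (the motivating analyses used imputed,
  complete data, so complete-case handling is a generalization).
* Contrast frequencies are taken from the same complete-case cows as the
  fit, for self-consistency.
* Ranking ties break by (chromosome, position) for determinism; upstream/
  downstream gene labels use strand when present and coordinate order with a
  `*` ("strandless") marker otherwise; intergenic labels use a 1 Mb window.
* Positions are 1-based in SNP maps; BED gene intervals keep the 0-based
  half-open convention with a single conversion point (`bed_to_1based()`).
* The exact mixed-model solvers are dense and capped (default n ≤ 2000);
  they exist for validation, not production scans.
* Test-suite problem sizes: oracle equivalence uses 50 pedigrees of ~120
  individuals; the null (type-I) suite uses 10 replicates of 1000 SNPs ×
  2000 cows; parameter recovery uses 4 replicates of 10,000 cows. These
  sizes put Monte-Carlo error well below the tested tolerances while
  keeping the default test run quick.

## Known limitations

* With PTA from a pedigree-only evaluation, the additive test is only
  approximately calibrated, and the approximation degrades with
  within-sample relatedness. In our null simulations at n = 2000 the
  empirical additive type-I error at nominal 0.01 is ≈ 0.009 with a single
  bred generation, ≈ 0.006–0.007 under the default two-generation half-sib
  design, and ≈ 0.005 in sib-dense designs (full-sib pairs everywhere,
  parents phenotyped in-sample) — i.e. the additive test is **mildly
  conservative** under multi-generation relatedness. The mechanism:
  BLUP-adjusted residuals are negatively correlated within families while
  allele dosage is positively correlated, so the contrast-variance
  estimate $v^2\sum s_c^2/n_c$ is biased upward for dosage-monotone
  contrasts. The dominance test stays calibrated (≈ 0.011) because its
  weights track heterozygosity, which is far less heritable. On iid
  phenotypes both tests are exactly calibrated (0.0108 at 20,000 null
  tests). Users should read additive p-values under strong relatedness as
  conservative.
* Pedigree-only PTA partially absorbs causal-SNP effects: they are
  heritable and family-structured, so the BLUP soaks up part of them
  through own and relatives' records, and `y* = y - 2 PTA` carries
  **multiplicatively attenuated** effects. Under the default conditions
  (n = 10,000, heritability 0.083) we measure the attenuation directly:
  over 8 replicate simulations a programmed dominance effect of 1.0 month
  is recovered as 0.857 (SE 0.095) and an additive effect of ~0.4 month as
  0.342 (SE 0.029) — about 14% shrinkage. This mirrors the real setting,
  where routine-evaluation breeding values contain the tested SNP's
  additive contribution by construction. Single-dataset estimates remain
  within their sampling error of the programmed values; the bias only
  becomes visible when averaging many replicates. Tests are unaffected
  under the null (no effect to absorb), but reported effect sizes should
  be read as mild underestimates.
* Dominance tests require all three genotype classes; for rare recessives
  this needs large n (the motivating analyses had ≥ 4600 cows in the rarest
  class).
* The negative-impact estimator is a raw class-mean difference; it carries
  no polygenic adjustment and is sensitive to family structure of the few
  rr cows at small n.

## A worked example

```{r, eval = FALSE}
cfg <- sim_config(
  n_founders = 1000, n_generations = 1, n_matings = 1000, n_offspring = 1,
  n_snps = 60, seed = 61,
  causal_add = data.frame(snp = 10, alpha = 2.5),
  causal_rec = data.frame(snp = 20, q = 0.3, ni = -8))
sim <- simulate_dataset(cfg)
sc <- agls_scan(sim$gm, sim$pheno)
summary(sc)
plot(sc, by = "additive")
panel <- panel_from_scan(sc)
head(heifer_cull_list(sim$gm, panel))
```
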