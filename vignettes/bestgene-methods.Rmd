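---
title: "Bidirectional effect genes as drug targets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional effect genes as drug targets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bestgene)
```

# The scientific problem

Most drug programs fail in the clinic, and human genetics is one of the few
prioritisation signals with a track record: targets supported by genetic
evidence are roughly twice as likely to be approved. `bestgene` implements a
sharper version of that signal — the *bidirectional allelic series*. A gene
in which gain-of-function (GoF) variants push a phenotype one way and
loss-of-function (LoF) variants push it the other way behaves like a natural
dose–response experiment: it tells you the gene sits causally on the axis,
which direction to modulate, and (because carriers of the protective
direction are walking around healthy) that modulation is unlikely to be
grossly toxic. The package calls such genes BEST genes (Bidirectional Effect
Selected Targets).

The package chains four analyses:

1. **Screen** a mutation catalog (HGMD-like gene/disease records) for genes
   with at least two disease associations of opposite direction on a shared
   phenotype axis.
2. **Quantify** how much BEST support enriches for clinical success: the
   relative risk of phase transitions for supported versus unsupported
   target–indication pairs, swept over an indication–trait similarity
   threshold.
3. **Validate** a concrete axis — height / idiopathic short stature (ISS,
   standardized height below −2 SD) — with a rare-variant exome battery:
   QC cascade, consequence masks, burden and SKAT tests, and
   polygenic-score (PS) stratification with heterogeneity statistics.
4. **Integrate** a cellular functional readout (cGMP produced by NPR2 in
   response to CNP, relative to wild type) with carrier phenotypes.

Real inputs for these analyses are licensed (HGMD), access-controlled
(UK Biobank) or external (clinical-trial outcome tables), so the package
ships a first-class synthetic-data generator that reproduces the
*statistical structure* of each input. Every analysis stage is exercised
end to end on generated data, with planted truths that the test suite
recovers.

# The statistical core

## Bidirectional screen

The screen collapses the catalog to unique (gene, disease) pairs, drops
genes with fewer than two unique disease associations, and classifies each
label with an explicit **direction lexicon**: generic antonym prefixes
("high …"/"low …", "increased …"/"decreased …", "long …"/"short …",
"hyper-"/"hypo-"), exact-phrase axis entries for labels whose axis is not
the literal remainder ("short QT syndrome" → QT interval, down), and an
exclusion list of molecular/cellular/benign phenotypes (enzyme activity,
cell permeability, pigmentation) that never yield a directional call. A
gene is BEST iff it has ≥1 up and ≥1 down call on the same axis; genes
bidirectional on two axes emit one record per axis. Labels that survive the
min-2 filter but match nothing are exported to a review queue — the
curation step is made explicit and auditable rather than hidden in manual
judgment, which is why the screen on real catalogs should be read as
lexicon-recall-limited with the queue closing the gap.

## Approval odds

A target–indication pair is *supported* when its target gene has evidence
(class BEST, OMIM-unidirectional or GWAS; precedence BEST > OMIM > GWAS,
configurable since no canonical order exists) for a trait whose semantic
similarity to the indication strictly exceeds a threshold. For each
transition (Phase I→II, II→III, III→Approval, I→Approval) the 2×2 of
support × success among pairs reaching the source phase gives the relative
risk

$$RR = \frac{a/(a+b)}{c/(c+d)},$$

with a 95% CI by the Katz log method
$\exp(\ln RR \pm 1.96\sqrt{1/a - 1/(a{+}b) + 1/c - 1/(c{+}d)})$, a 0.5
continuity correction (flagged) when a zero cell makes the log method
undefined, and the odds ratio reported alongside from the same counts. The
similarity threshold is swept over 0–1 in steps of 0.01 and the Phase I →
Approval maximum is reported with its threshold, ties toward the smaller
threshold. Sensitivity analyses either exclude the evidence of named
phenotype categories or stratify by category, skipping categories with ≤5
supported genes.

## Cohort QC

The sample cascade excludes: non-qualifying ancestry; sex-chromosome
aneuploidy; PCA-corrected heterozygosity outside [0.17, 0.21]; more than
80,000 non-reference variants; more than 200 singletons; het/hom ratio
outside [1.3, 1.85]; call rate below 0.985; chip heterozygote concordance
below 0.98. All criteria are conjunctive, so the kept set is
order-independent; the attrition table reports sequential removals.
One deliberate deviation: the literal one-sided rule "exclude Ti/Tv > 2.5"
would remove essentially every real exome (typical exome Ti/Tv ≈ 3.0), so
the Ti/Tv filter defaults to off, with the verbatim one-sided rule and a
two-sided window both available behind flags. Relatives of second degree or
closer are removed greedily — most-connected member first, ties by sample
id — which resolves pairs and cliques deterministically.

Variants require call rate ≥ 0.99 and an exact Hardy–Weinberg p ≥ 1e−10.
The HWE test is the conditional exact test (sum of probabilities of
heterozygote counts no more likely than observed, given allele counts).
Variants observed in an external reference panel are additionally checked
by a two-sided exact binomial test of the cohort allele count against the
reference frequency (drop at p < 1e−7); a reference frequency of exactly
zero for a covered site is floored at 1/(2·panel size), and variants
absent from the reference are kept and flagged unfilterable.

Masks: `protein_altering` = {stop-gained, frameshift, splice
acceptor/donor, missense}, `ptv` = the truncating subset, both at
within-cohort minor allele frequency strictly below 1e−4 computed in the
post-QC cohort. Genes with cumulative mask allele count below 20 are
excluded from gene-level testing; a carrier-count variant of the rule is
available since "≥20 carriers" and "cumulative AC ≥ 20" differ only for
samples carrying two alleles. X-chromosome allele numbers count males
once.

## Association battery

Height is split by sex, residualised on age and five genotype PCs by least
squares, and scaled to unit SD per stratum; ISS is z < −2 (strict). The
burden score is the per-sample sum of alternate-allele dosages over a
unit's mask variants (allele-count aggregation; a carrier-indicator mode
exists behind a flag). Linear burden regresses z on the score; logistic
burden regresses ISS on the score plus sex and age (the quantitative trait
is pre-residualised; the binary model's covariates are configurable) and
reports a Wald odds ratio, falling back to Firth-penalised logistic
regression under complete separation, flagged in the output.

SKAT computes $Q = r^\top G W^2 G^\top r$ with $r$ the intercept-only
null residuals (covariates are already absorbed in z), $G$ the unit's
dosage matrix and $W$ diagonal per-variant weights — `dbeta(MAF, 1, 25)`
by default (the rare-variant convention; no canonical choice exists for
this battery) or flat. The p-value comes from the eigenvalues of the projected
weighted kernel via `davies_pvalue()`: numerical inversion of the
characteristic function of $\sum_i \lambda_i \chi^2_1$ (Imhof-form
integrand under `stats::integrate`), with a Liu moment-matching fallback
when the quadrature fails, and the method recorded in the result. Gene
sets are all $2^5 = 32$ exclusive combinations of the five evidence flags
(GWAS, HGMD_SHORT, HGMD_TALL, OMIM_SHORT, OMIM_OVERGROWTH) plus the named
sets (Set1 = all five; Set2 = the four catalog flags without GWAS;
Bidirectional / Tall / Short per their flag definitions). Significance is
Bonferroni over the battery size (5 gene-level tests; set-level analyses
use the count of non-empty cells).

## Polygenic stratification

Weights come from the closed-form infinitesimal model: per LD block,
$w = (M/(N h^2) I + D)^{-1} \hat\beta$. Only this deterministic
closed form is implemented — the point-normal MCMC adds nothing to the
stratification analyses, which depend only on having a score. Scores are
weighted allele sums with sign flips for mismatched effect alleles and
mean imputation (2·AF) for missing dosages. Quintiles are rank-based with
remainders to the lower groups and stable tie-breaking. Within each
quintile, carrier versus non-carrier height contrasts (classes missense
and LoF, LoF taking precedence for double carriers) are combined by
fixed-effect inverse-variance meta-analysis; Cochran's
$Q = \sum w_i(\beta_i - \bar\beta)^2$, $I^2 = \max(0, (Q - df)/Q)$ and
$p_{het}$ from $\chi^2_{df}$ quantify heterogeneity. ISS odds ratios per
carrier-class × quintile cell use middle-quintile non-carriers as the
reference; cells fitted on essentially no cases (coefficient SE > 100)
are removed by that hard cutoff. The quintile contrasts are computed on
the pre-residualised z without further adjustment.

## Functional integration

Activity is cGMP relative to wild type: bins are low (< 0.2), supranormal
(> 1), intermediate otherwise, with both boundaries intermediate (strict
inequalities as printed). The activity–height regression treats each
carrier as one observation by default (a per-variant mode collapses to
mean carrier height), so the slope reads as SD of height per 100%
activity. The comparison with an in-silico deleteriousness score fits each
predictor separately and flags the higher R². For the joint effect of PS
and residual activity on height, a generalized-additive smoother is a
plausible choice, but the package uses a linear model: the scientific
claim at stake is additivity, which a linear fit tests directly, and a
smoother adds a tuning parameter without adding testable content.

# The synthetic-data generator

The generator's defaults are the study conditions, fixed once:

| Parameter | Default | What it emulates |
|---|---|---|
| `n_samples` | 34,000 | post-QC exome cohort size |
| `n_genes` / `n_best_genes` | 40 / 5 | evidence gene list (scaled down) and the five-gene bidirectional core |
| `carrier_freq` | 0.0055 | per-gene carrier probability (≈187 alleles per core gene; the five-gene set totals ≈930 alleles, carrier frequency ≈2.6%) |
| `rare_effect_sd` | −0.20 | mean per-allele height effect of core-set alleles |
| `ptv_fraction`, `ptv_effect` | 0.05, −0.85 | truncating alleles and their planted effect |
| `missense_effect_sd` | 0.58 | spread of the missense allelic series |
| `prs_h2` | 0.20 | height variance explained by the common-variant score |
| `iss_threshold` | −2 | ISS definition |
| `trial_rr` | 4 | planted Phase I→Approval relative risk for supported pairs |
| `phase_attrition` | 0.54 / 0.35 / 0.62 | base per-transition success probabilities |
| `n_pairs` | 26,884 | target–indication pairs |
| `support_similarity` | 0.8 | similarity above which the planted enrichment applies |

Two derivations worth recording:

* **The missense mean is derived, not free.** With a fraction $f$ of
  truncating alleles at effect $b_{PTV}$, the missense mean is
  $\mu_m = (\bar\beta - f\, b_{PTV})/(1-f)$ so the allele mixture averages
  to `rare_effect_sd` exactly. With the default mixture
  ($f=0.05$, $b_{PTV}=-0.85$, $\mu_m \approx -0.166$, $\tau = 0.58$), the
  implied carrier odds ratio for ISS at the −2 SD threshold is
  $\big[f\,\mathrm{odds}(b_{PTV}) + (1-f)\,\mathrm{odds}(\mu_m, \tau)\big]
  / \mathrm{odds}(0) \approx 2.75$, where
  $\mathrm{odds}(\mu,\tau)$ is the Gaussian-tail odds of
  $z < -2$ for a carrier shifted by $\mu$ with between-variant spread
  $\tau$. The effect **dispersion** is what turns a mean shift of −0.20
  into an odds ratio near 2.75; a homogeneous −0.20 shift would give only
  ≈1.6. A direct consequence: across PS quintiles the *missense* carrier
  contrast carries real between-variant variance on top of sampling error,
  so its Cochran's Q is over-dispersed even though the generator is
  strictly additive in PS × carrier — the clean additivity check
  ($I^2 \approx 0$) belongs to the LoF class, whose planted effect is
  constant. Real cohorts show the same asymmetry: missense allelic series
  are functionally heterogeneous while truncating alleles act alike.
* **Trial planting is on the risk scale.** Each of the three transition
  probabilities of a supported pair is multiplied by `trial_rr`^(1/3), so
  the cumulative Phase I→Approval relative risk equals `trial_rr` exactly
  when no probability clips at 1 (the configuration validator rejects
  clipping). Planting odds multipliers per phase would not compose to a
  recoverable cumulative relative risk. Only the BEST class carries
  planted enrichment; OMIM/GWAS annotations exist to exercise precedence.

Other generator choices: per-gene variant counts are Poisson (mean 120)
with per-variant allele counts 1 + Poisson truncated to keep within-cohort
AF below the 1e−4 scale at the default cohort size — matching the
singleton-heavy sparsity of real rare-variant data (mean AC per variant
≈1.55). Height is built as sex/age/PC structure plus the genetic score
plus rare effects plus Gaussian noise, with the residual variance chosen
so standardized height has unit variance — hence ISS prevalence lands at
the Gaussian tail (2.1–2.3% observed; Φ(−2) = 2.28%), consistent with
the ~2% population figure for ISS. Common SNPs are independent
(`ld_block_size = 1`); the infinitesimal solver accepts arbitrary PSD
blocks but the generator does not emulate realistic LD, which is a stated
non-goal. GWAS summary statistics are the true weights plus noise at the
per-SNP standard error implied by a 700,000-sample GWAS. Similarities are
Beta(2,8) background with Beta(24,3) for genuinely linked
indication–trait pairs, so "support" is sharply identified above the 0.8
threshold. Drug-program targets oversample evidenced genes (8:1), since
real development portfolios concentrate on targets with some rationale;
this keeps supported-pair counts at a realistic share of the table.
Functional activity is $1 + \mathrm{effect}/0.9 + \varepsilon$ clamped at
0, so the generative slope is 0.9 SD per 100% activity, strong losses
fall below 0.2, and gain-of-function alleles exceed 1. The in-silico
comparator score is mostly noise with a weak deleteriousness signal,
emulating a CADD-like predictor that the measured assay should beat.

All randomness flows from one root seed through named substreams
(catalog / trials / cohort / functional), so each stage is independently
reproducible and byte-stable; the QC-failure plantings are part of the
cohort substream.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: linkage disequilibrium and population
stratification beyond Gaussian PCs; sequencing artefacts (QC failures are
planted labels, not error processes); curation ambiguity in disease labels
(the catalog uses lexicon-consistent labels, so screen recall is 1 by
construction — on real catalogs recall depends on the lexicon and the
review queue); correlated trial outcomes within programs or sponsors; and
winner's-curse structure in GWAS weights.

# Numerical choices and degenerate inputs

* `davies_pvalue` integrates to absolute tolerance 1e−9 and falls back to
  Liu moment matching if the quadrature fails or leaves [0, 1]; p-values
  are clamped to (0, 1]. Eigenvalues below 1e−10 of the largest are
  dropped before inversion.
* `hwe_exact_p` compares conditional probabilities with a 1 + 1e−7
  relative guard (the convention of the reference implementation of the
  exact test) so ties at machine precision count as "as likely".
* Monomorphic sites return HWE p = 1; zero-carrier units are flagged
  untestable rather than erroring; all-zero genotype columns are dropped
  from SKAT.
* Quintile assignment breaks ties by stable input order and flags the
  all-equal degenerate case.
* Burden missing genotypes count as zero alternate alleles; score missing
  dosages impute to 2·AF.
* The relatedness graph is resolved greedily (most connections first,
  then id order) — minimal removal is NP-hard in general; on pairs and
  triangles the greedy answer equals the brute-force minimum, which the
  tests verify.

# Problem sizes used by the test suite

Unit tests run on cohorts of 150–4,000 samples with proportionally scaled
gene and variant counts, and pass a correspondingly scaled mask MAF cutoff
(rare-variant frequencies cannot sit on the 1e−4 scale in a 2,000-sample
cohort). Calibration uses 500 null cohorts of 600 samples; recovery runs
one cohort at the default 34,000-sample scale plus a 20,000-pair trial
table; the Davies Monte-Carlo oracle uses 1e7 draws and the SKAT
permutation oracle 1e6 permutations. These sizes were chosen so the full
suite completes in a few minutes while keeping every Monte-Carlo
comparison inside 3 standard errors.

# Known limitations

* The screen's recall on real catalogs is bounded by the lexicon; the
  review queue is the designed escape hatch. Screen output on a licensed
  catalog depends on the catalog snapshot and on curator judgment for the
  borderline labels, so no particular published gene list should be
  expected to reproduce exactly.
* SKAT here is the plain variance-component test (no SKAT-O, no
  small-sample moment adjustment); at very low allele counts its
  asymptotic p-values are conservative, which the calibration test bounds
  but does not remove.
* The approval-odds maximum over a threshold sweep is a maximum of noisy
  estimates and therefore biased slightly upward relative to the planted
  relative risk; the estimate at the planted threshold is the unbiased
  readout, and both are reported.
* The infinitesimal-model weights are exact only under the generator's
  independent-SNP LD; with real LD panels the block solve is correct but
  block boundaries become a modelling choice.
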