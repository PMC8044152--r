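# bestgene

Drug targets backed by human genetics succeed in the clinic more often, and
the strongest version of that evidence is a **bidirectional allelic
series**: a gene in which gain-of-function variants push a phenotype one
way and loss-of-function variants push it the other. Such a gene behaves
like a natural dose–response experiment — it localises causality to the
gene, tells you which direction to modulate, and the healthy carriers of
the protective direction argue against gross toxicity. `bestgene`
implements the full analysis chain around this idea, for statistical
geneticists and target-discovery teams:

1. **Bidirectional screen** — scan a mutation catalog (gene / disease-label
   records) for genes with opposing disease associations on a shared
   phenotype axis, using an explicit direction lexicon plus a human-review
   export.
2. **Approval odds** — estimate the relative risk of clinical
   phase transitions for target–indication pairs supported by each class of
   genetic evidence, over a sweep of indication–trait similarity
   thresholds:
   `RR = (a/(a+b)) / (c/(c+d))` with Katz log-method confidence intervals.
3. **Rare-variant validation** — exome cohort QC (heterozygosity,
   singleton, het/hom, call-rate and relatedness filters; exact
   Hardy–Weinberg and reference-frequency concordance tests), consequence
   masks (protein-altering, PTV; within-cohort MAF < 1e-4), burden
   regression and the SKAT variance-component test
   `Q = rᵀ G W² Gᵀ r` with p-values from the Davies characteristic-function
   inversion of `Σ λᵢ χ²₁`.
4. **Polygenic stratification** — infinitesimal-model weights
   `w = (M/(Nh²) I + D)⁻¹ β̂`, score quintiles, carrier effects per
   stratum with Cochran's Q / I² heterogeneity, and ISS odds ratios
   against the mid-score non-carrier reference.
5. **Functional integration** — cGMP activity binning (< 0.2 low, > 1
   supranormal), activity–height regression, and comparison against an
   in-silico deleteriousness score.

Real inputs (HGMD, UK Biobank, clinical-trial outcome tables) are licensed
or access-controlled, so the package includes a seeded synthetic-data
generator that reproduces the statistical structure of every input —
planted bidirectional genes, a five-gene core set whose rare alleles lower
height by 0.20 SD on average with an idiopathic-short-stature odds ratio
near 2.75, a polygenic score explaining 20% of height variance, and a
4-fold approval enrichment for supported targets. All analyses run end to
end on generated data.

## Worked example

```r
library(bestgene)

cfg <- simulation_config(seed = 42, n_samples = 10000)

# screen the mutation catalog for bidirectional genes
cat_sim <- simulate_catalog(cfg)
screen  <- call_bidirectional(cat_sim$catalog)
screen$best_genes
#> # A tibble: 5 × 5
#>   gene     axis                           n_up n_down evidence
#>   <chr>    <chr>                         <int>  <int> <list>
#> 1 GENE0001 ldl cholesterol                   1      1 <chr [2]>
#> 2 GENE0002 stature                           1      1 <chr [2]>
#> 3 GENE0003 blood glucose                     1      1 <chr [2]>
#> 4 GENE0004 clotting factor viii activity     1      1 <chr [2]>
#> 5 GENE0005 qt interval                       1      1 <chr [2]>

# exome cohort: normalize height, define ISS, test the core gene set
co  <- simulate_cohort(cfg)
ph  <- define_iss(normalize_height(co$samples))
ph$sex <- co$samples$sex[match(ph$sample_id, co$samples$sample_id)]
ph$age <- co$samples$age[match(ph$sample_id, co$samples$sample_id)]
dos  <- co$dosages[ph$sample_id, ]
core <- co$variants$variant_id[co$variants$gene %in% co$truth$core_genes]

dplyr::bind_rows(
  burden_test(dos, core, "Set1+Set2", ph, "linear"),
  burden_test(dos, core, "Set1+Set2", ph, "logistic"))
#> # A tibble: 2 × 7
#>   unit      test            effect ci_low ci_high        p    ac
#> 1 Set1+Set2 burden_linear   -0.189 -0.268  -0.110 2.65e- 6   611
#> 2 Set1+Set2 burden_logistic  2.88   2.09    3.96  7.62e-11   611
```

The linear burden says each rare core-set allele lowers standardized
height by 0.19 SD (CI covering the planted −0.20); the logistic burden
says carriers have 2.9-fold odds of idiopathic short stature (planted
2.75), from 611 alleles in a 10,000-sample cohort. ISS prevalence in this
cohort is 2.41%, the Gaussian-tail expectation at z < −2.

`run_pipeline(pipeline_config(sim = cfg))` chains every stage (screen →
approval odds → QC → association → polygenic stratification → functional)
and returns all stage tables plus a provenance record.

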