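# pgtkaryo

Karyotype and crossover inference from preimplantation genetic testing
(PGT-A) SNP arrays, given phased parental haplotypes.

When embryo biopsies are genotyped on a SNP array and the parents'
genotypes are phased, the per-marker B-allele frequency (BAF) track along
a chromosome encodes which parental homologs the embryo inherited, in what
number, and where recombination switched between them. `pgtkaryo` turns
that signal into calls via a haplotype-copying hidden Markov model and
provides the downstream analyses it enables:

* **Whole-chromosome aneuploidy** — `infer_karyotype()` classifies each
  chromosome as nullisomy, maternal/paternal monosomy, disomy, or
  maternal/paternal trisomy, summing over copying paths so that phasing
  switch errors (a few percent of sites under population phasing) are
  absorbed rather than miscalled. Works on multi-cell biopsies including
  high-fraction mosaics.
* **Segmental aneuploidy** — `detect_segments()` scans the MAP state path
  for sub-chromosomal copy-number runs (filters: ≥ 100 SNPs, local
  posterior > 0.8, ≥ 5 Mbp).
* **Trisomy origin** — `posterior_bph()` / `classify_origin()` separate
  trisomies carrying both parental homologs (BPH, the meiotic signature)
  from single-duplicated-homolog trisomies (SPH, candidate mitotic);
  `calibrate_alpha()` calibrates the decision threshold against the
  maternal-age effect in a cohort.
* **Crossover mapping** — `call_crossovers()` locates meiotic crossovers
  in a template embryo by comparing transmitted-allele likelihoods against
  sibling embryos at informative markers, with majority-sibling support to
  cancel phasing errors.
* **Crossover count statistics** — `variance_decomposition()` (exact
  law-of-total-variance identity A = B + C), `intraclass_correlation()`,
  `permuted_null()`, `mean_crossover_count()` quantify nucleus-wide
  covariation of recombination across chromosomes.
* **Simulation** — `sim_parents()`, `sim_embryo()`, `sim_mosaic_biopsy()`,
  `sim_segmental()`, `sim_family()` generate synthetic cohorts (HWE
  haplotypes, switch errors, array-noise grid, mosaic biopsies, segmental
  events) and drive the validation suite.

Everything is tidyverse-native: tibbles in and out, `tidy()` / `glance()`
verbs, `ggplot2::autoplot()` methods.

## Worked example

Simulate phased parents (4,000 SNPs on a 35 Mbp contig, 3% per-site
phasing switch error applied to the inference-time haplotypes), draw a
maternal-trisomy embryo at moderate array noise, and call it — note that
inference uses the *phase-corrupted* grid, as it would in practice:

```r
library(pgtkaryo)

sim <- sim_parents(seed = 1)
emb <- sim_embryo(sim$truth, "trisomy_maternal", noise_params(0.5, 0.175),
  seed = 2)
fit <- infer_karyotype(emb$baf, sim$phased)
glance(fit)
#> # A tibble: 1 × 16
#>   embryo_id chrom call          posterior_max bayes_factor pi0_hat sigma_hat
#>   <chr>     <chr> <chr>                 <dbl>        <dbl>   <dbl>     <dbl>
#> 1 embryo1   sim1  trisomy_mate…         1.000      812176.   0.494     0.186
#> # ℹ 9 more variables: loglik <dbl>, n_sites <int>, n_observed <int>, ...

tidy(fit)
#> # A tibble: 6 × 4
#>   embryo_id chrom class                      posterior
#>   <chr>     <chr> <chr>                          <dbl>
#> 1 embryo1   sim1  nullisomy              0.00000000109
#> 2 embryo1   sim1  monosomy_maternal_loss 0.0000000483
#> 3 embryo1   sim1  monosomy_paternal_loss 0.000000166
#> 4 embryo1   sim1  disomy                 0.000000826
#> 5 embryo1   sim1  trisomy_maternal       1.000
#> 6 embryo1   sim1  trisomy_paternal       0.00000123
```

Is the extra maternal copy meiotic? A BPH posterior near 1 says both
maternal homologs are present — the meiotic signature:

```r
posterior_bph(fit)
#> [1] 0.99645
```

Map a crossover in a sibling family (here forced at 17 Mbp in the
template's maternal meiosis; the call is an interval between flanking
informative markers, supported by 4 of 4 siblings):

```r
fam <- sim_family(sim$truth, n_embryos = 5, noise = NULL, seed = 5,
  crossovers = list(list(maternal = 17e6, paternal = numeric(0))))
call_crossovers(fam$baf, sim$truth, "maternal",
  noise = noise_params(0.5, 0.05), templates = "embryo01")
#> # A tibble: 1 × 7
#>   parent   template_embryo_id chrom  left_bp right_bp n_supporting_siblings
#>   <chr>    <chr>              <chr>    <dbl>    <dbl>                 <int>
#> 1 maternal embryo01           sim1  16958193 17020310                     4
#> # ℹ 1 more variable: n_total_siblings <int>
```

See `vignette("haplotype-hmm-methods")` for the model, the emission and
transition design decisions, and the remaining components (mosaic
biopsies, segmental detection, α calibration, covariance statistics).

## Command-line interface

A thin optional CLI wraps the main operations (requires `optparse`):

```sh
Rscript inst/cli/pgtkaryo.R simulate --seed 1 --out-dir simdata
Rscript inst/cli/pgtkaryo.R infer --baf simdata/baf.tsv \
  --vcf simdata/parents.vcf --out calls.tsv
Rscript inst/cli/pgtkaryo.R validate --quick
```

## File formats

* Phased parental genotypes: VCF (two samples, phased GT).
* BAF tables: TSV with a versioned header line (`# pgtkaryo_baf v1`).
* Karyotype calls / crossovers: TSV. Segments: BED (0-based half-open).

## License

MIT, see `LICENSE`.
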