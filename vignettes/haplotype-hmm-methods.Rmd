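---
title: "Karyotype and crossover inference from embryo SNP arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype and crossover inference from embryo SNP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
  fig.width = 7, fig.height = 3.5)
set.seed(1)
```

```{r load}
library(pgtkaryo)
```

Preimplantation genetic testing for aneuploidy (PGT-A) genotypes a few
trophectoderm cells of an embryo on a SNP array. The array yields, per
marker, a B-allele frequency (BAF): a noisy estimate of the fraction of
chromosome copies carrying the B allele. When the parents' genotypes are
phased — so that each marker is annotated with the alleles on the mother's
two homologs $(m_0, m_1)$ and the father's two homologs $(p_0, p_1)$ — the
BAF track along a chromosome carries enough information to determine not
just *how many* chromosome copies the embryo inherited, but *which parental
homologs* they are, where recombination switched between them, and which
parent contributed an extra or missing copy.

`pgtkaryo` implements this inference as a haplotype-copying hidden Markov
model (HMM), plus the downstream analyses it enables: parental and
homolog-level origin of trisomies, crossover mapping across sibling
embryos, and cohort statistics of crossover counts. A simulator generating
data from exactly the model's assumptions (plus controlled violations such
as phasing switch errors and mosaicism) is a first-class part of the
package and drives its validation.

## The hidden state space

At each marker the embryo copies alleles from some multiset of parental
homologs. For an autosome we consider all copy numbers 0–3:

* **nullisomy** — no copy, 1 state;
* **monosomy** — one copy: maternal loss (embryo keeps $p_0$ or $p_1$) or
  paternal loss ($m_0$ or $m_1$), 2 + 2 states;
* **disomy** — one maternal and one paternal homolog, $2 \times 2$ states;
* **trisomy** — two copies from one parent and one from the other, 6
  states per trisomic parent: the multiset of two maternal homolog labels
  ($\{m_0,m_0\}, \{m_0,m_1\}, \{m_1,m_1\}$) crossed with the paternal
  homolog, and symmetrically.

```{r states}
st <- karyotype_states("autosome")
dplyr::count(st, class)
```

Sex chromosomes use reduced spaces (e.g. no second paternal X homolog).
The trisomy states containing *both* homologs of the trisomic parent
(`m0/m1/p0`, `m0/m1/p1` for a maternal trisomy) are the **BPH** ("both
parental homologs") states; the others carry a single duplicated homolog
(**SPH**). This distinction is the basis of the meiotic/mitotic origin
classifier below.

## Emission model

Let $\mu$ be the expected BAF of a state at a marker: the mean of the B
allele over the copied homologs (e.g. $\mu = (m_0 + p_1)/2$ for the disomy
state $m_0/p_1$). Observed BAF $b \in [0,1]$ is modelled as a two-part
mixture governed by noise parameters $(\pi_0, \sigma)$:

* with probability $\pi_0$, a **boundary atom**: arrays rail homozygous
  signals exactly to 0 or 1, so states with $\mu = 0$ (or $\mu = 1$) place
  a point mass there;
* with probability $1 - \pi_0$, a **truncated normal** on $[0,1]$ centred
  at $\mu$ with scale $\sigma$.

Nullisomy has no genotype signal; its BAF is pure noise, modelled as a
truncated normal centred at $1/2$ with no atom. Missing observations
contribute unit likelihood.

Two deliberate design points:

1. **Boundary observations are scored on a mixed dominating measure.** A
   density and a point mass are not comparable quantities; to keep the
   likelihood of $b \in \{0, 1\}$ finite and $\pi_0$ identifiable, an atom
   observed at the boundary is scored as $\pi_0 / w + (1-\pi_0) f(b)$ with
   a fixed narrow bin width $w = 10^{-6}$ (`baf_atom_width`). This is
   equivalent to treating railed values as "within $w$ of the boundary"
   and affects all states equally, so posterior odds between states are
   driven by whether each state *predicts* an atom there.
2. **Intermediate dosages carry no atom by default.** One printed variant
   of this emission family places the $\pi_0$ atom at $b = 1$ even when
   $0 < \mu < 1$, which makes heterozygous-site draws collapse onto a
   boundary shared by many states and measurably degrades both noise
   estimation and disomy/trisomy separation. The package default
   (`else_atom = "none"`) restricts atoms to homozygous dosages; the
   printed variant remains available via `else_atom = "delta1_as_printed"`
   for comparison.

## Transitions

Hidden states change along the chromosome for two reasons: genuine
recombination and *phasing switch errors* in the parental reference
(population phasing flips $m_0 \leftrightarrow m_1$ from some marker
onward at a few percent of sites). Both events exchange homolog labels
**within** a ploidy class. Changes **between** classes — a genuine copy
number change within a chromosome — are vastly rarer (segmental
aneuploidy). The transition model therefore uses two per-base-pair rates:
$r = 10^{-8}$ between states of the same class and $a = 10^{-10}$ across
classes, with off-diagonal probability proportional to the marker gap $d$
(clamped via $1 - e^{-\text{rate} \cdot d}$ for pathological gaps).

Grouping by *class* rather than by copy number matters: maternal and
paternal trisomy share copy number 3, but letting them swap at the cheap
rate $r$ would allow phase-invariant state combinations to absorb switch
errors that the disomy states must pay for, biasing calls toward trisomy.

The forward–backward recursion exploits the two-rate structure: each step
needs only per-class sums, giving $O(S)$ work per state per site instead
of $O(S^2)$; the core is implemented in C++.

## Calling karyotypes

`infer_karyotype()` runs forward–backward over the joint state space
(all classes at once, uniform prior), yielding per-site posteriors
$\gamma$. The **class posterior** is the chromosome-average of the summed
within-class $\gamma$; a class is *called* when its posterior exceeds 0.9
and beats the runner-up by a Bayes factor of at least 2, otherwise the
chromosome is reported as no-call. Noise parameters are fitted per
chromosome by maximum likelihood (`fit_noise()`, grid-started L-BFGS-B)
unless supplied.

```{r infer}
sim <- sim_parents(seed = 1)          # 4,000 SNPs on 35 Mbp, 3% switch error
emb <- sim_embryo(sim$truth, "trisomy_maternal", noise_params(0.5, 0.175),
  seed = 2)
fit <- infer_karyotype(emb$baf, sim$phased)   # note: phase-corrupted grid
glance(fit)
```

Because the model sums over *paths* of homolog labels, it is robust to the
switch errors injected above: a phase flip costs one within-class
transition rather than corrupting every downstream marker.

```{r autoplot}
ggplot2::autoplot(fit)
```

### Mosaicism

A multi-cell biopsy averages BAF over cells; a chromosome monosomic in 90%
of cells produces dosages close to, but not exactly at, the haploid
expectations. The HMM scores such intermediate signals through the same
emission model, and high-fraction mosaics are still called as the
aneuploid class:

```{r mosaic}
bio <- sim_mosaic_biopsy(sim$truth, "monosomy_paternal_loss", n_cells = 10,
  n_aneuploid = 9, noise = noise_params(0.5, 0.175), seed = 3)
fit_m <- infer_karyotype(bio$baf, sim$phased, noise = noise_params(0.5, 0.175))
round(fit_m$class_posteriors, 3)
```

### Segmental aneuploidy

`detect_segments()` scans the maximum-a-posteriori state path for runs
whose class differs from the chromosome's majority class, then applies
three filters — at least 100 SNPs, mean local posterior above 0.8, and at
least 5 Mbp — reporting half-open genomic intervals:

```{r segmental}
seg <- sim_segmental(sim$truth, "trisomy_paternal", start_bp = 12e6,
  end_bp = 20e6, noise = noise_params(0.5, 0.175), seed = 4)
detect_segments(infer_karyotype(seg$baf, sim$phased))
```

## Trisomy origin: BPH versus SPH

A trisomy arising in meiosis (chiefly meiosis I nondisjunction) brings
*both* homologs of one parent into the embryo, at least near the
centromere; a trisomy arising mitotically duplicates the single
transmitted homolog, so the two like-parent copies are identical
everywhere. `posterior_bph()` measures, per site, the fraction of
trisomy-class posterior mass in the BPH states and averages it along the
chromosome; crossovers erode the BPH signal away from the centromere, so
even meiotic trisomies show intermediate values.

`classify_origin()` thresholds this statistic at $\alpha$. Rather than
fixing $\alpha$ by fiat, `calibrate_alpha()` exploits an epidemiological
constraint: mitotic errors show no maternal-age effect, while meiotic
errors rise steeply with age. For each candidate threshold the
embryos labelled mitotic are regressed on maternal age (binomial GLM) and
the calibrated $\alpha$ is the largest threshold whose "mitotic" set
still retains a null age effect.

## Crossover mapping across sibling embryos

IVF families contain several sibling embryos sharing the phased parents.
For markers where one parent is heterozygous and the other homozygous
(*informative* markers for that parent), the BAF of a disomic embryo
reveals which of the parent's homologs it received. Fixing a *template*
embryo, `call_crossovers()` computes for each sibling and each
consecutive pair of informative markers a log-likelihood ratio comparing
"template and sibling transmit the same parental homolog at both markers"
against "opposite homolog", marginalizing over the unobserved transmitted
alleles. Sign changes of this LLR along the chromosome mark either a
template crossover (reflected in *most* siblings, since their own
transmissions are independent) or a sibling's own crossover (specific to
one). Candidate switch points are clustered, clusters with odd parity
produce candidate crossovers, and a call requires strict majority support
among at least `min_siblings` informative siblings — this also cancels
phasing switch errors, which would otherwise mimic crossovers in *every*
embryo and are instead absorbed into the shared reference.

```{r crossovers}
fam <- sim_family(sim$truth, n_embryos = 5, noise = NULL, seed = 5,
  crossovers = list(list(maternal = 17e6, paternal = numeric(0))))
call_crossovers(fam$baf, sim$truth, "maternal",
  noise = noise_params(0.5, 0.05), templates = "embryo01")
```

## Crossover count statistics

Genome-wide crossover counts vary between embryos for two separable
reasons: independent per-chromosome variation, and nucleus-wide factors
that raise or lower recombination on *all* chromosomes of a meiosis at
once. With per-embryo, per-chromosome counts in a matrix, the law of
total variance gives an exact decomposition
$A = B + C$: total variance of genome-wide counts ($A$), the sum of
per-chromosome variances ($B$), and the inter-chromosomal covariance
($C$). `variance_decomposition()` reports these and $C/A$;
`intraclass_correlation()` gives the equivalent one-way random-effects
ICC with its F test; `permuted_null()` destroys covariance while keeping
marginals as a calibration null.

```{r costats}
u <- rgamma(300, 2, 2)                    # shared per-meiosis intensity
counts <- matrix(rpois(300 * 22, rep(u, 22) * 2), 300, 22)
variance_decomposition(counts)
intraclass_correlation(counts)
variance_decomposition(permuted_null(counts, seed = 1))$c_over_a
```

## Simulator and validation

All components are validated against `sim_parents()` /
`sim_embryo()` and friends, which generate: marker grids with uniform
positions and Hardy–Weinberg genotypes; a phase-corrupted copy of the
parental haplotypes (per-site switch probability 3%) standing in for
population phasing at inference time; meioses with Poisson crossovers;
BAF draws from the emission model over a $(\pi_0, \sigma)$ grid; mosaic
biopsies; and segmental events. The package's acceptance suite
(`tests/testthat/test-acceptance.R`, full scale in
`scripts/acceptance.R`) checks per-class precision/recall of karyotype
calls, mosaic monosomy posteriors, segmental precision, exhaustive-
enumeration equivalence of the forward algorithm, noise-parameter
recovery, exact crossover recall on noiseless families, and the
statistics identities.
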