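---
title: "Phenotyping mutant embryo atlases: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping mutant embryo atlases: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscape)
```

phenoscape implements the analytical core of a whole-embryo single-cell
phenotyping workflow: given sparse count matrices and low-dimensional
embeddings for cohorts of mutant and wild-type mouse embryos, it asks where
in transcriptional space mutant cells are enriched or depleted, which cell
types change in proportion, how similar embryos and genotypes are to one
another, and whether a mutant is developmentally delayed relative to a
staged reference atlas. This vignette describes each model, the tunable
parameters that matter, the synthetic cohorts the package tests itself
against, and the numerical decisions taken where the design was genuinely
open.

## The lochNESS score

For one mutant against a pooled wild type, every cell receives

$$\mathrm{lochNESS} = \frac{\#\{\text{mutant cells among } k\text{-NNs}\}/k}
{m/N} - 1,$$

where $N$ is the dataset size, $m$ the number of mutant cells, and
$k = \sqrt{N}/2$ scales with the dataset (rounded half-even, floored at 1).
Cells of the focal cell's own embryo are excluded from its neighbourhood so
that a cell is never scored against its own replicate. The score is the
fold change of the local mutant fraction over the global one, minus one:
0 means perfect mixing, $-1$ means no mutant neighbours, and the maximum
$1/(m/N) - 1$ means an all-mutant neighbourhood.

Neighbour search is exact (chunked squared-Euclidean distances), with ties
at identical distance resolved toward the lower cell index so that results
are reproducible and testable against a brute-force reference
implementation. Approximate search is deliberately avoided: at the
per-trajectory dataset sizes this package targets (thousands to tens of
thousands of cells in $\le 30$ dimensions) exact search is affordable, and
exactness is what lets the test suite require equality with an independent
oracle rather than "close enough".

Two properties of the score are worth knowing:

* **Discreteness.** With neighbourhood size $k$ the score takes $k + 1$
  values. Quantiles of its null distribution therefore sit on mass points,
  and the fraction of cells strictly beyond a pooled null quantile can fall
  visibly below the nominal tail mass even under perfect calibration. The
  test suite handles this by comparing observed exceedance with the null's
  own exceedance at the same threshold.
* **Baseline bias at few embryos.** The denominator uses the global $m/N$
  although same-embryo cells are excluded from the neighbourhood, exactly as
  the score is defined. A mutant cell's eligible pool then contains a
  mutant fraction of $(m - n_e)/(N - n_e)$, slightly below $m/N$, and
  conversely for wild-type cells. With around a hundred embryos (each
  $\sim 1\%$ of cells) this bias is negligible; with a handful of large
  embryos it reaches a sizeable fraction of the null standard deviation.
  Calibration checks in this package therefore use cohorts of many small
  embryos, and users with few embryos should interpret tail counts against
  the permutation null, not against a nominal level.

**Permutation null and deviance.** `lochness_null()` recomputes the score
under random permutations of the mutant/wild-type labels, reusing the
neighbour graph (valid because neighbours do not depend on labels). By
default labels are permuted at the cell level, matching the score's
definition of exchangeability; an embryo-level mode is available for users
worried about within-embryo correlation. The deviance of a score vector is
the average Euclidean distance to the permuted vectors, paired per cell.
The distance is divided by $\sqrt{n_\text{cells}}$ (a per-cell RMS) so
deviances are comparable across sub-trajectories of different sizes, which
the screening heat-map needs; the raw Euclidean distance is available via
`normalize = "none"`. Pairing observed and permuted scores per cell (rather
than comparing sorted distributions) is the default because it is sensitive
to *where* the shifts happen, not only to the marginal shape.

**LISI comparison.** `compute_lisi()` implements the local inverse Simpson
index with Gaussian-kernel weights tuned by binary search to a perplexity of
$\lfloor 0.5\sqrt{N/3}\rfloor$ over $K = 3 \times \text{perplexity}$
neighbours. The formula's typesetting admits a second reading,
$\lfloor 0.5\sqrt{N}/3 \rfloor$; the $\sqrt{N/3}$ reading is the default
here because it keeps $K$ close to the lochNESS neighbourhood size. Note
that at small perplexities a perfectly mixed two-label neighbourhood does
not reach LISI 2: with $\sim 5$ effective neighbours, sampling noise alone
keeps the index near 1.7. Comparisons of mixed versus separated data should
either fix a larger perplexity or compare against a matched null.

**Score-linked genes.** `lochness_gene_assoc()` fits, per gene, a
negative-binomial GLM of counts on the cell's lochNESS with the log size
factor as offset, tests the coefficient with a Wald test, and adjusts across
genes by Benjamini–Hochberg. Genes with adjusted $p < 0.05$ and positive
(negative) coefficients are reported as associated with mutant-enriched
(depleted) territory. A Poisson GLM is the fallback when the NB fit fails
to converge (typically near-zero-count genes). One caveat inherent to BH at
a 5% target: when only a couple of dozen genes are truly linked, the
realized false-discovery proportion of a single experiment is quantized in
steps of $\sim 1/\#\text{calls}$ and will exceed 5% in a sizeable minority
of experiments even though the expected FDR is controlled.

## Composition testing

Cells are cross-tabulated into an embryo × cell-type matrix. Counts are
normalized by per-embryo size factors (total over geometric mean of totals,
so log factors sum to zero), cell types whose normalized mean count per
embryo is below 10 are not tested, and the remaining normalized counts are
rounded to integers (the regression needs integer trials; the mean filter
is applied before rounding so a type at 9.9 stays untested). For each
mutant genotype within its background strain, each type is tested against
the pooled reference — all other embryos of the same background, wild type
and other mutants alike — with a beta-binomial regression:
$k_i \sim \mathrm{BetaBin}(n_i, \mu_i, \rho)$,
$\mathrm{logit}(\mu_i) = \beta_0 + \beta_1\,\mathrm{genotype}_i$, with one
overdispersion $\rho$ shared across embryos (genotype enters only the
mean). The fit is by maximum likelihood (`nlminb` on
$(\beta_0, \beta_1, \mathrm{logit}\,\rho)$) restarted from the binomial
solution with $\rho \in \{0.001, 0.01, 0.1\}$ and polished from the winning
point; if the binomial boundary $\rho \to 0$ dominates, the binomial GLM
solution is returned with $\rho = 0$. The genotype effect is tested by Wald
from the observed information, falling back to a likelihood ratio when the
Hessian is near-singular. Significance is reported at an uncorrected 0.05
and flagged as nominal — no correction across types, by design, since
downstream interpretation treats these as screening calls.

With four embryos per genotype the Wald test runs slightly hot: measured
type-I rates on null cohorts are around 7–11% at a nominal 5%, tightening
toward the nominal level as replicates grow. This is a small-sample
property of the test itself, not of the implementation, and is shared by
any ML-based Wald test at $n = 8$.

Effect summaries are log2 proportion ratios of merged counts,
$\log_2\frac{(k_\mathrm{mut}+\tfrac12)/(N_\mathrm{mut}+\tfrac12)}
{(k_\mathrm{ref}+\tfrac12)/(N_\mathrm{ref}+\tfrac12)}$, with the 0.5
pseudocount guarding zeros; display values are clipped at $\pm 2$.

## Power simulation

`simulate_power()` measures the detection power of the composition test as
a function of cell-type abundance, effect size and replicate number. Each
grid point simulates paired cohorts from the Dirichlet model below, applies
the effect to one focal type at a time (an effect size of 0.1 multiplies
that type's mutant counts by 0.9), runs the same beta-binomial test, and
reports the rejection fraction at $\alpha = 0.05$. Power above 0.8 is
taken as "sufficient" detection, the standard convention, exposed in the
configuration.

## The synthetic cohorts

The generators define the study conditions every test runs under.

**Composition cohorts** (`simulate_composition_cohort()`): per-embryo cell
totals are truncated-normal (mean 15,000, SD 3,000, floor 100 — the scale
of a sci-RNA-seq3 embryo); 20 cell types by default, with baseline
proportions on a geometric ladder from ~15% down to ~0.8%; per-embryo
proportions are Dirichlet draws $\mathrm{Dir}(c \cdot p)$ around the
baseline; counts are the product of proportions and totals (rounded), with
mutant counts multiplied by $1 - \text{effect}$. The concentration default
is $c = 8000$, which gives a replicate-to-replicate CV of about 11% for a
1%-abundance type (and ~2.5% for a 15% type). This value was chosen to
match the replicate variability implied by the detectability the method is
known to achieve on real cohorts — a 25% shift in a 1% type is reliably
detectable with four replicates per group — which pins the per-embryo CV of
rare types near 10–15%; looser concentrations (CVs of 30–40%) would make
that regime undetectable at any realistic replicate number. The
concentration is a single exposed parameter, so users can re-run the power
analysis under their own replicate variability. Note one structural
consequence of the product-form generator (no multinomial sampling on top
of the Dirichlet): tight concentrations make very small effects on abundant
types marginally detectable at large replicate numbers, so "1% effects are
undetectable" holds in the sense of power far below any useful threshold,
not power exactly at $\alpha$.

**Embedding cohorts** (`simulate_embedding_cohort()`): Gaussian-mixture
blobs in $d \ge 2$ dimensions with genotype-specific mixture weights; an
enriched component with higher mutant weight creates localized enrichment
for lochNESS and screening to find. **Expression**
(`simulate_expression()`): gamma-Poisson counts (dispersion 0.5) with
lognormal gene means, per-cell library factors spanning at least two-fold,
and selected genes whose log-mean is shifted by slope × covariate.
**Reference timecourse** (`simulate_reference_timecourse()`): stages E9.5
to E13.5, each a blob displaced along the first axis by a drift per day with
isotropic noise.

What these generators deliberately do not model: gene–gene correlation,
batch effects, embryo-level random effects in embedding space, doublets, or
ambient RNA. Passing tests therefore demonstrate correctness of the
statistics and calibration under clean exchangeability — not robustness to
every artefact of real data.

## Similarity, staging and delay

`embryo_similarity()` scores, for each cell and each target embryo, the
observed over expected fraction of that embryo among the cell's $k$ nearest
neighbours ($k = \sqrt{N}/2$ again), and averages over the cells of each
scoring embryo. Only the query cell itself is excluded from its
neighbourhood — same-embryo neighbours count toward the diagonal, which is
what makes within-embryo coherence visible. Per cell, neighbour counts sum
to $k$, so the $n_j/N$-weighted row mean is exactly 1 (asserted at run
time); under exchangeable positions every entry has expectation 1.
`genotype_similarity()` averages embryo-level entries within genotype
pairs, excluding each embryo's self-pair; averaging embryos first (rather
than pooling cells) keeps each embryo equally weighted regardless of its
cell count. The observed/expected construction is directional, so the
matrix need not be symmetric.

Whole-embryo staging: pseudobulk profiles (summed counts per embryo) are
size-factor normalized, $\log_2(x+1)$-transformed (pseudocount 1), and
decomposed by centered — not variance-scaled — PCA; external embryos are
projected with the stored center and rotation. Centering-only is the
appropriate choice for pseudobulk staging, where the dominant variance axis
is developmental age and rescaling genes would dilute it.

Developmental delay: each query cell's time score is the mean stage label
of its $k = 10$ nearest reference cells (the reference neighbourhood size
is not dictated by the data size here, so it is a plain configurable
constant), and genotypes are compared by a two-sided Welch test on
cell-level scores. Cell-level testing pseudoreplicates — cells of one
embryo are not independent — so an embryo-level mode (average within
embryos first) is provided and recommended whenever embryo numbers allow.

## Trajectory matching across atlases

For trajectories $a$ in atlas A and $b$ in atlas B, aggregate profiles
(summed log-normalized counts per trajectory) are compared by reciprocal
non-negative least squares: predict $T_a$ from all of B's trajectories and
$T_b$ from all of A's, each on the union of the target's 3,000 most highly
expressed and 3,000 most specific genes, where specificity is the target's
share of the gene's across-trajectory total. The two directional
coefficients combine as
$\beta = 2(\beta_{ab} + 0.001)(\beta_{ba} + 0.001)$ — large only when
prediction is reciprocal and specific; the 0.001 offset keeps the product
strictly positive and is retained verbatim rather than rescaled. NNLS uses
the Lawson–Hanson active-set solver with the intercept freed by mean
centering, so only slopes are sign-constrained.

## Numerical choices, in one place

* kNN ties: lower cell index wins (stable radix order); shared by the test
  oracles.
* $k$ rounding: `round()` (half-even), floor 1.
* Beta-binomial: $\rho$ optimized on the logit scale within
  $[10^{-6}, 0.95]$, coefficients within $\pm 15$; binomial boundary taken
  when it dominates; Wald first, LR fallback.
* Deviance: per-cell pairing, RMS normalization (raw available).
* Label transfer tie-breaks: vote, then smallest mean neighbour distance,
  then lexicographic label.
* Degenerate inputs: all-cells-removed filters warn rather than error;
  zero-variance delay tests return a flagged limit instead of NaN.
* Randomness: every generator takes an explicit seed; pipeline stages
  derive seeds from `pipeline_config(seed)` plus fixed stage offsets, so a
  full run is reproducible end to end.

## Problem sizes in the shipped checks

The package's own verification runs on cohorts of 2,400–5,000 cells,
permutation nulls of 50–100 replicates, power grids of 100 simulations per
point, and 100-cohort parameter-recovery studies — sizes chosen so the
whole suite exercises every claim at meaningful Monte-Carlo precision while
remaining quick to run. All of them scale up by changing the design
objects; nothing in the implementation is specific to these sizes.
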