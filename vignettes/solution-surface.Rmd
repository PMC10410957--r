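---
title: "The solution surface of the haplotype copying model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The solution surface of the haplotype copying model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lssurface)
```

## The model

The Li-Stephens (LS) haplotype copying model treats a focal chromosome of
$L$ linked markers as an imperfect mosaic of $N$ template haplotypes
$\mathbf H \in \mathcal D^{L\times N}$.  A *copying path*
$\pi \in [N]^L$ names the template copied at each site; the path follows a
stationary Markov chain (template switch with probability $p_\rho$ per
transition, new template uniform over all $N$), and the copied allele is
corrupted with per-site error probability $p_\theta$.  Up to an additive
constant the negative log-likelihood of a path is

$$-\log p(h \mid \pi) = \alpha(\theta)\, m(\pi) + \beta(\rho)\, k(\pi) + C,$$

where $m(\pi)$ counts mismatches between $h$ and the copied alleles,
$k(\pi)$ counts template switches, and the penalties are
$\alpha = -\log \frac{p_\theta}{1-3p_\theta}$,
$\beta = -\log \frac{p_\rho}{1-N p_\rho}$.  The Viterbi (maximum a
posteriori) decoding minimizes this cost.  We consider only this
frequentist decoding; posterior/forward-backward quantities change
continuously with the parameters and are outside the package's scope.
The inter-site switch probability is constant (no per-site recombination
map), which is appropriate for dense, fairly uniform marker panels.

Two facts organize everything here:

1. **Only the ratio matters.**  Rescaling the cost by $\alpha$ shows that
   the set of optimal paths depends on $(\theta,\rho)$ only through
   $c = \beta(\rho)/\alpha(\theta)$ (`penalty_ratio()`), so the
   two-parameter plane collapses to the single penalty axis
   $\beta \in (0,\infty)$ with the mismatch penalty normalized to 1.
   `equivalence_curve()` traces the one-dimensional family of
   $(p_\theta, p_\rho)$ pairs sharing one $c$.

2. **The optimum is a lower convex hull of lattice points.**  Writing
   $J_L(r)$ for the least mismatch count among paths with exactly $r$
   switches, the optimal cost at penalty $\beta$ is
   $\min_r J_L(r) + \beta r$ — a minimum of finitely many lines.  The
   minimizers as $\beta$ sweeps $(0,\infty)$ are exactly the vertices of
   the lower convex hull of $\{(r, J_L(r))\}$, and the penalty axis is
   partitioned at the exact rational breakpoints
   $\beta_i = (J(r_i) - J(r_{i+1}))/(r_{i+1} - r_i)$
   (`chain_breakpoints()`).  Because all coordinates are integer
   counts, every hull and breakpoint is computed in exact integer/rational
   arithmetic: results are bit-identical across platforms and immune to
   floating-point concerns.

## The single-pass algorithm

A naive approach would maintain the piecewise-linear value function of the
classical Viterbi recurrence for all $\beta$ simultaneously; computing
pointwise minima of $N$ piecewise-linear functions per site is correct but
far too slow, and survives here only as a validation oracle
(`j_table()`, `viterbi_haploid()`).

Instead the package propagates *frontiers* of integer cost points.  For
each template $n$, the locally active chain $F^{(n)}_\ell$ is the
lower-left hull of $(k(\pi), m(\pi))$ over paths ending at $n$; the global
chain $G_\ell$ merges them.  Moving to site $\ell+1$ with mismatch
indicator $d$, every vertex of $F^{(n)}_{\ell+1}$ arises either from
$F^{(n)}_\ell$ without a switch, shifted to $(r, m+d)$, or from
$G_\ell$ with one switch, shifted to $(r+1, m+d)$; hulling the candidate
union completes the step.  Only hull vertices are ever stored.  One pass
over the sites yields $\mathrm{vtx}(\mathcal J_L)$, the breakpoints, and —
via backpointers recorded per surviving vertex — one representative
optimal path per region (`partition_haploid()`).

The *lower-left* restriction is deliberate: since $\beta > 0$, vertices on
segments of slope $\ge 0$ (more switches without fewer mismatches) are
never optimal, so each chain keeps only the strictly convex,
strictly-decreasing-$m$ portion ending at the minimal-mismatch vertex.
For the same reason the truncated-epigraph boundary points play no
computational role and are not materialized.  Candidate sets are allowed
to contain formally inadmissible points (e.g. a "switch" candidate whose
parent path already ends at the same template): such a point ties an
admissible candidate in $m$ at strictly larger $r$, so it can never
become a chain vertex; the exhaustive-enumeration tests confirm this.

The diploid decoder (`partition_diploid()`) tracks unordered template
pairs ($m$ is symmetric in the two paths, so ordered pairs are
redundant).  Per pair, candidates come from the pair's own chain (no
switch), from the two per-template "partially active" chains (one
coordinate switches), and from the global chain (both switch), at
$r$, $r+1$, $r+2$ respectively.  Work per site is one hull update per
unordered pair, i.e. $\Theta(N^2)$ — the practical limit on panel size;
panels beyond a few hundred templates are out of scope.

Both production passes are implemented in compiled code (integer
arithmetic throughout); `frontier_init()`/`extend_frontier()` expose the
haploid recurrence step in plain R and the test suite checks the two
routes against each other and against three independent oracles
(exhaustive path enumeration, fixed-penalty Viterbi with exact rational
$\beta$, and the direct $J$-table recurrence).

### Determinism and tie-breaking

Ties are resolved by fixed rules so outputs are reproducible:

* candidate points with equal $(r, m)$ prefer the no-switch (then
  fewer-switch) parent, then the lower template or pair index;
* exactly at a breakpoint both flanking vertices are optimal;
  `region_for_beta()` returns the smaller-$r$ vertex and flags the tie;
  regions are reported as half-open intervals $[\beta_i, \beta_{i-1})$;
* representative paths are one deterministic choice among the possibly
  many optimal paths per region.  Downstream losses are defined with
  respect to this representative; any quantity that depends on *which*
  optimal path is chosen inherits that (documented) arbitrariness.

## A worked example

```{r}
H <- matrix(c("a", "c",
              "c", "a"), nrow = 2, byrow = TRUE)  # two sites, two templates
h <- c("c", "c")
s <- partition_haploid(h, allele_matrix(H))
s
reconstruct_path(s, 2)
```

Copying template 2 then template 1 reproduces `h` exactly at the price of
one switch; staying on either template costs one mismatch.  The two
decodings exchange optimality exactly at $\beta = 1$.

## Synthetic data

`generate_panel()` builds panels sequentially: an ancestral background
haplotype, then each new haplotype copies from its predecessors under the
copying model itself (switch probability growing with the number of
available templates, copy errors seeding new variants).  This mimics the
allele-frequency and linkage structure of resequencing panels — a
decreasing site-frequency spectrum and mosaic relatedness — while staying
a pure function of its seed.  It is not a coalescent-with-recombination
simulator: genealogies are not exchangeable, variance in coalescence
depth is understated, and physical positions are abstract.  Tests passing
on mosaic panels therefore demonstrate algorithmic correctness and
realistic cost-surface shapes, not population-genetic calibration.  For
the study pipelines, `simulate_panel_msprime()` drives the msprime
coalescent simulator (through the bundled Python script) with either a
constant-size population or a built-in single-population African growth
history (ancestral size 7310; 14474 from 5920 generations ago;
1.66%/generation exponential growth from roughly 205 generations ago),
returning only biallelic segregating sites under a binary mutation model.

`sample_focal()` draws a focal haplotype from the generative model itself
and returns the latent path, giving every experiment a known truth; on
the biallelic alphabet a copy error flips the allele (the
uniform-over-three-alternatives rule degenerates), so the expected
mismatch count of the true path is $L p_\theta$.

## The imputation and phasing studies

`run_imputation_replicates()` repeats the following: simulate a panel and
focal haplotype; compute minor allele frequencies over *all* chromosomes
including the focal (the filter is applied to the sample before the
focal/panel split) and mask sites with MAF below 0.05; build the solution
surface on the retained markers; impute each masked site by copying, at
the nearest retained marker (ties to the left; leading sites use the
first marker), the allele of that region's representative path; score
with Hamming loss and with inverse-variance weights
$[\mathrm{MAF}(1-\mathrm{MAF})]^{-1}$ taken from the full pre-masking
sample (masked sites have no post-masking frequency by construction).
Per replicate and loss, the penalty axis yields a piecewise-constant loss
curve; `optimal_interval()` reports the maximal contiguous minimal-loss
runs (primary = smallest lower bound, multimodality flagged).  Because
desk-scale losses are small integers, minima are often tied across
non-contiguous runs; the headline per-replicate indicator is therefore
whether the *reference* penalty's region attains the minimal loss, where
the reference $c = \beta(\rho_0)/\alpha(\theta_0)$ comes from the
generative rates (for coalescent panels, the per-marker scaled rates are
the per-bp rates times the mean retained-marker spacing).

`run_phasing_replicates()` analogously phases an unphased genotype formed
from two simulated haplotypes and scores each region's representative
pair by switch error, following the usual convention: only sites
heterozygous in both truth and estimate with matching alleles are
compared, and the count is the number of adjacent orientation flips.
At mismatch sites the phased output emits the copied template alleles,
not the genotype's.

**Problem sizes.**  The original studies use 1000 replicates of
100 Mb panels with 1000 templates; at that scale a single replicate takes
hours.  The package's studies are scaled down to what a single CPU
handles comfortably while keeping roughly $10^4$ segregating sites and a
200-template panel (4 Mb at scaled rates $10^{-4}$ for the constant-size
study; 2 Mb at rates chosen to give scaled per-bp values near
$8.7\times10^{-4}$ and $9.8\times10^{-4}$ for the growth demography;
24 replicates), and a 100-template, 1 Mb diploid phasing study.  At this
scale the qualitative structure of the full studies — the reference
penalty is optimal for imputation much more often under Hamming loss than
under the rare-variant-upweighting loss, and phasing error is minimized
at or above the reference penalty — reproduces clearly; the quantitative
advantage of the growth demography over the constant-size model, which
the full protocol exhibits, does not survive this degree of downscaling
(small panels change nearest-relative structure under recent growth far
more than under constant size), and the package reports rather than
asserts it.

## Numerical and design choices

* **Exactness.**  Hulls, breakpoints, and oracle comparisons use integer
  and reduced-rational arithmetic only; rational penalties are compared
  by cross-multiplication.  Oracle-versus-surface tests assert equality,
  never tolerance.
* **Diploid mismatch semantics.**  The per-site diploid mismatch is the
  size of the *set* symmetric difference between genotype and copied
  alleles, exactly as the likelihood defines it; for biallelic data this
  equals the absolute dosage difference (property-tested), and the set
  convention for exotic non-biallelic cases (e.g. `{a,a}` vs `{c,c}`,
  which scores 2) is a documented choice.
* **Parameter maps.**  The coalescent-motivated map
  $p_\theta = (1 - e^{-\theta/N})/3$ is the default; the original
  $p_\theta = \tilde\theta/[2(N+\tilde\theta)]$ map is available as
  `model = "original"`.  Both enforce $p_\theta < 1/4$ and
  $p_\rho < 1/(N+1)$ so the penalties stay positive.
* **Degenerate inputs.**  Single-site panels, single-template panels
  (no switches possible), and single-vertex surfaces (no breakpoints;
  one region covering all $\beta$) are all well-defined and tested.
* **Known limitations.**  No per-site recombination map; no posterior
  decoding; diploid panels beyond a few hundred templates are
  impractical ($\Theta(N^2)$ per site); switch-error parity with any
  particular external tool build is not asserted, only the convention.
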