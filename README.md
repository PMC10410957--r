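# lssurface

Exact solution surface of the Li-Stephens (LS) haplotype copying model.

The LS model decodes a focal chromosome of `L` markers as a mosaic of `N`
template haplotypes: a copying path `π` pays `α(θ)` per allele mismatch and
`β(ρ)` per template switch,

```
-log p(h | π, H, θ, ρ) = α(θ) m(π) + β(ρ) k(π) + C ,
```

and the Viterbi decoding minimizes this cost. Because the output depends on
`(θ, ρ)` only through `c = β(ρ)/α(θ)`, and because the optimum at penalty
`β` is `min_r J_L(r) + β r` with `J_L(r)` the least mismatch count among
paths with exactly `r` switches, the whole family of decodings is governed
by the lower convex hull of the integer points `(r, J_L(r))`. This package
computes that hull — and hence **every** optimal decoding for **all**
penalty settings — in a single pass over the data, with exact integer
arithmetic and exact rational breakpoints, for both a focal haplotype
(`partition_haploid()`) and an unphased diplotype over path pairs
(`partition_diploid()`, `Θ(N²)` work per site).

Who this is for: anyone studying how the mutation/recombination penalty
setting affects LS-based genotype imputation and phasing — the package
bundles the downstream pipelines (MAF masking, nearest-flanking-marker
imputation, Hamming and inverse-variance-weighted losses, switch error),
slow reference decoders for validation, a self-contained mosaic panel
simulator, and an optional msprime coalescent hook.

## A worked example

```r
library(lssurface)
H <- matrix(c("a", "c",
              "c", "a"), nrow = 2, byrow = TRUE)  # 2 sites x 2 templates
h <- c("c", "c")
s <- partition_haploid(h, allele_matrix(H))
s
#> Li-Stephens haploid solution surface: L = 2 sites, N = 2 templates
#> 2 region(s) over beta in (0, Inf):
#>   beta in [1, Inf): r = 0, m = 1
#>   beta in [0, 1): r = 1, m = 0
reconstruct_path(s, 2)
#> [1] 2 1
```

Read: for any switch penalty above 1, the optimal decoding stays on one
template and accepts one mismatch (`r = 0, m = 1`); below 1 it pays one
switch (path `2 1`: copy template 2, then template 1) to match every
allele; the exchange happens exactly at the rational breakpoint `β = 1`.
`region_for_beta()` looks up the optimal vertex for any penalty,
`chain_breakpoints()` exposes the exact fractions, and
`surface_to_json()` serializes everything. Mapping a region back to
concrete `(θ, ρ)` pairs uses `penalty_ratio()` / `equivalence_curve()`.

A command-line driver for file-based use (plain matrices or phased VCF)
is installed at `inst/scripts/lssurface.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/lssurface.R", package="lssurface"))')" \
    haploid --panel panel.txt --focal focal.txt --out surface.json
```

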