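# Diploid solution surface over unordered pairs of copying paths.
#
# The state space is the set of unordered template pairs (n1 <= n2), since
# the genotype likelihood is symmetric in the two paths.  Per pair the
# frontier holds the locally active chain F^(n1,n2); per template the
# "partially active" chain P^(n) merges every pair chain involving n; the
# global chain G merges everything.  Extending one site with mismatch d for
# the pair, the candidates are (no switch) F^(n1,n2) at (r, m+d), (one
# switch, either coordinate) P^(n1) and P^(n2) at (r+1, m+d), and (double
# switch) G at (r+2, m+d).  Candidates whose provenance would not realize
# the claimed switch count are always dominated at equal m by a
# fewer-switch candidate, so they never survive the lower-left hull.

#' Per-site diploid mismatch between a genotype and a template pair
#'
#' Size of the set symmetric difference between the unordered genotype at
#' site `l` and the alleles carried by templates `n1`, `n2` there; one of
#' 0, 1, 2.  Symmetric in `(n1, n2)`.
#'
#' @param l site index.
#' @param n1,n2 template indices.
#' @param g genotype sequence (`L x 2`).
#' @param H template panel.
#' @return integer in `0:2`.
#' @export
diploid_site_mismatch <- function(l, n1, n2, g, H) {
  if (l < 1L || l > nrow(H)) stop("site index out of range")
  if (any(c(n1, n2) < 1L) || any(c(n1, n2) > ncol(H))) stop("template index out of range")
  as.integer(site_pair_mismatch(g[l, 1L], g[l, 2L], H[l, n1], H[l, n2]))
}

# integer encoding shared with the compiled cores (0/1 stays, acgt -> 1..4)
encode_alleles <- function(x) {
  if (is.numeric(x)) {
    matrix(as.integer(x), nrow(x), ncol(x))
  } else {
    matrix(match(x, c("a", "c", "g", "t")), nrow(x), ncol(x))
  }
}

#' All diploid decodings of an unphased genotype sequence
#'
#' Diploid analogue of [partition_haploid()]: the optimal cost structure is
#' `m(path1, path2) + beta * (k(path1) + k(path2))`, minimized over pairs
#' of copying paths, and the surface partitions `beta in (0, Inf)` into
#' regions of constant optimum.  One representative path pair is
#' reconstructed per region; pair order within the representative is
#' arbitrary (genotypes are unphased).  Work per site is quadratic in the
#' panel size (one update per unordered template pair).
#'
#' @param g genotype sequence (`L x 2` unordered allele pairs, see
#'   [as_genotype()]), or a 2-column matrix.
#' @param H template panel.
#' @return an `"ls_surface"` (see [partition_haploid()]) with
#'   `mode = "diploid"` and `paths` a list of `list(path1, path2)`.
#' @export
partition_diploid <- function(g, H) {
  L <- nrow(H); N <- ncol(H)
  if (is.null(L) || L < 1L) stop("panel must have at least one site")
  g <- as_genotype(unclass(g))
  if (nrow(g) != L) stop("genotype length must equal the panel's site count")
  core <- .ls_diploid_core(encode_alleles(g), encode_alleles(unclass(H)))
  chain <- vertex_chain(core$r, core$m)
  bps <- chain_breakpoints(chain)
  paths <- lapply(seq_along(core$r), function(i) {
    list(core$path1[i, ], core$path2[i, ])
  })
  build_surface(chain, bps, paths, mode = "diploid", L = L, N = N)
}

#' Haplotypes emitted by a diploid copying-path pair
#'
#' Each haplotype's allele at a site is the allele of the template it
#' copies from there.  At sites where the copied alleles do not reproduce
#' the genotype exactly (mismatch sites), the template alleles are emitted
#' as copied, not the genotype's.
#'
#' @param pair list of two equal-length copying paths (as returned in an
#'   `"ls_surface"` with `mode = "diploid"`).
#' @param H template panel.
#' @return list of two allele vectors.
#' @export
phase_from_pair <- function(pair, H) {
  idx <- seq_along(pair[[1L]])
  list(H[cbind(idx, pair[[1L]])], H[cbind(idx, pair[[2L]])])
}
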