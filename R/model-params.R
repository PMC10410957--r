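#' Number of template switches along a copying path
#'
#' Counts adjacent positions at which the path changes template, i.e. the
#' number of crossover recombinations implied by the path.
#'
#' @param path integer vector of template indices in `1..N`.
#' @return nonnegative integer; 0 for length-1 paths.
#' @export
switch_count <- function(path) {
  if (length(path) == 0L) stop("empty path")
  sum(path[-1L] != path[-length(path)])
}

#' Number of copying mismatches along a path
#'
#' Counts sites at which the focal haplotype disagrees with the template it
#' copies from under `path`.  The path may be a prefix (length <= L).
#'
#' @param path integer vector of template indices.
#' @param h focal haplotype.
#' @param H template panel.
#' @return nonnegative integer.
#' @export
mismatch_count <- function(path, h, H) {
  if (length(path) == 0L) stop("empty path")
  if (length(path) > nrow(H)) stop("path longer than the panel")
  if (any(path < 1L | path > ncol(H))) stop("path index outside 1..N")
  idx <- seq_along(path)
  sum(h[idx] != H[cbind(idx, path)])
}

# per-site unordered-genotype vs template-pair mismatch, set semantics:
# |{g1,g2} symdiff {a1,a2}| with sets (not multisets).  Vectorized over sites.
site_pair_mismatch <- function(g1, g2, a1, a2) {
  sizeA <- 1L + (g1 != g2)
  sizeB <- 1L + (a1 != a2)
  inter <- (a1 == g1 | a1 == g2) + ((a2 != a1) & (a2 == g1 | a2 == g2))
  sizeA + sizeB - 2L * inter
}

#' Diploid mismatch count between a path pair and a genotype sequence
#'
#' Site-wise size of the symmetric difference between the unordered genotype
#' `{g1, g2}` and the unordered copied alleles `{H[l, path1], H[l, path2]}`,
#' summed over sites, with *set* (not multiset) semantics: e.g. a homozygous
#' genotype `{0,0}` against templates carrying `{0,1}` contributes 1.
#' Symmetric in the two paths and in the within-site genotype order.  For
#' biallelic data this equals the absolute dosage difference at every site.
#'
#' @param path1,path2 equal-length integer paths.
#' @param g genotype sequence (`L x 2`, see [as_genotype()]).
#' @param H template panel.
#' @return nonnegative integer.
#' @export
diploid_mismatch_count <- function(path1, path2, g, H) {
  if (length(path1) != length(path2)) stop("paths must have equal length")
  if (length(path1) == 0L) stop("empty path")
  idx <- seq_along(path1)
  sum(site_pair_mismatch(g[idx, 1L], g[idx, 2L],
                         H[cbind(idx, path1)], H[cbind(idx, path2)]))
}

#' Per-site copying probabilities from population-scaled rates
#'
#' `p_theta_map()` maps a scaled mutation rate to the per-site copying-error
#' probability; the default `"coalescent"` map is
#' `p_theta = (1 - exp(-theta/N)) / 3` (time to first coalescence between the
#' focal and a template is roughly 1/N), and `"original"` is
#' `p_theta = theta / (2 (N + theta))` from the model's original
#' population-genetic derivation.  `p_rho_map()` maps a scaled recombination
#' rate to the per-transition switch probability
#' `p_rho = (1 - exp(-rho/N)) / N`.
#'
#' @param theta,rho positive scaled rates.
#' @param N panel size.
#' @param model which mutation-rate map to use.
#' @return probability.
#' @export
p_theta_map <- function(theta, N, model = c("coalescent", "original")) {
  model <- match.arg(model)
  if (any(theta <= 0)) stop("theta must be positive")
  switch(model,
    coalescent = (1 - exp(-theta / N)) / 3,
    original   = theta / (2 * (N + theta))
  )
}

#' @rdname p_theta_map
#' @export
p_rho_map <- function(rho, N) {
  if (any(rho <= 0)) stop("rho must be positive")
  (1 - exp(-rho / N)) / N
}

#' Mismatch and switch penalties
#'
#' The negative log-likelihood of a copying path is, up to a constant,
#' `alpha(theta) * m(path) + beta(rho) * k(path)` with
#' `alpha = -log(p_theta / (1 - 3 p_theta))` and
#' `beta = -log(p_rho / (1 - N p_rho))`.  Both are strictly decreasing in
#' their rate argument; the standing assumption `min(alpha, beta) > 0`
#' requires `p_theta < 1/4` and `p_rho < 1/(N+1)`, which is enforced.
#' `alpha_from_p()` / `beta_from_p()` take the per-site probabilities
#' directly; `ls_alpha()` / `ls_beta()` first map scaled rates through
#' [p_theta_map()] / [p_rho_map()].
#'
#' @param p_theta copying-error probability in (0, 1/4).
#' @param p_rho switch probability in (0, 1/(N+1)).
#' @param theta,rho positive scaled rates.
#' @param N panel size.
#' @param model mutation-rate map, see [p_theta_map()].
#' @return positive penalty.
#' @export
alpha_from_p <- function(p_theta) {
  if (any(p_theta <= 0)) stop("p_theta must be > 0")
  if (any(p_theta >= 1 / 4)) stop("p_theta must be < 1/4 (alpha > 0 required)")
  -log(p_theta / (1 - 3 * p_theta))
}

#' @rdname alpha_from_p
#' @export
beta_from_p <- function(p_rho, N) {
  if (any(p_rho <= 0)) stop("p_rho must be > 0")
  if (any(p_rho >= 1 / (N + 1))) stop("p_rho must be < 1/(N+1) (beta > 0 required)")
  -log(p_rho / (1 - N * p_rho))
}

#' @rdname alpha_from_p
#' @export
ls_alpha <- function(theta, N, model = c("coalescent", "original")) {
  alpha_from_p(p_theta_map(theta, N, model))
}

#' @rdname alpha_from_p
#' @export
ls_beta <- function(rho, N) {
  beta_from_p(p_rho_map(rho, N), N)
}

#' Penalty ratio c = beta(rho) / alpha(theta)
#'
#' The model's output depends on `(theta, rho)` only through this ratio:
#' rescaling the cost by `alpha` leaves the path ranking unchanged, so every
#' parameter pair on the one-dimensional curve of constant `c` yields the
#' same set of optimal decodings.
#'
#' @inheritParams alpha_from_p
#' @return positive ratio.
#' @export
penalty_ratio <- function(theta, rho, N, model = c("coalescent", "original")) {
  ls_beta(rho, N) / ls_alpha(theta, N, model)
}

#' Curve of equivalent (p_theta, p_rho) pairs for a given penalty ratio
#'
#' For fixed `c = beta / alpha`, every pair with
#' `p_rho = 1 / (N + (p_theta / (1 - 3 p_theta))^(-c))` produces identical
#' model output.
#'
#' @param c positive penalty ratio.
#' @param p_theta_grid probabilities in (0, 1/4).
#' @param N panel size.
#' @return data.frame with columns `p_theta`, `p_rho`.
#' @export
equivalence_curve <- function(c, p_theta_grid, N) {
  if (c <= 0) stop("c must be positive")
  if (any(p_theta_grid <= 0 | p_theta_grid >= 1 / 4)) {
    stop("p_theta grid values must lie in (0, 1/4)")
  }
  p_rho <- 1 / (N + (p_theta_grid / (1 - 3 * p_theta_grid))^(-c))
  data.frame(p_theta = p_theta_grid, p_rho = p_rho)
}

#' Normalized path cost m + c k
#'
#' The cost of a decoding once the mismatch penalty is rescaled to 1:
#' `m(path) + c * k(path)` for a haploid path, and
#' `m(path1, path2) + c * (k(path1) + k(path2))` for a diploid pair.  The
#' additive likelihood constant is dropped.
#'
#' @param path integer path (haploid).
#' @param h focal haplotype.
#' @param H template panel.
#' @param c positive penalty ratio.
#' @return nonnegative cost.
#' @export
path_cost <- function(path, h, H, c) {
  if (c <= 0) stop("c must be positive")
  mismatch_count(path, h, H) + c * switch_count(path)
}

#' @rdname path_cost
#' @param path1,path2 integer path pair (diploid).
#' @param g genotype sequence.
#' @export
path_cost_diploid <- function(path1, path2, g, H, c) {
  if (c <= 0) stop("c must be positive")
  diploid_mismatch_count(path1, path2, g, H) +
    c * (switch_count(path1) + switch_count(path2))
}
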