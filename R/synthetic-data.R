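# Self-contained data generators: a sequential mosaic (PAC-style) panel
# simulator, a generative focal sampler from the copying model itself,
# minor-allele-frequency masking, and the analytic neutral-spectrum
# retention fraction.  An optional hook to msprime (driven through the
# bundled Python script) provides coalescent panels for the full
# experiment pipelines.

#' Simulate a template panel with coalescent-like allele-frequency structure
#'
#' The `"mosaic"` model builds haplotypes sequentially: the first is an
#' all-ancestral background, and haplotype `k + 1` copies from the first
#' `k` under the copying model itself (template switch with total
#' probability `k * p_rho`, capped below 1; per-site copying error
#' `p_theta`, which on the biallelic alphabet flips the allele).  Copying
#' errors seed new variants whose frequencies then grow by descent, giving
#' a decreasing site-frequency spectrum and realistic linkage structure.
#' Only segregating sites are returned; generation continues in batches
#' until `L` segregating sites are available.  The `"iid"` model draws
#' sites independently with a frequency drawn from the neutral spectrum
#' (no linkage); it exists for controlled tests.
#'
#' @param N number of template haplotypes.
#' @param L number of segregating sites.
#' @param p_theta per-site copying-error probability.
#' @param p_rho per-transition switch probability (see [beta_from_p()] for
#'   the implied penalty).
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   its arguments).
#' @param model `"mosaic"` or `"iid"`.
#' @return an [allele_matrix()] of 0/1 alleles, `L x N`, every row
#'   segregating.
#' @export
generate_panel <- function(N, L, p_theta, p_rho, seed, model = c("mosaic", "iid")) {
  model <- match.arg(model)
  if (p_theta <= 0 || p_theta >= 1 / 4) stop("p_theta must lie in (0, 1/4)")
  if (p_rho <= 0 || p_rho >= 1 / (N + 1)) stop("p_rho must lie in (0, 1/(N+1))")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  if (model == "iid") {
    freqs <- neutral_sfs_frequencies(L, N)
    H <- vapply(freqs, function(f) {
      x <- stats::rbinom(N, 1L, f)
      while (all(x == x[1L])) x <- stats::rbinom(N, 1L, f)
      x
    }, integer(N))
    return(allele_matrix(t(H)))
  }
  batch <- max(L, 64L)
  rows_keep <- NULL
  H <- NULL
  while (is.null(rows_keep) || length(rows_keep) < L) {
    Hb <- matrix(0L, batch, N)
    for (k in 2:N) {
      sw_prob <- min((k - 1L) * p_rho, 0.95)
      tpl <- integer(batch)
      tpl[1L] <- sample.int(k - 1L, 1L)
      sw <- stats::runif(batch) < sw_prob
      for (j in 2:batch) tpl[j] <- if (sw[j]) sample.int(k - 1L, 1L) else tpl[j - 1L]
      copied <- Hb[cbind(seq_len(batch), tpl)]
      err <- stats::runif(batch) < p_theta
      Hb[, k] <- ifelse(err, 1L - copied, copied)
    }
    H <- rbind(H, Hb)
    seg <- rowSums(H) > 0L & rowSums(H) < N
    rows_keep <- which(seg)
    batch <- max(64L, L - length(rows_keep))
  }
  allele_matrix(H[rows_keep[seq_len(L)], , drop = FALSE])
}

# frequencies drawn from the neutral spectrum P(count = i) proportional to
# 1/i, i = 1..n-1
neutral_sfs_frequencies <- function(L, n) {
  i <- seq_len(n - 1L)
  counts <- sample(i, L, replace = TRUE, prob = 1 / i)
  counts / n
}

#' Sample a focal haplotype from the copying model
#'
#' Draws the latent copying path as the model's stationary Markov chain
#' (switch event with total probability `N * p_rho`, new template uniform
#' over all `N` including the current one), then copies the panel alleles
#' with per-site error `p_theta`.  On the biallelic alphabet an error
#' flips the allele; on the nucleotide alphabet an error occurs with
#' probability `3 * p_theta` and substitutes uniformly among the three
#' other nucleotides.
#'
#' @param H template panel.
#' @param p_theta per-site copying-error probability in (0, 1/4).
#' @param p_rho per-transition switch probability in (0, 1/(N+1)).
#' @param seed integer seed.
#' @return list with `haplotype` and the latent `path`.
#' @export
sample_focal <- function(H, p_theta, p_rho, seed) {
  N <- ncol(H); L <- nrow(H)
  if (p_theta <= 0 || p_theta >= 1 / 4) stop("p_theta must lie in (0, 1/4)")
  if (p_rho <= 0 || p_rho >= 1 / (N + 1)) stop("p_rho must lie in (0, 1/(N+1))")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  path <- integer(L)
  path[1L] <- sample.int(N, 1L)
  if (L >= 2L) {
    sw <- stats::runif(L) < N * p_rho
    for (l in 2:L) path[l] <- if (sw[l]) sample.int(N, 1L) else path[l - 1L]
  }
  hap <- H[cbind(seq_len(L), path)]
  if (is.numeric(hap)) {
    err <- stats::runif(L) < p_theta
    hap[err] <- 1L - hap[err]
  } else {
    err <- stats::runif(L) < 3 * p_theta
    if (any(err)) {
      hap[err] <- vapply(hap[err], function(x) sample(setdiff(c("a", "c", "g", "t"), x), 1L), "")
    }
  }
  list(haplotype = hap, path = path)
}

#' Mask sites by minor allele frequency
#'
#' The minor allele frequency is computed over all chromosomes *including*
#' the focal one(s); sites with MAF below the threshold are masked and
#' later imputed, the rest are retained.
#'
#' @param H template panel (biallelic).
#' @param focal optional focal haplotype (vector) or haplotypes (matrix
#'   columns) included in the frequency computation.
#' @param threshold MAF threshold; sites with `MAF >= threshold` are
#'   retained.
#' @return list with strictly increasing integer vectors `retained`,
#'   `masked`, and the per-site `maf`.
#' @export
mask_by_maf <- function(H, focal = NULL, threshold = 0.05) {
  if (!is.numeric(H[1L, 1L])) stop("MAF masking requires biallelic 0/1 data")
  X <- cbind(unclass(H), focal)
  f <- rowMeans(X)
  maf <- pmin(f, 1 - f)
  retained <- which(maf >= threshold)
  list(retained = retained, masked = which(maf < threshold), maf = maf)
}

#' Expected fraction of sites retained by a MAF filter under the neutral
#' site-frequency spectrum
#'
#' For a sample of `n` chromosomes, a segregating site has derived-allele
#' count `i` with probability proportional to `1/i`; the site is retained
#' when `min(i, n - i) / n >= threshold`.  The returned fraction is the
#' ratio of harmonic sums over retained counts to the full harmonic sum.
#'
#' @param n sample size (chromosomes), `>= 2`.
#' @param threshold MAF threshold in (0, 0.5].
#' @return retention fraction in (0, 1].
#' @export
expected_maf_retention <- function(n, threshold = 0.05) {
  if (n < 2L) stop("need at least two chromosomes")
  if (threshold <= 0 || threshold > 0.5) stop("threshold must lie in (0, 0.5]")
  i <- seq_len(n - 1L)
  keep <- pmin(i, n - i) / n >= threshold
  sum(1 / i[keep]) / sum(1 / i)
}

#' Simulate a coalescent haplotype panel through msprime
#'
#' Optional hook to the msprime coalescent simulator (run through the
#' Python interpreter on the PATH) for full-pipeline experiments with
#' genuinely coalescent panels.  Supports a constant-size population and a
#' built-in African single-population growth demography (ancestral size
#' 7310 until 5920 generations ago, then 14474, with exponential growth
#' at 1.66% per generation starting about 205 generations ago — the
#' African component of a standard human out-of-Africa model).  Mutations
#' use a binary 0/1 model; only biallelic segregating sites are returned.
#'
#' @param n number of haploid samples.
#' @param length_bp sequence length in base pairs.
#' @param mu per-bp per-generation mutation rate.
#' @param recomb per-bp per-generation recombination rate.
#' @param Ne effective population size (constant demography).
#' @param demography `"constant"` or `"african_growth"`.
#' @param seed integer seed passed to msprime.
#' @param python python interpreter to invoke.
#' @return list with `H` (sites x samples 0/1 matrix), `positions` (bp),
#'   `E_T2` (mean pairwise coalescence time in generations, for deriving
#'   population-scaled rates), `theta_bp`, `rho_bp` (scaled rates per bp,
#'   `2 * E_T2 * rate`).
#' @export
simulate_panel_msprime <- function(n, length_bp, mu, recomb, Ne = 1,
                                   demography = c("constant", "african_growth"),
                                   seed, python = "python") {
  demography <- match.arg(demography)
  if (missing(seed)) stop("seed is required")
  script <- system.file("python", "panel_sim.py", package = "lssurface")
  if (script == "") stop("bundled msprime driver not found")
  out <- tempfile(fileext = ".txt")
  on.exit(unlink(out), add = TRUE)
  status <- system2(python,
    c(script, "--n", n, "--length", sprintf("%.10g", length_bp),
      "--mu", sprintf("%.10g", mu), "--rho", sprintf("%.10g", recomb),
      "--ne", sprintf("%.10g", Ne), "--demography", demography,
      "--seed", seed, "--out", out),
    stdout = "", stderr = "")
  if (status != 0L) stop("msprime driver failed (is msprime installed for 'python'?)")
  lines <- readLines(out)
  meta <- jsonlite::fromJSON(sub("^#meta ", "", lines[1L]))
  pos <- as.numeric(strsplit(lines[2L], " ", fixed = TRUE)[[1L]])
  H <- do.call(rbind, lapply(lines[-(1:2)], function(s) {
    as.integer(strsplit(s, " ", fixed = TRUE)[[1L]])
  }))
  if (is.null(H)) stop("msprime simulation produced no segregating sites")
  list(H = H, positions = pos, E_T2 = meta$E_T2,
       theta_bp = 2 * meta$E_T2 * mu, rho_bp = 2 * meta$E_T2 * recomb)
}
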