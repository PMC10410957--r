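# Downstream evaluation pipelines: imputation-error-versus-penalty and
# phasing-switch-error-versus-penalty, run over the full solution surface.

#' Impute masked sites from a copying path on the retained sites
#'
#' Each masked site is imputed by pasting the copying-path state from the
#' nearest retained (flanking) marker by site-index distance — ties go to
#' the left flank, and masked sites before the first retained site use the
#' first — and emitting that template's allele at the masked site.
#'
#' @param path copying path defined on the retained sites, in retained
#'   order.
#' @param retained,masked strictly increasing site-index vectors
#'   partitioning the full site set.
#' @param H_full full template panel (all sites).
#' @return allele vector, one entry per masked site.
#' @export
impute_from_path <- function(path, retained, masked, H_full) {
  if (length(retained) == 0L) stop("retained set must be nonempty")
  if (length(path) != length(retained)) stop("path must cover the retained sites")
  nearest <- nearest_flank(retained, masked)
  H_full[cbind(masked, path[nearest])]
}

# index (into `retained`) of the nearest retained site for each masked
# site; ties to the left
nearest_flank <- function(retained, masked) {
  left <- findInterval(masked, retained)            # 0 if before first
  right <- pmin(left + 1L, length(retained))
  leftc <- pmax(left, 1L)
  dl <- abs(masked - retained[leftc])
  dr <- abs(retained[right] - masked)
  ifelse(left == 0L, 1L, ifelse(dl <= dr, leftc, right))
}

#' Weighted imputation loss
#'
#' `sum_l w_l |true_l - imputed_l|`.  Unit weights give the Hamming loss;
#' weights `1 / (MAF_l (1 - MAF_l))` give the inverse-variance-weighted
#' loss that upweights rare variants.
#'
#' @param truth,imputed equal-length 0/1 allele vectors (masked sites).
#' @param weights positive site weights (default all 1).
#' @return nonnegative loss.
#' @export
imputation_loss <- function(truth, imputed, weights = rep(1, length(truth))) {
  if (length(truth) != length(imputed)) stop("truth and imputed lengths differ")
  if (any(weights <= 0) || any(!is.finite(weights))) {
    stop("weights must be positive and finite (is a masked site non-segregating?)")
  }
  sum(weights * abs(truth - imputed))
}

#' Inverse-variance weights from minor allele frequencies
#' @param maf per-site minor allele frequencies in (0, 0.5].
#' @return weights `1 / (maf (1 - maf))`.
#' @export
maf_weights <- function(maf) {
  if (any(maf <= 0)) stop("cannot weight a non-segregating site (MAF = 0)")
  1 / (maf * (1 - maf))
}

#' Per-region loss curve over a solution surface
#'
#' Evaluates one loss value per surface region using that region's
#' representative decoding: for imputation losses the representative path
#' imputes the masked sites; for switch error the representative pair is
#' phased and compared to the true haplotype pair.  The curve is piecewise
#' constant in the penalty by construction.
#'
#' @param surface an `"ls_surface"`.
#' @param loss_kind `"hamming"`, `"maf_weighted"`, or `"switch_error"`.
#' @param truth for imputation losses: true alleles at the masked sites;
#'   for switch error: list of the two true haplotypes (all sites).
#' @param H_full full panel (imputation) or panel on the surface's sites
#'   (switch error).
#' @param retained,masked site partitions (imputation losses only).
#' @param maf full-sample minor allele frequencies at the masked sites
#'   (`"maf_weighted"` only).
#' @return object of class `"ls_loss_curve"`: the surface's region table
#'   with a `loss` column.
#' @export
loss_curve <- function(surface, loss_kind = c("hamming", "maf_weighted", "switch_error"),
                       truth, H_full, retained = NULL, masked = NULL, maf = NULL) {
  loss_kind <- match.arg(loss_kind)
  M <- nrow(surface$regions)
  loss <- numeric(M)
  if (loss_kind %in% c("hamming", "maf_weighted")) {
    if (surface$mode != "haploid") stop("imputation losses expect a haploid surface")
    w <- if (loss_kind == "hamming") rep(1, length(masked)) else maf_weights(maf)
    for (i in seq_len(M)) {
      imp <- impute_from_path(surface$paths[[i]], retained, masked, H_full)
      loss[i] <- imputation_loss(truth, imp, w)
    }
  } else {
    if (surface$mode != "diploid") stop("switch error expects a diploid surface")
    for (i in seq_len(M)) {
      est <- phase_from_pair(surface$paths[[i]], H_full)
      loss[i] <- switch_error(truth, est)$count
    }
  }
  out <- cbind(surface$regions, loss = loss)
  class(out) <- c("ls_loss_curve", class(out))
  attr(out, "loss_kind") <- loss_kind
  out
}

#' @export
plot.ls_loss_curve <- function(x, xmax = NULL, ...) {
  up <- ifelse(is.finite(x$beta_upper), x$beta_upper,
               if (is.null(xmax)) 2 * max(1, x$beta_lower[1L]) else xmax)
  graphics::plot(NA, xlim = log1p(c(0, max(up))), ylim = range(x$loss),
                 xlab = "log(1 + beta)", ylab = attr(x, "loss_kind"), ...)
  graphics::segments(log1p(x$beta_lower), x$loss, log1p(up), x$loss)
  invisible(x)
}

#' Interval of penalties minimizing a loss curve
#'
#' Returns the maximal union of contiguous minimal-loss regions.  If the
#' minimum is attained on non-contiguous runs, all maximal runs are
#' reported and the result is flagged multimodal; the primary interval is
#' the run with the smallest lower penalty bound.  `contains_reference`
#' says whether the reference penalty ratio falls inside the primary
#' interval.
#'
#' @param curve an `"ls_loss_curve"`.
#' @param reference_c optional reference penalty (e.g. the ratio implied by
#'   the population-scaled rates).
#' @return list with `loss` (the minimum), `primary` (c(lower, upper)),
#'   `runs` (matrix of all minimal runs), `multimodal`,
#'   `contains_reference` (NA when no reference is given).
#' @export
optimal_interval <- function(curve, reference_c = NULL) {
  stopifnot(nrow(curve) >= 1L)
  lmin <- min(curve$loss)
  is_min <- curve$loss == lmin
  # regions are ordered by decreasing beta (region 1 unbounded above)
  runs <- split(which(is_min), cumsum(!is_min)[is_min])
  ivals <- t(vapply(runs, function(idx) {
    c(lower = min(curve$beta_lower[idx]), upper = max(curve$beta_upper[idx]))
  }, numeric(2)))
  ord <- order(ivals[, 1L])
  ivals <- ivals[ord, , drop = FALSE]
  primary <- ivals[1L, ]
  contains <- if (is.null(reference_c)) NA else {
    reference_c >= primary[1L] && reference_c < primary[2L]
  }
  list(loss = lmin, primary = primary, runs = ivals,
       multimodal = nrow(ivals) > 1L, contains_reference = contains)
}

#' Switch error between a true and an estimated haplotype pair
#'
#' Follows the usual phasing-evaluation convention (as in vcftools'
#' `--diff-switch-error`): only sites that are heterozygous in *both* the
#' truth and the estimate with the same allele pair are compared; at each
#' such site the orientation records whether estimated haplotype 1 carries
#' true haplotype 1's allele; the switch count is the number of
#' consecutive comparable sites at which the orientation flips.  Globally
#' swapping either pair leaves the count unchanged.
#'
#' @param truth,estimate lists of two equal-length biallelic haplotypes.
#' @return list with `count`, `rate` (`count / (comparable - 1)`, 0 when
#'   there are fewer than 2 comparable sites), `comparable` (number of
#'   comparable heterozygous sites), and `defined` (FALSE when no site is
#'   comparable).
#' @export
switch_error <- function(truth, estimate) {
  t1 <- truth[[1L]]; t2 <- truth[[2L]]
  e1 <- estimate[[1L]]; e2 <- estimate[[2L]]
  if (length(t1) != length(e1)) stop("truth and estimate lengths differ")
  het_t <- t1 != t2
  het_e <- e1 != e2
  same_alleles <- (pmin(t1, t2) == pmin(e1, e2)) & (pmax(t1, t2) == pmax(e1, e2))
  comp <- which(het_t & het_e & same_alleles)
  if (length(comp) == 0L) {
    return(list(count = 0L, rate = 0, comparable = 0L, defined = FALSE))
  }
  orient <- e1[comp] == t1[comp]
  count <- sum(orient[-1L] != orient[-length(orient)])
  rate <- if (length(comp) >= 2L) count / (length(comp) - 1L) else 0
  list(count = as.integer(count), rate = rate,
       comparable = length(comp), defined = TRUE)
}

# simulate one study replicate's data under either engine
simulate_replicate <- function(config, seed, n_focal = 1L) {
  engine <- config$engine %||% "mosaic"
  if (engine == "mosaic") {
    H <- unclass(generate_panel(config$N, config$L, config$p_theta,
                                config$p_rho, seed = seed))
    focal <- vapply(seq_len(n_focal), function(j) {
      sample_focal(H, config$p_theta, config$p_rho, seed = seed + 7919L * j)$haplotype
    }, integer(nrow(H)))
    ref_c <- beta_from_p(config$p_rho, config$N) / alpha_from_p(config$p_theta)
    list(H = H, focal = focal, positions = NULL, reference_c = ref_c,
         theta_bp = NULL, rho_bp = NULL)
  } else if (engine == "msprime") {
    sim <- simulate_panel_msprime(config$n_samples, config$length_bp,
                                  config$mu, config$recomb,
                                  Ne = config$Ne %||% 1,
                                  demography = config$demography %||% "constant",
                                  seed = seed)
    focal <- sim$H[, seq_len(n_focal), drop = FALSE]
    H <- sim$H[, -seq_len(n_focal), drop = FALSE]
    list(H = H, focal = focal, positions = sim$positions, reference_c = NULL,
         theta_bp = sim$theta_bp, rho_bp = sim$rho_bp)
  } else stop("unknown engine: ", engine)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reference penalty ratio for coalescent data: population-scaled per-marker
# rates are the per-bp scaled rates times the mean retained-marker spacing
reference_c_coalescent <- function(theta_bp, rho_bp, span_bp, n_markers, N) {
  spacing <- span_bp / n_markers
  ls_beta(rho_bp * spacing, N) / ls_alpha(theta_bp * spacing, N)
}

#' Run the haploid imputation study over replicates
#'
#' Per replicate: simulate a panel and focal haplotype, mask low-MAF sites
#' (frequency computed over all chromosomes including the focal), compute
#' the solution surface on the retained sites, impute the masked sites per
#' region, and record — for both the Hamming and MAF-weighted losses — the
#' minimal-loss penalty interval and whether the reference penalty (from
#' the generative/population-scaled rates) falls inside it.
#'
#' @param config list; common fields: `engine` (`"mosaic"` default, or
#'   `"msprime"`), `maf_threshold` (default 0.05), `seed_base` (replicate
#'   `i` uses `seed_base + i`).  Mosaic fields: `N`, `L`, `p_theta`,
#'   `p_rho`.  msprime fields: `n_samples`, `length_bp`, `mu`, `recomb`,
#'   `Ne`, `demography`.
#' @param R number of replicates.
#' @return data.frame, one row per replicate, with optimal-interval bounds
#'   and `optimal_contains_ref` flags for each loss; failed replicates are
#'   recorded with `ok = FALSE`.
#' @export
run_imputation_replicates <- function(config, R) {
  rows <- vector("list", R)
  for (i in seq_len(R)) {
    rows[[i]] <- tryCatch(
      one_imputation_replicate(config, seed = (config$seed_base %||% 0L) + i),
      error = function(e) data.frame(replicate = i, ok = FALSE,
                                     error = conditionMessage(e))
    )
    rows[[i]]$replicate <- i
  }
  out <- do.call(rbind, lapply(rows, pad_row,
                               fields = c("replicate", "ok", "n_retained", "n_masked",
                                          "n_regions", "reference_c",
                                          "ham_lower", "ham_upper", "ham_optimal_loss",
                                          "ham_contains_ref", "ham_ref_optimal",
                                          "wt_lower", "wt_upper", "wt_optimal_loss",
                                          "wt_contains_ref", "wt_ref_optimal",
                                          "error")))
  rownames(out) <- NULL
  out
}

one_imputation_replicate <- function(config, seed) {
  sim <- simulate_replicate(config, seed, n_focal = 1L)
  h <- sim$focal[, 1L]
  H <- sim$H
  msk <- mask_by_maf(H, focal = h, threshold = config$maf_threshold %||% 0.05)
  if (length(msk$retained) < 2L || length(msk$masked) < 1L) {
    stop("degenerate masking: too few retained or masked sites")
  }
  ref_c <- sim$reference_c
  if (is.null(ref_c)) {
    span <- max(sim$positions) - min(sim$positions)
    ref_c <- reference_c_coalescent(sim$theta_bp, sim$rho_bp, span,
                                    length(msk$retained), ncol(H))
  }
  surf <- partition_haploid(h[msk$retained], allele_matrix(H[msk$retained, , drop = FALSE]))
  truth <- h[msk$masked]
  ham <- loss_curve(surf, "hamming", truth = truth, H_full = H,
                    retained = msk$retained, masked = msk$masked)
  wt <- loss_curve(surf, "maf_weighted", truth = truth, H_full = H,
                   retained = msk$retained, masked = msk$masked,
                   maf = msk$maf[msk$masked])
  oh <- optimal_interval(ham, ref_c)
  ow <- optimal_interval(wt, ref_c)
  # the study's headline quantity: does the reference-penalty region attain
  # the minimal loss (robust to the minimum being tied across
  # non-contiguous regions)
  iref <- region_for_beta(surf$vertices, surf$breakpoints, ref_c)
  data.frame(ok = TRUE, n_retained = length(msk$retained),
             n_masked = length(msk$masked), n_regions = nrow(surf$regions),
             reference_c = ref_c,
             ham_lower = oh$primary[1L], ham_upper = oh$primary[2L],
             ham_optimal_loss = oh$loss, ham_contains_ref = oh$contains_reference,
             ham_ref_optimal = ham$loss[iref] == oh$loss,
             wt_lower = ow$primary[1L], wt_upper = ow$primary[2L],
             wt_optimal_loss = ow$loss, wt_contains_ref = ow$contains_reference,
             wt_ref_optimal = wt$loss[iref] == ow$loss)
}

#' Run the diploid phasing study over replicates
#'
#' Per replicate: simulate a panel and two focal haplotypes, combine them
#' into an unphased genotype sequence, compute the diploid solution
#' surface, phase each region's representative pair, and record the
#' switch-error curve's minimal interval and whether the reference penalty
#' falls inside it.
#'
#' @inheritParams run_imputation_replicates
#' @return data.frame, one row per replicate.
#' @export
run_phasing_replicates <- function(config, R) {
  rows <- vector("list", R)
  for (i in seq_len(R)) {
    rows[[i]] <- tryCatch(
      one_phasing_replicate(config, seed = (config$seed_base %||% 0L) + i),
      error = function(e) data.frame(replicate = i, ok = FALSE,
                                     error = conditionMessage(e))
    )
    rows[[i]]$replicate <- i
  }
  out <- do.call(rbind, lapply(rows, pad_row,
                               fields = c("replicate", "ok", "n_sites", "n_regions",
                                          "reference_c", "opt_lower", "opt_upper",
                                          "optimal_switch_count", "contains_ref",
                                          "switch_rate_at_ref", "error")))
  rownames(out) <- NULL
  out
}

one_phasing_replicate <- function(config, seed) {
  sim <- simulate_replicate(config, seed, n_focal = 2L)
  h1 <- sim$focal[, 1L]; h2 <- sim$focal[, 2L]
  H <- sim$H
  ref_c <- sim$reference_c
  if (is.null(ref_c)) {
    span <- max(sim$positions) - min(sim$positions)
    ref_c <- reference_c_coalescent(sim$theta_bp, sim$rho_bp, span, nrow(H), ncol(H))
  }
  g <- genotype_from_pair(h1, h2)
  surf <- partition_diploid(g, allele_matrix(H))
  curve <- loss_curve(surf, "switch_error", truth = list(h1, h2), H_full = H)
  opt <- optimal_interval(curve, ref_c)
  iref <- region_for_beta(surf$vertices, surf$breakpoints, ref_c)
  se_ref <- switch_error(list(h1, h2), phase_from_pair(surf$paths[[iref]], H))
  data.frame(ok = TRUE, n_sites = nrow(H), n_regions = nrow(surf$regions),
             reference_c = ref_c, opt_lower = opt$primary[1L],
             opt_upper = opt$primary[2L], optimal_switch_count = opt$loss,
             contains_ref = opt$contains_reference,
             switch_rate_at_ref = se_ref$rate)
}

# align replicate rows (including failures) on a common column set
pad_row <- function(row, fields) {
  for (f in setdiff(fields, names(row))) row[[f]] <- NA
  row[fields]
}
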