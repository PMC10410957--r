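test_that("nearest-flanking-marker imputation applies the documented tie rules", {
  # full site set 1..7; retained 2, 6; masked sites take the nearer flank
  H_full <- cbind(c(0, 0, 0, 0, 0, 0, 0), c(1, 1, 1, 1, 1, 1, 1))
  path <- c(1L, 2L)                      # copy template 1 at site 2, template 2 at site 6
  imp <- impute_from_path(path, retained = c(2L, 6L), masked = c(1L, 3L, 4L, 5L, 7L),
                          H_full = H_full)
  # site 1: before first retained -> first; site 4: equidistant -> left flank
  expect_identical(imp, c(0, 0, 0, 1, 1))
  expect_error(impute_from_path(integer(0), integer(0), 1L, H_full), "nonempty")

  # zero-error regime: imputation recovers the truth at every masked site
  set.seed(111)
  H <- generate_panel(10, 200, 0.03, 0.01, seed = 12)
  truth_col <- 4L
  h <- H[, truth_col]
  msk <- mask_by_maf(H, focal = h, threshold = 0.1)
  s <- partition_haploid(h[msk$retained], allele_matrix(unclass(H)[msk$retained, ]))
  expect_identical(s$vertices$m[1], 0L)
  imp <- impute_from_path(s$paths[[1]], msk$retained, msk$masked, H)
  expect_identical(imp, h[msk$masked])
})

test_that("imputation losses weight errors as documented", {
  expect_identical(imputation_loss(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_identical(imputation_loss(c(0, 1), c(1, 1), weights = maf_weights(c(0.5, 0.1))), 4)
  set.seed(112)
  truth <- sample(0:1, 40, TRUE); imp <- sample(0:1, 40, TRUE)
  expect_equal(imputation_loss(truth, imp), sum(truth != imp))
  expect_error(maf_weights(c(0.1, 0)), "non-segregating")
  expect_error(imputation_loss(1, c(1, 0)), "differ")
})

test_that("loss curves are piecewise constant over regions with the expected extremes", {
  set.seed(113)
  H <- generate_panel(12, 400, 0.03, 0.01, seed = 13)
  f <- sample_focal(H, 0.03, 0.01, seed = 14)
  h <- f$haplotype
  msk <- mask_by_maf(H, focal = h, threshold = 0.05)
  Hr <- allele_matrix(unclass(H)[msk$retained, ])
  s <- partition_haploid(h[msk$retained], Hr)
  curve <- loss_curve(s, "hamming", truth = h[msk$masked], H_full = H,
                      retained = msk$retained, masked = msk$masked)
  expect_identical(nrow(curve), nrow(s$regions))
  expect_true(all(curve$loss >= 0))
  # extremes reproduce directly constructed paths
  M <- nrow(curve)
  D <- matrix(as.integer(h[msk$retained] != Hr), nrow(Hr), ncol(Hr))
  best_col <- which.min(colSums(D))
  left_imp <- impute_from_path(rep(best_col, nrow(Hr)), msk$retained, msk$masked, H)
  expect_identical(curve$loss[1], imputation_loss(h[msk$masked], left_imp))
  # weighted curve shares the region table
  wcurve <- loss_curve(s, "maf_weighted", truth = h[msk$masked], H_full = H,
                       retained = msk$retained, masked = msk$masked,
                       maf = msk$maf[msk$masked])
  expect_identical(wcurve$vertex, curve$vertex)
})

test_that("optimal intervals report maximal minimal-loss runs and reference containment", {
  mk_curve <- function(losses) {
    M <- length(losses)
    bps <- seq(M - 1, 1)                  # breakpoints M-1, ..., 1
    data.frame(vertex = seq_len(M), loss = losses,
               beta_lower = c(bps, 0), beta_upper = c(Inf, bps))
  }
  cv <- mk_curve(c(3, 1, 1, 2))
  oi <- optimal_interval(cv, reference_c = 1.5)
  expect_identical(oi$loss, 1)
  expect_identical(unname(oi$primary), c(1, 3))
  expect_false(oi$multimodal)
  expect_true(oi$contains_reference)
  # constant curve: single region covering everything
  oc <- optimal_interval(mk_curve(c(2, 2, 2)), reference_c = 100)
  expect_identical(unname(oc$primary), c(0, Inf))
  expect_true(oc$contains_reference)
  # non-contiguous minima: all runs reported, primary has the smallest lower bound
  om <- optimal_interval(mk_curve(c(1, 5, 1, 2)), reference_c = 3.5)
  expect_true(om$multimodal)
  expect_identical(nrow(om$runs), 2L)
  expect_identical(unname(om$primary), c(1, 2))
  expect_false(om$contains_reference)   # reference is in the non-primary run
})

test_that("switch error follows the vcftools-style convention", {
  truth <- list(c(0, 0, 0), c(1, 1, 1))
  est_same <- list(c(1, 1, 1), c(0, 0, 0))       # global swap is not a switch
  expect_identical(switch_error(truth, est_same)$count, 0L)
  est_flip <- list(c(0, 1, 0), c(1, 0, 1))       # orientation +, -, +
  se <- switch_error(truth, est_flip)
  expect_identical(se$count, 2L)
  expect_identical(se$rate, 1)
  # single comparable het site: count 0
  t1 <- list(c(0, 0), c(1, 0))
  expect_identical(switch_error(t1, t1)$count, 0L)
  # discordant-allele and non-het sites are excluded from comparison
  truth2 <- list(c(0, 0, 0, 1), c(1, 0, 1, 0))
  est2 <- list(c(0, 1, 1, 1), c(1, 1, 0, 0))     # site 2 not het in truth
  se2 <- switch_error(truth2, est2)
  expect_identical(se2$comparable, 3L)
  # no comparable sites: undefined, rate 0
  se3 <- switch_error(list(c(0, 0), c(0, 0)), list(c(0, 1), c(1, 0)))
  expect_false(se3$defined)
  expect_identical(se3$rate, 0)
  # invariance under global swaps of either pair
  set.seed(114)
  for (rep in 1:10) {
    tp <- list(sample(0:1, 20, TRUE), sample(0:1, 20, TRUE))
    ep <- list(sample(0:1, 20, TRUE), sample(0:1, 20, TRUE))
    base <- switch_error(tp, ep)$count
    expect_identical(switch_error(tp[2:1], ep)$count, base)
    expect_identical(switch_error(tp, ep[2:1])$count, base)
  }
})

test_that("replicate studies run end to end on mosaic data", {
  cfg <- list(engine = "mosaic", N = 25, L = 250, p_theta = 0.02, p_rho = 0.004,
              maf_threshold = 0.05, seed_base = 40)
  res <- run_imputation_replicates(cfg, R = 3)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$ok))
  expect_true(all(res$ham_lower <= res$ham_upper))
  expect_true(all(res$n_retained + res$n_masked == 250))
  # deterministic given the seed policy
  res2 <- run_imputation_replicates(cfg, R = 3)
  expect_identical(res, res2)

  cfgp <- list(engine = "mosaic", N = 12, L = 120, p_theta = 0.02, p_rho = 0.004,
               seed_base = 50)
  resp <- run_phasing_replicates(cfgp, R = 2)
  expect_true(all(resp$ok))
  expect_true(all(resp$optimal_switch_count >= 0))
  expect_true(all(resp$contains_ref %in% c(TRUE, FALSE)))
  expect_true(all(resp$n_regions >= 1))
})
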