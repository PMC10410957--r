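test_that("switch and mismatch counters follow their definitions", {
  expect_identical(switch_count(c(3, 3, 3, 3)), 0L)
  expect_identical(switch_count(c(1, 2, 1)), 2L)
  expect_identical(switch_count(c(1, 1, 2, 2, 3)), 2L)
  expect_identical(switch_count(5L), 0L)
  expect_error(switch_count(integer(0)), "empty path")

  H <- matrix(c(0, 0, 1, 0, 1, 1), nrow = 3)
  expect_identical(mismatch_count(c(1, 1, 1), H[, 1], H), 0L)
  expect_identical(mismatch_count(c(1, 1), c(0, 1), matrix(c(0, 0), 2, 1)), 1L)
  expect_error(mismatch_count(c(1, 3), c(0, 1), H), "outside")

  set.seed(61)
  for (rep in 1:20) {
    inst <- rand_instance(N = 3, L = 6)
    path <- sample.int(3, 6, replace = TRUE)
    manual <- sum(vapply(1:6, function(l) inst$h[l] != inst$H[l, path[l]], logical(1)))
    expect_identical(mismatch_count(path, inst$h, inst$H), as.integer(manual))
  }
})

test_that("diploid mismatch uses set semantics and matches the dosage oracle on biallelic data", {
  H <- matrix(c(0, 1, 1, 0), 2, 2)
  g <- genotype_from_pair(H[, 1], H[, 2])
  expect_identical(diploid_mismatch_count(c(1, 1), c(2, 2), g, H), 0L)
  # single-site set arithmetic, all 9 biallelic cases against |dosage diff|
  for (g1 in 0:1) for (g2 in 0:1) for (a1 in 0:1) for (a2 in 0:1) {
    got <- diploid_site_mismatch(1, 1, 2, as_genotype(matrix(c(g1, g2), 1, 2)),
                                 matrix(c(a1, a2), 1, 2))
    expect_identical(got, as.integer(abs((g1 + g2) - (a1 + a2))))
  }
  # printed-formula cases
  expect_identical(diploid_site_mismatch(1, 1, 2, as_genotype(matrix(c(0, 0), 1, 2)),
                                         matrix(c(0, 1), 1, 2)), 1L)
  expect_identical(diploid_site_mismatch(1, 1, 2, as_genotype(matrix(c(0, 1), 1, 2)),
                                         matrix(c(1, 1), 1, 2)), 1L)
  # symmetry in paths and in within-genotype order
  set.seed(62)
  for (rep in 1:20) {
    H <- matrix(sample(0:1, 12, TRUE), 6, 2)
    ga <- matrix(sample(0:1, 12, TRUE), 6, 2)
    g <- as_genotype(ga)
    gswap <- as_genotype(ga[, 2:1])
    p1 <- sample.int(2, 6, TRUE); p2 <- sample.int(2, 6, TRUE)
    expect_identical(diploid_mismatch_count(p1, p2, g, H),
                     diploid_mismatch_count(p2, p1, g, H))
    expect_identical(diploid_mismatch_count(p1, p2, g, H),
                     diploid_mismatch_count(p1, p2, gswap, H))
  }
  expect_error(diploid_mismatch_count(c(1, 1), 1L, g, H), "equal length")
})

test_that("penalties are positive, strictly decreasing, and reject boundary probabilities", {
  expect_error(alpha_from_p(1 / 4), "1/4")
  expect_error(beta_from_p(1 / 101, N = 100), "1/\\(N\\+1\\)")
  expect_error(alpha_from_p(0), "> 0")
  th <- c(0.01, 0.1, 1, 10); N <- 100
  a <- ls_alpha(th, N)
  expect_true(all(a > 0))
  expect_true(all(diff(a) < 0))
  rho <- c(1e-4, 1e-2, 1, 50)
  b <- ls_beta(rho, N)
  expect_true(all(b > 0))
  expect_true(all(diff(b) < 0))
  # direct evaluation at a realistic panel scale
  expect_true(is.finite(ls_beta(1e-4 * 2000, 1000)) && ls_beta(1e-4 * 2000, 1000) > 0)
  # the original-map alternative is accepted and differs from the default
  expect_gt(ls_alpha(1, 100, model = "original"), 0)
  expect_false(isTRUE(all.equal(ls_alpha(1, 100), ls_alpha(1, 100, model = "original"))))
})

test_that("equivalence curve round-trips through the penalty ratio", {
  N <- 50
  for (c0 in c(0.3, 1, 2.7)) {
    grid <- c(0.01, 0.05, 0.12, 0.2, 0.24)
    curve <- equivalence_curve(c0, grid, N)
    expect_true(all(curve$p_rho > 0 & curve$p_rho < 1 / N))
    back <- beta_from_p(curve$p_rho, N) / alpha_from_p(curve$p_theta)
    expect_equal(back, rep(c0, length(grid)), tolerance = 1e-10)
  }
  expect_error(equivalence_curve(1, 0.3, N), "\\(0, 1/4\\)")
  # c -> infinity sends p_rho -> 0 at fixed p_theta < 1/4
  expect_lt(equivalence_curve(50, 0.1, N)$p_rho, 1e-12)
  # monotonicity of c in theta at fixed rho
  cs <- vapply(c(0.5, 1, 2, 4), function(th) penalty_ratio(th, 1, N), numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("normalized path cost matches the penalty-weighted likelihood up to scale", {
  H <- matrix(c(0, 0, 0, 1, 1, 1), 3, 2)
  h <- c(0, 0, 0)
  expect_identical(path_cost(c(1, 1, 1), h, H, c = 2), 0)
  expect_identical(path_cost(c(2, 1, 2), h, H, c = 0.5), 2 + 0.5 * 2)
  expect_error(path_cost(c(1, 1, 1), h, H, c = 0), "positive")
  theta <- 0.8; rho <- 1.6; N <- 2
  c0 <- penalty_ratio(theta, rho, N)
  p <- c(1, 2, 2)
  expect_equal(ls_alpha(theta, N) * path_cost(p, h, H, c0),
               ls_alpha(theta, N) * mismatch_count(p, h, H) +
                 ls_beta(rho, N) * switch_count(p),
               tolerance = 1e-12)
})

test_that("parameter pairs on one equivalence curve rank all paths identically", {
  set.seed(63)
  N <- 3; L <- 5
  for (rep in 1:20) {
    inst <- rand_instance(N, L)
    pts <- enumerate_haploid_costs(inst$h, inst$H)
    theta <- runif(1, 0.1, 3); rho <- runif(1, 0.1, 3)
    c0 <- penalty_ratio(theta, rho, N)
    base_rank <- rank(round(pts$m + c0 * pts$r, 9), ties.method = "min")
    curve <- equivalence_curve(c0, c(0.02, 0.07, 0.13, 0.19, 0.23), N)
    for (i in seq_len(nrow(curve))) {
      ci <- beta_from_p(curve$p_rho[i], N) / alpha_from_p(curve$p_theta[i])
      expect_identical(rank(round(pts$m + ci * pts$r, 9), ties.method = "min"),
                       base_rank)
    }
  }
})
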