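test_that("degenerate and worked instances produce the expected surfaces", {
  # exact match: one zero-cost region
  H <- matrix(c(0, 1, 0, 1, 1, 0), 3, 2)
  s <- partition_haploid(H[, 1], allele_matrix(H))
  expect_identical(nrow(s$regions), 1L)
  expect_identical(s$vertices$r, 0L)
  expect_identical(s$vertices$m, 0L)
  expect_identical(s$paths[[1]], rep(1L, 3))

  # N = 1: only constant paths
  H1 <- matrix(c(0, 1, 1, 0), 4, 1)
  s1 <- partition_haploid(c(0, 0, 1, 1), allele_matrix(H1))
  expect_identical(nrow(s1$regions), 1L)
  expect_identical(s1$vertices$m, 2L)

  # two-site crossover instance: regions (0,1) r=0 m=1 and r=1 m=0 split at beta=1
  H2 <- matrix(c("a", "c", "c", "a"), 2, 2)
  s2 <- partition_haploid(c("c", "c"), allele_matrix(H2))
  expect_identical(s2$vertices$r, c(0L, 1L))
  expect_identical(s2$vertices$m, c(1L, 0L))
  expect_identical(s2$breakpoints$num, 1L)
  expect_identical(s2$breakpoints$den, 1L)
  expect_identical(reconstruct_path(s2, 2), c(2L, 1L))
  expect_error(partition_haploid(c("c"), allele_matrix(H2)), "length")
})

test_that("the surface equals the exhaustive-enumeration oracle on random instances", {
  set.seed(81)
  for (rep in 1:60) {
    N <- sample(2:4, 1); L <- sample(2:8, 1)
    inst <- rand_instance(N, L)
    s <- partition_haploid(inst$h, allele_matrix(inst$H))
    pts <- enumerate_haploid_costs(inst$h, inst$H)
    expect_surface_matches_enumeration(s, pts, n_beta = 20)
    for (i in seq_along(s$paths)) {
      p <- s$paths[[i]]
      expect_identical(switch_count(p), s$vertices$r[i])
      expect_identical(mismatch_count(p, inst$h, inst$H), s$vertices$m[i])
    }
  }
})

test_that("extreme vertices match their closed forms and regions are monotone", {
  set.seed(82)
  for (rep in 1:25) {
    N <- sample(2:12, 1); L <- sample(5:60, 1)
    inst <- rand_instance(N, L)
    s <- partition_haploid(inst$h, allele_matrix(inst$H))
    D <- matrix(as.integer(inst$h != inst$H), L, N)
    # leftmost vertex: copy the closest template in its entirety
    expect_identical(s$vertices$m[1], as.integer(min(colSums(D))))
    expect_identical(s$vertices$r[1], 0L)
    # rightmost vertex: free recombination, per-site best template
    M <- length(s$vertices$r)
    expect_identical(s$vertices$m[M], as.integer(sum(apply(D, 1, min))))
    # r strictly increasing, m strictly decreasing as beta decreases
    if (M > 1) {
      expect_true(all(diff(s$vertices$r) > 0))
      expect_true(all(diff(s$vertices$m) < 0))
    }
    # regions tile (0, Inf)
    expect_identical(s$regions$beta_lower[M], 0)
    expect_identical(s$regions$beta_upper[1], Inf)
    if (M > 1) {
      expect_identical(s$regions$beta_lower[-M], s$regions$beta_upper[-1])
    }
  }
})

test_that("the plain-R frontier recurrence reproduces the compiled global chain", {
  set.seed(83)
  for (rep in 1:10) {
    N <- sample(2:6, 1); L <- sample(3:15, 1)
    inst <- rand_instance(N, L)
    fr <- frontier_init(inst$h, inst$H)
    for (l in 2:L) fr <- extend_frontier(fr, l, inst$h, inst$H)
    s <- partition_haploid(inst$h, allele_matrix(inst$H))
    expect_identical(fr$global$r, s$vertices$r)
    expect_identical(fr$global$m, s$vertices$m)
    # frontier invariants: G merges the locals; vertices within site bounds
    expect_identical(fr$global, merge_chains(fr$local))
    expect_true(all(fr$global$r <= L - 1) && all(fr$global$m <= L))
  }
  inst <- rand_instance(3, 5)
  fr <- frontier_init(inst$h, inst$H)
  expect_error(extend_frontier(fr, 3, inst$h, inst$H), "site l - 1")
})

test_that("vertices and breakpoints are invariant under template relabeling", {
  set.seed(84)
  for (rep in 1:10) {
    N <- sample(3:8, 1); L <- sample(10:40, 1)
    inst <- rand_instance(N, L)
    s <- partition_haploid(inst$h, allele_matrix(inst$H))
    perm <- sample.int(N)
    s2 <- partition_haploid(inst$h, allele_matrix(inst$H[, perm]))
    expect_identical(s$vertices, s2$vertices)
    expect_identical(s$breakpoints, s2$breakpoints)
    # representative paths may relabel but must still attain the vertices
    for (i in seq_along(s2$paths)) {
      expect_identical(mismatch_count(s2$paths[[i]], inst$h, inst$H[, perm]),
                       s2$vertices$m[i])
    }
  }
})

test_that("surfaces serialize to JSON with run-length encoded paths", {
  H <- matrix(c("a", "c", "c", "a"), 2, 2)
  s <- partition_haploid(c("c", "c"), allele_matrix(H))
  js <- jsonlite::fromJSON(surface_to_json(s), simplifyVector = FALSE)
  expect_identical(js$mode, "haploid")
  expect_identical(length(js$paths), 2L)
  # vertex (1,0) path (2,1): segments (site 1, template 2), (site 2, template 1)
  expect_identical(js$paths[[2]], list(list(1L, 2L), list(2L, 1L)))
})
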