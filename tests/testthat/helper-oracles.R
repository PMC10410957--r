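# Shared fixtures and independent oracles, built in code.

# random biallelic instance
rand_instance <- function(N, L) {
  list(H = matrix(sample(0:1, L * N, replace = TRUE), L, N),
       h = sample(0:1, L, replace = TRUE))
}

# Independent hull oracle: a cost point is a vertex of the lower-left chain
# iff it is the unique minimizer of m + beta * r for some beta > 0.  Scans
# exact rational betas: all positive pairwise slopes plus midpoints between
# consecutive ones (and sentinels below/above), comparing costs by
# cross-multiplication so the whole check is exact.
hull_by_unique_minimizer <- function(r, m) {
  pts <- unique(data.frame(r = as.integer(r), m = as.integer(m)))
  # reduce duplicates in r (pointwise min): a dominated point can never be
  # a unique minimizer anyway, but reducing keeps the scan small
  n <- nrow(pts)
  betas <- list(c(1L, 10000L))                      # tiny beta sentinel
  slopes <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dr <- pts$r[j] - pts$r[i]; dm <- pts$m[i] - pts$m[j]
      if (dr != 0 && sign(dm) * sign(dr) > 0) {
        slopes <- rbind(slopes, c(abs(dm), abs(dr)))
      }
    }
  }
  if (!is.null(slopes)) {
    vals <- slopes[, 1] / slopes[, 2]
    o <- order(vals)
    slopes <- slopes[o, , drop = FALSE]
    vals <- vals[o]
    uniq <- slopes[!duplicated(vals), , drop = FALSE]
    vals <- vals[!duplicated(vals)]
    if (nrow(uniq) >= 2) {
      for (i in seq_len(nrow(uniq) - 1)) {
        # exact midpoint (a/b + c/d)/2 = (ad + cb) / (2bd)
        a <- uniq[i, 1]; b <- uniq[i, 2]; cc <- uniq[i + 1, 1]; d <- uniq[i + 1, 2]
        betas <- c(betas, list(c(a * d + cc * b, 2 * b * d)))
      }
    }
    betas <- c(betas, list(c(uniq[nrow(uniq), 1] * 2 + uniq[nrow(uniq), 2], uniq[nrow(uniq), 2])))
  }
  keep <- rep(FALSE, n)
  for (bb in betas) {
    cost <- bb[2] * pts$m + bb[1] * pts$r      # exact scaled cost
    mn <- min(cost)
    if (sum(cost == mn) == 1L) keep[which.min(cost)] <- TRUE
  }
  out <- pts[keep, , drop = FALSE]
  out[order(out$r), , drop = FALSE]
}

# enumeration-backed check that a surface matches ground truth at many
# exact rational betas
expect_surface_matches_enumeration <- function(surface, pts, n_beta = 50) {
  hull <- lower_left_hull(pts$r, pts$m)
  expect_identical(surface$vertices$r, hull$r)
  expect_identical(surface$vertices$m, hull$m)
  rmax <- max(pts$r)
  for (b in seq_len(n_beta)) {
    bn <- sample.int(2L * rmax + 4L, 1L)
    bd <- sample.int(9L, 1L)
    idx <- region_for_beta(surface$vertices, surface$breakpoints, c(bn, bd))
    expect_identical(min(bd * pts$m + bn * pts$r),
                     bd * surface$vertices$m[idx] + bn * surface$vertices$r[idx])
  }
}
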