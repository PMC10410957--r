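# Slow, independent reference decoders used for validation only.
#
# All oracles accept an exact rational penalty beta = num/den and work in
# scaled integer arithmetic (minimize den * m + num * k), so comparisons
# against the surface algorithms are exact equalities, never tolerances.

check_beta_rational <- function(beta_num, beta_den) {
  if (beta_num <= 0 || beta_den <= 0) stop("beta must be a positive rational")
  if (beta_num != floor(beta_num) || beta_den != floor(beta_den)) {
    stop("beta must be given as an integer num/den pair")
  }
  invisible(TRUE)
}

#' Fixed-penalty Viterbi decoding (haploid reference implementation)
#'
#' Direct `O(L N)` dynamic programme minimizing `m + beta k` at one exact
#' rational `beta = beta_num / beta_den`.  Ties prefer staying on the
#' current template, then lower template indices.
#'
#' @param h focal haplotype.
#' @param H template panel.
#' @param beta_num,beta_den positive integers encoding beta exactly.
#' @return list with `path` (integer vector), `cost` (numeric `m + beta k`),
#'   and `cost_scaled` (exact integer `beta_den * m + beta_num * k`).
#' @export
viterbi_haploid <- function(h, H, beta_num, beta_den = 1L) {
  check_beta_rational(beta_num, beta_den)
  L <- nrow(H); N <- ncol(H)
  h <- as_haplotype(h, H)
  q <- beta_den; p <- beta_num
  S <- q * as.numeric(h[1L] != H[1L, ])
  stay <- matrix(TRUE, L, N)
  from <- integer(L)
  if (L >= 2L) {
    for (l in 2:L) {
      gmin_n <- which.min(S)                 # lowest index on ties
      gmin <- S[gmin_n]
      sw <- gmin + p
      stay[l, ] <- S <= sw                   # prefer no switch on ties
      from[l] <- gmin_n
      S <- pmin(S, sw) + q * (h[l] != H[l, ])
    }
  }
  path <- integer(L)
  path[L] <- which.min(S)
  if (L >= 2L) {
    for (l in L:2) {
      path[l - 1L] <- if (stay[l, path[l]]) path[l] else from[l]
    }
  }
  cs <- min(S)
  list(path = path, cost = cs / q, cost_scaled = cs)
}

#' Fixed-penalty Viterbi decoding (diploid reference implementation)
#'
#' `O(L N^2)` dynamic programme over ordered template pairs minimizing
#' `m(path1, path2) + beta (k(path1) + k(path2))` at one exact rational
#' beta, using the row-min/column-min/global-min decomposition for the
#' single- and double-switch transitions.
#'
#' @param g genotype sequence (`L x 2`).
#' @param H template panel.
#' @param beta_num,beta_den positive integers encoding beta exactly.
#' @return list with `pair` (list of two paths), `cost`, `cost_scaled`.
#' @export
viterbi_diploid <- function(g, H, beta_num, beta_den = 1L) {
  check_beta_rational(beta_num, beta_den)
  L <- nrow(H); N <- ncol(H)
  g <- as_genotype(unclass(g))
  q <- beta_den; p <- beta_num
  site_d <- function(l) {
    a <- H[l, ]
    outer(seq_len(N), seq_len(N),
          function(i, j) site_pair_mismatch(g[l, 1L], g[l, 2L], a[i], a[j]))
  }
  S <- q * site_d(1L)
  move <- vector("list", L)   # per site: transition code matrix
  if (L >= 2L) {
    for (l in 2:L) {
      rowm <- apply(S, 1L, min)          # best over second coordinate
      colm <- apply(S, 2L, min)
      gm <- min(S)
      cand1 <- S                          # stay/stay
      cand2 <- outer(rowm, rep(p, N), `+`)       # keep first, switch second
      cand3 <- outer(rep(p, N), colm, `+`)       # switch first, keep second
      cand4 <- gm + 2 * p                  # switch both
      best <- pmin(cand1, cand2, cand3, cand4)
      code <- matrix(4L, N, N)
      code[cand3 <= best] <- 3L
      code[cand2 <= best] <- 2L
      code[cand1 <= best] <- 1L
      move[[l]] <- code
      S <- best + q * site_d(l)
    }
  }
  # backtrack (ties resolved by the code preference above, then lowest index)
  amin <- arrayInd(which.min(S), dim(S))
  p1 <- integer(L); p2 <- integer(L)
  p1[L] <- amin[1L]; p2[L] <- amin[2L]
  if (L >= 2L) {
    # recompute forward tables to trace argmins cheaply
    Ss <- vector("list", L)
    S2 <- q * site_d(1L); Ss[[1L]] <- S2
    for (l in 2:L) {
      rowm <- apply(S2, 1L, min); colm <- apply(S2, 2L, min); gm <- min(S2)
      best <- pmin(S2, outer(rowm, rep(p, N), `+`), outer(rep(p, N), colm, `+`), gm + 2 * p)
      S2 <- best + q * site_d(l)
      Ss[[l]] <- S2
    }
    for (l in L:2) {
      prev <- Ss[[l - 1L]]
      i <- p1[l]; j <- p2[l]
      cd <- move[[l]][i, j]
      if (cd == 1L) { p1[l - 1L] <- i; p2[l - 1L] <- j }
      else if (cd == 2L) { p1[l - 1L] <- i; p2[l - 1L] <- which.min(prev[i, ]) }
      else if (cd == 3L) { p1[l - 1L] <- which.min(prev[, j]); p2[l - 1L] <- j }
      else { am <- arrayInd(which.min(prev), dim(prev)); p1[l - 1L] <- am[1L]; p2[l - 1L] <- am[2L] }
    }
  }
  cs <- min(S)
  list(pair = list(p1, p2), cost = cs / q, cost_scaled = cs)
}

#' Direct mismatch-table dynamic programme
#'
#' Computes `J[r, n]`, the least mismatch count among length-`L` paths with
#' exactly `r` switches ending at template `n` (`r` in `0..L-1`), by the
#' direct `O(L^2 N)` recurrence; infeasible entries are `Inf`.  The lower
#' hull of `(r, min_n J[r, n])` must equal the surface's vertex chain —
#' this table exists purely as a cross-check and is far too slow for
#' production use.
#'
#' @param h focal haplotype.
#' @param H template panel.
#' @return list with matrix `J` (`L x N`, row `r+1` = `r` switches) and
#'   vector `J_min` (`min_n J[r, n]`).
#' @export
j_table <- function(h, H) {
  L <- nrow(H); N <- ncol(H)
  h <- as_haplotype(h, H)
  J <- matrix(Inf, nrow = L, ncol = N)    # rows: r = 0 .. L-1
  J[1L, ] <- as.numeric(h[1L] != H[1L, ])
  if (L >= 2L) {
    for (l in 2:L) {
      d <- as.numeric(h[l] != H[l, ])
      Jnew <- matrix(Inf, nrow = L, ncol = N)
      rmax <- l - 1L
      prev_min <- apply(J, 1L, min)
      for (r in 0:rmax) {
        stayv <- J[r + 1L, ]
        swv <- if (r >= 1L) prev_min[r] else Inf
        Jnew[r + 1L, ] <- pmin(stayv, swv) + d
      }
      J <- Jnew
    }
  }
  list(J = J, J_min = apply(J, 1L, min))
}

#' Exhaustively enumerate haploid path costs
#'
#' All `N^L` copying paths with their switch and mismatch counts; tiny
#' instances only.  Used as the ground-truth oracle for the surface.
#'
#' @param h focal haplotype.
#' @param H template panel.
#' @return data.frame with columns `r`, `m`, one row per path.
#' @export
enumerate_haploid_costs <- function(h, H) {
  L <- nrow(H); N <- ncol(H)
  if (N^L > 2^20) stop("instance too large to enumerate")
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), L)))
  D <- matrix(as.integer(h != H[cbind(rep(seq_len(L), N), rep(seq_len(N), each = L))]), L, N)
  m <- rowSums(matrix(D[cbind(rep(seq_len(L), each = nrow(paths)), as.vector(paths))],
                      nrow(paths), L))
  r <- if (L >= 2L) rowSums(paths[, -1L, drop = FALSE] != paths[, -L, drop = FALSE]) else 0L
  data.frame(r = as.integer(r), m = as.integer(m))
}

#' Exhaustively enumerate diploid path-pair costs
#'
#' All unordered pairs of `N^L` paths with `r = k(path1) + k(path2)` and
#' the diploid mismatch count; tiny instances only.
#'
#' @param g genotype sequence.
#' @param H template panel.
#' @return data.frame with columns `r`, `m`.
#' @export
enumerate_diploid_costs <- function(g, H) {
  L <- nrow(H); N <- ncol(H)
  if (N^(2 * L) > 2^20) stop("instance too large to enumerate")
  g <- as_genotype(unclass(g))
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), L)))
  P <- nrow(paths)
  k1 <- if (L >= 2L) rowSums(paths[, -1L, drop = FALSE] != paths[, -L, drop = FALSE]) else rep(0L, P)
  # site-wise pair mismatch matrices
  Dl <- lapply(seq_len(L), function(l) {
    a <- H[l, ]
    outer(seq_len(N), seq_len(N),
          function(i, j) site_pair_mismatch(g[l, 1L], g[l, 2L], a[i], a[j]))
  })
  m <- matrix(0L, P, P)
  for (l in seq_len(L)) {
    m <- m + Dl[[l]][cbind(rep(paths[, l], P), rep(paths[, l], each = P))]
  }
  r <- outer(k1, k1, `+`)
  data.frame(r = as.integer(r), m = as.integer(m))
}
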