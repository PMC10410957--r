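# Exact integer-lattice lower-left hull machinery.
#
# All cost points (r = switches, m = mismatches) are integers; hulls and
# breakpoints are computed in exact integer/rational arithmetic so results
# are identical across platforms.

# Indices (into the input vectors) of the strictly convex lower-left chain.
# Preference on exact (r, m) ties goes to the earlier index, so callers
# encode tie-break policy by candidate order.  Steps: pointwise-min
# reduction over duplicate r; truncation at the first r attaining the
# minimal m (slope >= 0 tail is never optimal for beta > 0); monotone-chain
# scan with strict convexity (collinear interior points dropped).
lll_keep <- function(r, m) {
  n <- length(r)
  if (n == 0L) stop("empty point set")
  o <- order(r, m)                        # stable: earliest index wins ties
  r <- r[o]; m <- m[o]
  first <- !duplicated(r)
  o <- o[first]; r <- r[first]; m <- m[first]
  cut <- which(m == min(m))[1L]
  if (cut < length(r)) {
    o <- o[seq_len(cut)]; r <- r[seq_len(cut)]; m <- m[seq_len(cut)]
  }
  k <- length(r)
  if (k <= 2L) return(o)
  h <- integer(k); top <- 0L
  for (i in seq_len(k)) {
    while (top >= 2L) {
      i1 <- h[top - 1L]; i2 <- h[top]
      # pop i2 unless slope(i1,i2) < slope(i2,i) strictly (exact integers)
      if ((m[i2] - m[i1]) * (r[i] - r[i2]) >= (m[i] - m[i2]) * (r[i2] - r[i1])) {
        top <- top - 1L
      } else break
    }
    top <- top + 1L
    h[top] <- i
  }
  o[h[seq_len(top)]]
}

#' Construct a vertex chain
#'
#' A vertex chain is the strictly convex lower-left hull of a set of integer
#' cost points `(r, m)`: `r` strictly increasing, `m` strictly decreasing,
#' successive slopes strictly increasing.  This is the object that encodes
#' every possible optimal cost structure for positive switch penalties.
#'
#' @param r,m equal-length integer vectors.
#' @return object of class `"vertex_chain"`: list with integer vectors `r`,
#'   `m` satisfying the chain invariants.
#' @export
vertex_chain <- function(r, m) {
  r <- as.integer(r); m <- as.integer(m)
  if (length(r) != length(m) || length(r) == 0L) stop("r and m must be nonempty and equal length")
  if (any(is.na(r)) || any(is.na(m))) stop("vertex coordinates must be integers")
  ch <- structure(list(r = r, m = m), class = "vertex_chain")
  validate_chain(ch)
  ch
}

validate_chain <- function(chain) {
  r <- chain$r; m <- chain$m
  if (any(r < 0L) || any(m < 0L)) stop("vertex coordinates must be nonnegative")
  if (length(r) > 1L) {
    if (any(diff(r) <= 0L)) stop("chain r must be strictly increasing")
    if (any(diff(m) >= 0L)) stop("chain m must be strictly decreasing")
    if (length(r) > 2L) {
      dr <- diff(r); dm <- diff(m)
      # strict convexity by cross-multiplication: dm[i]/dr[i] < dm[i+1]/dr[i+1]
      i <- seq_len(length(dr) - 1L)
      if (any(dm[i] * dr[i + 1L] >= dm[i + 1L] * dr[i])) {
        stop("chain slopes must be strictly increasing (strict convexity)")
      }
    }
  }
  invisible(chain)
}

#' @export
print.vertex_chain <- function(x, ...) {
  cat(sprintf("vertex chain with %d vertices: ", length(x$r)))
  cat(paste0("(", x$r, ",", x$m, ")", collapse = " "), "\n")
  invisible(x)
}

#' Lower-left hull of integer cost points
#'
#' Reduces duplicate `r` values to their minimal `m`, then returns the
#' strictly convex lower-left chain: the portion of the lower convex hull
#' with strictly negative slope, ending at the minimal-mismatch vertex.
#' Points on slope `>= 0` segments are discarded because they are never
#' optimal under a positive switch penalty.  All arithmetic is exact.
#'
#' @param r,m integer vectors (switch counts, mismatch counts), or a
#'   two-column matrix as `r` with `m` missing.
#' @return a [vertex_chain()].
#' @export
lower_left_hull <- function(r, m = NULL) {
  if (is.null(m)) { m <- r[, 2L]; r <- r[, 1L] }
  if (length(r) == 0L) stop("empty point set")
  if (any(r != floor(r)) || any(m != floor(m))) stop("cost points must be exact integers")
  keep <- lll_keep(as.integer(r), as.integer(m))
  vertex_chain(r[keep], m[keep])
}

#' Merge vertex chains
#'
#' The lower-left hull of the pooled vertices of several chains.  Because
#' every vertex of the merged hull must be a vertex of some input chain
#' (pooled hulls are spanned by their extreme points), merging the chains is
#' equivalent to hulling the union of the underlying raw point sets.
#'
#' @param chains list of [vertex_chain()] objects.
#' @return a [vertex_chain()].
#' @export
merge_chains <- function(chains) {
  if (length(chains) == 0L) stop("need at least one chain")
  r <- unlist(lapply(chains, `[[`, "r"), use.names = FALSE)
  m <- unlist(lapply(chains, `[[`, "m"), use.names = FALSE)
  lower_left_hull(r, m)
}

# reduced integer fraction helpers --------------------------------------

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(nz <- b != 0)) {
    t <- b[nz]
    b[nz] <- a[nz] %% t
    a[nz] <- t
  }
  a
}

reduce_fraction <- function(num, den) {
  g <- gcd_int(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

#' Exact breakpoints of a vertex chain
#'
#' The penalty axis is partitioned by the slope magnitudes between
#' consecutive hull vertices: `beta_i = (m_i - m_{i+1}) / (r_{i+1} - r_i)`,
#' returned as reduced integer fractions in strictly decreasing order.
#' A single-vertex chain has no breakpoints (one region covering all
#' `beta > 0`).
#'
#' @param chain a [vertex_chain()].
#' @return object of class `"breakpoints"`: data.frame with integer columns
#'   `num`, `den` and the numeric `value = num/den`.
#' @export
chain_breakpoints <- function(chain) {
  validate_chain(chain)
  M <- length(chain$r)
  if (M == 1L) {
    out <- data.frame(num = integer(0), den = integer(0), value = numeric(0))
  } else {
    num <- chain$m[-M] - chain$m[-1L]
    den <- chain$r[-1L] - chain$r[-M]
    f <- reduce_fraction(num, den)
    out <- data.frame(num = as.integer(f$num), den = as.integer(f$den),
                      value = f$num / f$den)
  }
  class(out) <- c("breakpoints", class(out))
  out
}

#' Optimal vertex for a given switch penalty
#'
#' Returns the index (into the chain) of the vertex minimizing
#' `m_i + beta * r_i`.  Exactly at a breakpoint both flanking vertices are
#' optimal; the smaller-`r` vertex is returned and the result carries
#' `attr(, "tie") = TRUE`.  Rational penalties can be supplied exactly via
#' `beta = c(num, den)`.
#'
#' @param chain a [vertex_chain()].
#' @param bps breakpoints of `chain` (recomputed if missing).
#' @param beta positive penalty; either a single numeric or an exact
#'   `c(num, den)` integer pair.
#' @return integer vertex index with logical attribute `"tie"`.
#' @export
region_for_beta <- function(chain, bps = NULL, beta) {
  if (is.null(bps)) bps <- chain_breakpoints(chain)
  if (length(beta) == 2L) { bn <- beta[1L]; bd <- beta[2L] } else { bn <- beta; bd <- 1 }
  if (bd <= 0 || bn <= 0) stop("beta must be positive")
  # region i covers [beta_i, beta_{i-1}); vertex i optimal there.
  # count breakpoints strictly greater than beta (cross-multiplied compare)
  gt <- sum(bps$num * bd > bn * bps$den)
  idx <- gt + 1L
  tie <- any(bps$num * bd == bn * bps$den)
  attr(idx, "tie") <- tie
  idx
}

#' Serialize a vertex chain and its breakpoints to JSON
#'
#' Dialect: `{"vertices": [[r, m], ...], "breakpoints": [[num, den], ...]}`.
#'
#' @param chain a [vertex_chain()].
#' @param bps breakpoints (recomputed if missing).
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
chain_to_json <- function(chain, bps = NULL, path = NULL) {
  if (is.null(bps)) bps <- chain_breakpoints(chain)
  obj <- list(
    vertices = unname(Map(c, chain$r, chain$m)),
    breakpoints = unname(Map(c, bps$num, bps$den))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
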