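# Single-pass haploid solution surface.
#
# Per template n the frontier holds the locally active chain F^(n) (hull of
# (switches, mismatches) over paths ending at n); the global chain G is the
# merge of the F^(n).  Extending to the next site, each template's new chain
# is the hull of its stay-candidates {(r, m + d)} and the switch-candidates
# {(r + 1, m + d)} drawn from G: every new locally active path either
# extends a locally active path without switching or enters from a globally
# active path with one switch.  The production pass (with backpointers for
# path reconstruction) runs in compiled code; frontier_init()/
# extend_frontier() expose the same recurrence step in plain R as the
# reference the compiled core is tested against.

#' Per-site copying-error indicator
#'
#' @param l site index (1-based).
#' @param n template index.
#' @param h focal haplotype.
#' @param H template panel.
#' @return 0 if `h[l]` equals `H[l, n]`, else 1.
#' @export
mismatch_indicator <- function(l, n, h, H) {
  if (l < 1L || l > nrow(H)) stop("site index out of range")
  if (any(n < 1L | n > ncol(H))) stop("template index out of range")
  as.integer(h[l] != H[l, n])
}

#' Haploid frontier recurrence (reference implementation)
#'
#' `frontier_init()` builds the site-1 frontier (per-template chains with
#' the single point `(0, d_1(n))` and their merge); `extend_frontier()`
#' advances it one site: each template's new local chain is the lower-left
#' hull of its no-switch candidates `(r, m + d)` and the switch candidates
#' `(r + 1, m + d)` drawn from the previous global chain.  These functions
#' carry no backpointers; [partition_haploid()] is the production path.
#'
#' @param h focal haplotype.
#' @param H template panel.
#' @return list with `local` (list of `N` [vertex_chain()]s), `global`
#'   (their merge), and `site`.
#' @export
frontier_init <- function(h, H) {
  N <- ncol(H)
  local <- lapply(seq_len(N), function(n) vertex_chain(0L, mismatch_indicator(1L, n, h, H)))
  list(local = local, global = merge_chains(local), site = 1L)
}

#' @rdname frontier_init
#' @param frontier a frontier at site `l`.
#' @param l the site to extend to (`frontier$site + 1`).
#' @export
extend_frontier <- function(frontier, l, h, H) {
  if (l != frontier$site + 1L) stop("frontier is not at site l - 1")
  if (l > nrow(H)) stop("site index beyond the panel")
  G <- frontier$global
  local <- lapply(seq_len(ncol(H)), function(n) {
    d <- mismatch_indicator(l, n, h, H)
    fn <- frontier$local[[n]]
    lower_left_hull(c(fn$r, G$r + 1L), c(fn$m + d, G$m + d))
  })
  list(local = local, global = merge_chains(local), site = l)
}

#' All haploid decodings of a focal haplotype
#'
#' Computes, in one pass over the sites, the complete set of optimal
#' haploid decodings as the switch penalty `beta` sweeps `(0, Inf)`.  The
#' result partitions the penalty axis into half-open regions
#' `[beta_i, beta_{i-1})`, each with a constant optimal cost structure
#' `(r_i, m_i)` and one representative optimal copying path attaining
#' exactly those switch and mismatch counts.  Ties at candidate points are
#' broken deterministically: no-switch parents are preferred to switch
#' parents, then lower template indices.
#'
#' @param h focal haplotype (length `L`).
#' @param H template panel (`L x N`).
#' @return object of class `"ls_surface"`: list with elements
#'   `vertices` ([vertex_chain()] at the final site), `breakpoints`
#'   ([chain_breakpoints()]), `regions` (data.frame tiling `(0, Inf)`,
#'   one row per vertex, with exact rational bounds), `paths` (list of
#'   representative copying paths, one per vertex), `mode = "haploid"`,
#'   `L`, `N`.
#' @export
partition_haploid <- function(h, H) {
  L <- nrow(H); N <- ncol(H)
  if (is.null(L) || L < 1L) stop("panel must have at least one site")
  h <- as_haplotype(h, H)
  D <- matrix(as.integer(h != H), L, N)
  core <- .ls_haploid_core(D)
  chain <- vertex_chain(core$r, core$m)
  bps <- chain_breakpoints(chain)
  paths <- lapply(seq_along(core$r), function(i) core$paths[i, ])
  build_surface(chain, bps, paths, mode = "haploid", L = L, N = N)
}

# assemble the region table shared by the haploid and diploid surfaces
build_surface <- function(chain, bps, paths, mode, L, N) {
  M <- length(chain$r)
  lower_num <- c(bps$num, 0L)
  lower_den <- c(bps$den, 1L)
  upper_num <- c(NA_integer_, bps$num)   # region 1 unbounded above
  upper_den <- c(NA_integer_, bps$den)
  regions <- data.frame(
    vertex = seq_len(M),
    r = chain$r, m = chain$m,
    beta_lower = lower_num / lower_den,
    beta_upper = c(Inf, bps$value),
    lower_num = lower_num, lower_den = lower_den,
    upper_num = upper_num, upper_den = upper_den,
    tie_at_lower = c(rep(TRUE, M - 1L), FALSE)
  )
  structure(
    list(vertices = chain, breakpoints = bps, regions = regions,
         paths = paths, mode = mode, L = L, N = N),
    class = "ls_surface"
  )
}

#' @export
print.ls_surface <- function(x, ...) {
  cat(sprintf("Li-Stephens %s solution surface: L = %d sites, N = %d templates\n",
              x$mode, x$L, x$N))
  cat(sprintf("%d region(s) over beta in (0, Inf):\n", nrow(x$regions)))
  for (i in seq_len(nrow(x$regions))) {
    rg <- x$regions[i, ]
    cat(sprintf("  beta in [%s, %s): r = %d, m = %d\n",
                format(rg$beta_lower, digits = 4),
                format(rg$beta_upper, digits = 4), rg$r, rg$m))
  }
  invisible(x)
}

#' Representative optimal path for a surface vertex
#'
#' @param surface an `"ls_surface"` from [partition_haploid()] or
#'   [partition_diploid()].
#' @param vertex vertex index (row of `surface$regions`).
#' @return integer copying path (haploid) or list of two paths (diploid)
#'   whose switch and mismatch counts equal the vertex coordinates exactly.
#' @export
reconstruct_path <- function(surface, vertex) {
  if (vertex < 1L || vertex > length(surface$paths)) stop("invalid vertex index")
  surface$paths[[vertex]]
}

#' Serialize a solution surface to JSON
#'
#' Vertices and breakpoints use the exact dialect of [chain_to_json()];
#' representative paths are run-length encoded as `(start_site, template)`
#' segments.
#'
#' @param surface an `"ls_surface"`.
#' @param path optional output file.
#' @param include_paths include run-length encoded representative paths.
#' @return JSON string.
#' @export
surface_to_json <- function(surface, path = NULL, include_paths = TRUE) {
  rle_encode <- function(p) {
    r <- rle(p)
    starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    unname(Map(c, starts, r$values))
  }
  obj <- list(
    mode = jsonlite::unbox(surface$mode),
    L = jsonlite::unbox(surface$L),
    N = jsonlite::unbox(surface$N),
    vertices = unname(Map(c, surface$vertices$r, surface$vertices$m)),
    breakpoints = unname(Map(c, surface$breakpoints$num, surface$breakpoints$den))
  )
  if (include_paths) {
    obj$paths <- if (surface$mode == "haploid") {
      lapply(surface$paths, rle_encode)
    } else {
      lapply(surface$paths, function(pr) list(rle_encode(pr[[1L]]), rle_encode(pr[[2L]])))
    }
  }
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
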