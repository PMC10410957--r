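#' Validate a template haplotype panel
#'
#' A panel is an `L x N` matrix whose rows are sites and whose columns are
#' template haplotypes, over a finite allele alphabet.  The default alphabet
#' is biallelic `0/1`; nucleotide data may be supplied as lower-case
#' characters `"a","c","g","t"`.  An optional vector of strictly increasing
#' physical positions (bp) can be attached as `attr(H, "positions")`.
#'
#' @param x matrix (integer 0/1 or character acgt), sites in rows, templates
#'   in columns.
#' @param positions optional numeric vector of length `nrow(x)`, strictly
#'   increasing physical coordinates.
#' @return the validated matrix, with class `"allele_matrix"` prepended and
#'   the positions attached (if given).
#' @export
allele_matrix <- function(x, positions = NULL) {
  if (!is.matrix(x)) stop("panel must be a matrix (sites x templates)")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("panel must have L >= 1 sites and N >= 1 templates")
  check_alleles(x)
  if (!is.null(positions)) {
    if (length(positions) != nrow(x)) stop("positions must have one entry per site")
    if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
    attr(x, "positions") <- as.numeric(positions)
  }
  class(x) <- c("allele_matrix", class(x))
  x
}

# alphabet check shared by panel / focal / genotype validators
check_alleles <- function(x) {
  v <- as.vector(x)
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1))) stop("numeric alleles must be biallelic 0/1")
  } else if (is.character(v)) {
    if (!all(v %in% c("a", "c", "g", "t"))) stop("character alleles must be in {a,c,g,t}")
  } else stop("alleles must be numeric 0/1 or characters a/c/g/t")
  invisible(TRUE)
}

#' Validate a focal haplotype against a panel
#'
#' @param h allele vector of length `L`.
#' @param H template panel; if supplied, lengths and alphabets must agree.
#' @return `h`, invisibly validated.
#' @export
as_haplotype <- function(h, H = NULL) {
  h <- as.vector(h)
  check_alleles(h)
  if (!is.null(H)) {
    if (length(h) != nrow(H)) stop("focal haplotype length must equal the panel's site count")
    if (is.numeric(h) != is.numeric(H[1L, 1L])) stop("focal and panel alphabets differ")
  }
  h
}

#' Construct an unordered genotype sequence
#'
#' A diplotype is a sequence of unordered allele pairs; it is stored as an
#' `L x 2` matrix with each row canonically sorted, so that the two input
#' allele orders at a site are indistinguishable downstream.
#'
#' @param g `L x 2` matrix of alleles, or the result of [genotype_from_pair()].
#' @return `L x 2` matrix with rows sorted, class `"genotype_sequence"`.
#' @export
as_genotype <- function(g) {
  if (!is.matrix(g) || ncol(g) != 2L) stop("genotypes must be an L x 2 matrix")
  check_alleles(g)
  swap <- g[, 1L] > g[, 2L]
  if (any(swap)) g[swap, ] <- g[swap, 2:1, drop = FALSE]
  class(g) <- c("genotype_sequence", class(g))
  g
}

#' Combine two haplotypes into an unphased genotype sequence
#' @param h1,h2 allele vectors of equal length.
#' @return canonical genotype sequence (phase discarded).
#' @export
genotype_from_pair <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("haplotypes must have equal length")
  as_genotype(cbind(h1, h2, deparse.level = 0))
}

#' Read a plain-text allele matrix
#'
#' One row per site, whitespace- or comma-separated integer alleles, one
#' column per template haplotype.
#'
#' @param file path.
#' @return an [allele_matrix()].
#' @export
read_allele_matrix <- function(file) {
  sep <- if (grepl("\\.csv$", file)) "," else ""
  x <- as.matrix(utils::read.table(file, sep = sep, header = FALSE))
  dimnames(x) <- NULL
  allele_matrix(x)
}

#' Read a focal haplotype from a one-column text file
#' @param file path.
#' @return allele vector.
#' @export
read_focal_haplotype <- function(file) {
  as_haplotype(utils::read.table(file, header = FALSE)[[1L]])
}

#' Read a phased VCF into a panel plus a designated focal sample
#'
#' Requires phased GT fields (`|` separators).  Biallelic records only; the
#' two haplotypes of every non-focal sample become columns of the panel, and
#' the focal sample's two haplotypes are returned separately (use either as
#' the focal haplotype, or both to form a genotype sequence).
#'
#' @param file VCF path (plain text or bgzipped).
#' @param focal_sample sample name to split off as the focal individual.
#' @return list with `H` ([allele_matrix()]), `focal` (2-column matrix of the
#'   focal sample's haplotypes), and `positions`.
#' @export
read_panel_vcf <- function(file, focal_sample) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF panels requires the vcfR package")
  }
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) stop("VCF genotypes must be phased ('|')")
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE))) stop("multiallelic records are not supported")
  samples <- colnames(gt)
  if (!(focal_sample %in% samples)) stop(sprintf("focal sample '%s' not found in VCF", focal_sample))
  split_gt <- function(col) {
    parts <- strsplit(col, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("expected diploid phased genotypes")
    m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
    if (any(is.na(m)) || any(!m %in% c(0L, 1L))) stop("GT alleles must be 0 or 1")
    m
  }
  cols <- lapply(samples, function(s) split_gt(gt[, s]))
  names(cols) <- samples
  focal <- cols[[focal_sample]]
  panel <- do.call(cbind, cols[setdiff(samples, focal_sample)])
  pos <- as.numeric(vcfR::getPOS(v))
  list(
    H = allele_matrix(panel, positions = pos),
    focal = focal,
    positions = pos
  )
}
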