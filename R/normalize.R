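#' Median-of-ratios size factors
#'
#' Per-sample scaling constants in the classic median-of-ratios style: each
#' gene's geometric mean across samples is the reference, genes with a zero
#' count in any sample are excluded (their log-geometric mean is -Inf), and
#' a sample's factor is the median over the remaining reference genes of
#' count / reference. An even number of reference genes takes the
#' arithmetic mean of the two central ratios (the [stats::median()]
#' convention).
#'
#' @param x a [count_matrix()] or numeric matrix (genes x samples).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
#' @examples
#' m <- matrix(c(2, 2, 4, 4), 2)          # sample 2 at double depth
#' size_factors(m)                        # c(1/sqrt(2), sqrt(2))
size_factors <- function(x) {
  counts <- .as_counts(x)
  log_geo <- rowMeans(log(counts))        # -Inf for any gene with a zero
  ref <- is.finite(log_geo)
  if (!any(ref))
    stop("no reference genes: every gene has a zero count in some sample; ",
         "filter samples or supply deeper data")
  sf <- apply(counts[ref, , drop = FALSE], 2,
              function(col) exp(stats::median(log(col) - log_geo[ref])))
  names(sf) <- colnames(counts)
  sf
}

#' Divide counts by per-sample size factors
#'
#' @param x a [count_matrix()] or numeric matrix.
#' @param sf positive size factors, one per sample; defaults to
#'   [size_factors()] of `x`.
#' @return numeric matrix of normalized (real-valued) counts.
#' @export
normalize_counts <- function(x, sf = size_factors(x)) {
  counts <- .as_counts(x)
  if (length(sf) != ncol(counts))
    stop("need one size factor per sample")
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factors must be positive and finite")
  sweep(counts, 2, sf, "/")
}
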