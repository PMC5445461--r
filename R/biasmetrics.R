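# Read-count bias profiling: order genes by mean normalized count, cut them
# into fixed-size bins, and summarize the SNR spread and the proportion of
# DE calls per bin. A Spearman rank trend over bins reduces the profile to
# a scalar in [-1, 1].

#' Bin genes by mean normalized count
#'
#' Sorts genes in ascending order of their mean normalized count (over all
#' samples, ties broken by gene identifier) and forms consecutive bins of
#' `bin_size` genes; a shorter final bin holds any remainder. Per bin, the
#' 5/25/50/75/95% quantiles and the IQR of the SNR are computed over genes
#' with a defined SNR.
#'
#' @param gene_scores data.frame with `gene_id` and `snr` (e.g. from
#'   [snr_scores()]).
#' @param mean_counts per-gene mean normalized count, aligned with
#'   `gene_scores`.
#' @param bin_size genes per bin (>= 2).
#' @return a `bias_profile` data.frame, one row per bin, with the bin
#'   membership stored in `attr(, "bins")`.
#' @export
bin_genes <- function(gene_scores, mean_counts, bin_size = 1000) {
  stopifnot(is.data.frame(gene_scores), "snr" %in% names(gene_scores))
  if (bin_size < 2) stop("'bin_size' must be >= 2")
  n <- nrow(gene_scores)
  if (length(mean_counts) != n)
    stop("'mean_counts' must align with 'gene_scores'")
  if (n < bin_size)
    warning("fewer genes than one bin; returning a single bin")
  ord <- order(mean_counts, gene_scores$gene_id)
  bin_of_rank <- ceiling(seq_len(n) / bin_size)
  bins <- split(ord, bin_of_rank)
  rows <- lapply(seq_along(bins), function(b) {
    idx <- bins[[b]]
    snr <- gene_scores$snr[idx]
    snr <- snr[!is.na(snr)]
    q <- if (length(snr)) stats::quantile(snr, c(.05, .25, .5, .75, .95),
                                          names = FALSE)
         else rep(NA_real_, 5)
    data.frame(bin_index = b, n_genes = length(idx),
               count_low = min(mean_counts[idx]),
               count_high = max(mean_counts[idx]),
               snr_q05 = q[1], snr_q25 = q[2], snr_q50 = q[3],
               snr_q75 = q[4], snr_q95 = q[5],
               snr_spread = q[4] - q[2])
  })
  profile <- do.call(rbind, rows)
  attr(profile, "bins") <- bins
  attr(profile, "gene_ids") <- gene_scores$gene_id
  class(profile) <- c("bias_profile", "data.frame")
  profile
}

#' Fill per-bin DE-call proportions into a bias profile
#'
#' @param profile a `bias_profile` from [bin_genes()].
#' @param de_calls logical per gene (aligned with the `gene_scores` used to
#'   build the profile), e.g. `fdr_q < 0.05`.
#' @return the profile with a `de_proportion` column.
#' @export
de_proportion_per_bin <- function(profile, de_calls) {
  stopifnot(inherits(profile, "bias_profile"))
  bins <- attr(profile, "bins")
  if (length(de_calls) != length(attr(profile, "gene_ids")))
    stop("'de_calls' must have one value per profiled gene")
  profile$de_proportion <- vapply(bins, function(idx)
    mean(de_calls[idx], na.rm = TRUE), numeric(1))
  profile
}

#' Scalar read-count-bias trend
#'
#' Spearman rank correlation between the bin index (ascending mean count)
#' and a per-bin channel: `+1` means the channel increases strictly with
#' the read count (maximal bias), `0` means no monotone association. A
#' constant channel returns 0 with attribute `degenerate = TRUE`. Because
#' the smallest-count bins carry the "local" bias at any dispersion, they
#' can be set aside via `skip_first` before the trend is computed.
#'
#' This scalar is a summary statistic of the bias profile defined by this
#' package; the bias itself is conventionally assessed visually.
#'
#' @param profile a `bias_profile` with the requested channel filled in.
#' @param channel `"de_proportion"` or `"snr_spread"`.
#' @param skip_first number of initial bins to exclude (default 0).
#' @return numeric in \[-1, 1\].
#' @export
bias_trend <- function(profile, channel = c("de_proportion", "snr_spread"),
                       skip_first = 0) {
  channel <- match.arg(channel)
  if (!channel %in% names(profile))
    stop("channel '", channel, "' not present; fill the profile first")
  keep <- profile$bin_index > skip_first
  y <- profile[[channel]][keep]
  if (length(y) < 3) stop("need at least 3 bins for a trend")
  if (length(unique(y)) == 1) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(profile$bin_index[keep], y, method = "spearman")
}
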