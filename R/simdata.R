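#' Construct a count matrix with a two-group sample annotation
#'
#' Lightweight container for gene x sample integer read counts, in the style
#' of edgeR's DGEList: a list with the count matrix, gene and sample
#' identifiers, and a two-level group factor.
#'
#' @param counts integer matrix, genes in rows, samples in columns; all
#'   entries must be non-negative integers.
#' @param group factor (or coercible) of length `ncol(counts)`.
#' @param gene_ids,sample_ids optional identifiers; default to the dimnames
#'   or `gene1..`, `sample1..`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, group, gene_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("'counts' must be a finite numeric matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers")
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- colnames(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(counts)))
  if (length(gene_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("identifier lengths must match the matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  group <- as.factor(group)
  if (length(group) != ncol(counts))
    stop("'group' must have one label per sample")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(counts = counts, group = group,
                 gene_ids = gene_ids, sample_ids = sample_ids),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)", levels(x$group),
                               tabulate(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

.as_counts <- function(x) if (inherits(x, "count_matrix")) x$counts else as.matrix(x)

#' Draw per-gene base mean counts
#'
#' The base means stand in for the medians of a deeply sequenced tumor
#' cohort: a heavy right tail spanning several orders of magnitude. The
#' parametric mode draws from a log-normal with log-mean `meanlog` and
#' log-sd `sdlog`, truncated below at 1 by rejection; the file mode
#' resamples (with replacement) the positive values listed one per line,
#' so users can plug in medians from a real dataset.
#'
#' @param n_genes number of means to draw.
#' @param mean_source `"parametric"` or a path to a file with one positive
#'   mean per line.
#' @param meanlog,sdlog log-scale location and spread of the parametric
#'   log-normal (defaults `log(500)` and 2, a high-depth profile).
#' @param seed optional integer seed.
#' @return numeric vector of `n_genes` strictly positive means.
#' @export
sample_base_means <- function(n_genes, mean_source = "parametric",
                              meanlog = log(500), sdlog = 2, seed = NULL) {
  if (n_genes < 1) stop("'n_genes' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (identical(mean_source, "parametric")) {
    out <- stats::rlnorm(n_genes, meanlog, sdlog)
    # truncate below at 1 by rejection so the tail shape is preserved
    bad <- which(out < 1)
    while (length(bad)) {
      out[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
      bad <- bad[out[bad] < 1]
    }
    return(out)
  }
  if (is.character(mean_source) && length(mean_source) == 1 &&
      file.exists(mean_source)) {
    vals <- suppressWarnings(as.numeric(readLines(mean_source)))
    if (length(vals) < 1) stop("mean file is empty: ", mean_source)
    bad <- which(is.na(vals) | vals <= 0)
    if (length(bad))
      stop("non-positive or unparsable mean at line ", bad[1],
           " of ", mean_source)
    return(sample(vals, n_genes, replace = TRUE))
  }
  stop("unknown 'mean_source': must be \"parametric\" or an existing file path")
}

#' Assign differential expression to a fraction of genes
#'
#' Flags `round(de_fraction * n)` genes as differentially expressed, each
#' receiving a fold change drawn uniformly from `fc_range` and a direction
#' (up or down in the test group) with probability 1/2 each. All other genes
#' keep fold change 1. The result is the ground-truth table consumed by
#' [simulate_counts()].
#'
#' @param base_means positive numeric vector of group-1 (control) means.
#' @param de_fraction fraction of genes to perturb, in \[0, 1\].
#' @param fc_range length-2 numeric, `1 <= low <= high`; a degenerate range
#'   such as `c(2, 2)` gives every DE gene the same fold change.
#' @param dispersion non-negative NB dispersion, scalar or per-gene.
#' @param seed optional integer seed.
#' @return data.frame (`sim_truth`) with columns `gene_id`, `base_mean`,
#'   `dispersion`, `fold_change`, `direction`, `is_de`.
#' @export
inject_de <- function(base_means, de_fraction, fc_range = c(1.3, 4),
                      dispersion = 0, seed = NULL) {
  if (any(base_means <= 0)) stop("'base_means' must be positive")
  if (de_fraction < 0 || de_fraction > 1)
    stop("'de_fraction' must be in [0, 1]")
  if (length(fc_range) != 2 || fc_range[1] < 1 || fc_range[2] < fc_range[1])
    stop("'fc_range' must be c(low, high) with 1 <= low <= high")
  if (any(dispersion < 0)) stop("'dispersion' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(base_means)
  n_de <- round(de_fraction * n)
  truth <- data.frame(
    gene_id = paste0("gene", seq_len(n)),
    base_mean = base_means,
    dispersion = rep_len(dispersion, n),
    fold_change = rep(1, n),
    direction = rep("none", n),
    is_de = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  if (n_de > 0) {
    de <- sample.int(n, n_de)
    truth$fold_change[de] <- stats::runif(n_de, fc_range[1], fc_range[2])
    truth$direction[de] <- ifelse(stats::runif(n_de) < 0.5, "up", "down")
    truth$is_de[de] <- TRUE
  }
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

#' Simulate NB (or Poisson) read counts from a truth table
#'
#' Group 1 samples draw from the base mean; group 2 samples from
#' `base_mean * fold_change` (direction "up") or `base_mean / fold_change`
#' ("down"). Genes with dispersion 0 are Poisson; genes with dispersion
#' `a > 0` are negative binomial with mean `mu` and size `1/a`, i.e.
#' variance `mu + a * mu^2`. Counts are generated at the normalized scale
#' (all true size factors 1) unless `depth_factors` supplies per-sample
#' depth multipliers to exercise the normalization path.
#'
#' @param truth a `sim_truth` table from [inject_de()].
#' @param n_samples_per_group length-2 integer, samples in groups 1 and 2.
#' @param seed optional integer seed.
#' @param depth_factors optional positive per-sample multipliers.
#' @return a [count_matrix()] with groups `"g1"` and `"g2"`.
#' @export
simulate_counts <- function(truth, n_samples_per_group = c(10, 10),
                            seed = NULL, depth_factors = NULL) {
  stopifnot(is.data.frame(truth),
            all(c("base_mean", "dispersion", "fold_change", "direction") %in%
                  names(truth)))
  if (any(truth$dispersion < 0)) stop("negative dispersion in truth table")
  n1 <- n_samples_per_group[1]; n2 <- n_samples_per_group[2]
  if (n1 < 1 || n2 < 1) stop("each group needs at least one sample")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  mu1 <- truth$base_mean
  mu2 <- ifelse(truth$direction == "up", mu1 * truth$fold_change,
                ifelse(truth$direction == "down", mu1 / truth$fold_change, mu1))
  mu <- cbind(matrix(rep(mu1, n1), n, n1), matrix(rep(mu2, n2), n, n2))
  if (!is.null(depth_factors)) {
    if (length(depth_factors) != n1 + n2 || any(depth_factors <= 0))
      stop("'depth_factors' must be positive, one per sample")
    mu <- sweep(mu, 2, depth_factors, "*")
  }
  disp <- rep_len(truth$dispersion, n)
  x <- matrix(0, n, n1 + n2)
  pois <- disp == 0
  if (any(pois))
    x[pois, ] <- stats::rpois(sum(pois) * (n1 + n2), mu[pois, ])
  if (any(!pois))
    x[!pois, ] <- stats::rnbinom(sum(!pois) * (n1 + n2),
                                 size = 1 / disp[!pois], mu = mu[!pois, ])
  count_matrix(x, group = factor(rep(c("g1", "g2"), c(n1, n2))),
               gene_ids = truth$gene_id,
               sample_ids = paste0(rep(c("g1_s", "g2_s"), c(n1, n2)),
                                   c(seq_len(n1), seq_len(n2))))
}

#' Binomially down-sample a count matrix
#'
#' Emulates a shallower sequencing run: each count `X` is replaced by a
#' `Binomial(X, fraction)` draw, so per-sample totals scale in expectation
#' by `fraction` and Poisson marginals stay Poisson (thinning closure).
#' A per-sample vector of fractions equalizes depths to a target sample.
#'
#' @param x a [count_matrix()] or integer matrix.
#' @param fraction retention probability in \[0, 1\], scalar or per-sample.
#' @param seed optional integer seed.
#' @return object of the same type as `x`.
#' @export
downsample <- function(x, fraction, seed = NULL) {
  counts <- .as_counts(x)
  if (any(fraction < 0) || any(fraction > 1))
    stop("'fraction' must be in [0, 1]")
  if (!(length(fraction) %in% c(1L, ncol(counts))))
    stop("'fraction' must be a scalar or one value per sample")
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(rep(rep_len(fraction, ncol(counts)), each = nrow(counts)),
              nrow(counts))
  thin <- matrix(stats::rbinom(length(counts), size = counts, prob = p),
                 nrow(counts), dimnames = dimnames(counts))
  storage.mode(thin) <- "double"
  if (inherits(x, "count_matrix")) {
    x$counts <- thin
    x
  } else thin
}

#' Partition genes into disjoint gene-sets
#'
#' Randomly partitions the gene universe into `n_sets` disjoint sets whose
#' sizes differ by at most one — the null gene-set collection used for the
#' GSEA false-positive experiment, in which no set can be genuinely
#' enriched.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_sets number of sets, at most `length(gene_ids)`.
#' @param seed optional integer seed.
#' @return named list of character vectors (`set001`, `set002`, ...).
#' @export
make_gene_sets <- function(gene_ids, n_sets, seed = NULL) {
  n <- length(gene_ids)
  if (n_sets < 1 || n_sets > n)
    stop("'n_sets' must be between 1 and the number of genes")
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(gene_ids)
  sizes <- rep(n %/% n_sets, n_sets)
  extra <- n %% n_sets
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  idx <- rep(seq_len(n_sets), sizes)
  sets <- split(shuffled, idx)
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  sets
}
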