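# Weighted Kolmogorov-Smirnov gene-set enrichment with two null models:
# sample permutation (group labels reshuffled, gene scores recomputed) and
# preranked / gene permutation (gene labels reshuffled against a fixed
# ranking). NES, nominal p and FDR q follow the canonical sign-stratified
# pooled-null procedure.

# ES from the sorted rank positions of a set's members. 'w_at_pos' holds
# |score|^p at those positions; misses decrement by 1/(N - m). The running
# sum peaks just after a hit and troughs just before one, so only those 2m
# candidates are inspected.
.es_from_pos <- function(pos, w_at_pos, N) {
  m <- length(pos)
  W <- sum(w_at_pos)
  cumw <- if (W > 0) cumsum(w_at_pos) / W else seq_len(m) / m
  miss <- (pos - seq_len(m)) / (N - m)
  peak <- cumw - miss
  trough <- c(0, cumw[-m]) - miss
  max_es <- max(peak)
  min_es <- min(trough)
  if (max_es > -min_es) max_es else min_es
}

# ranked universe bookkeeping: scores named by gene, NA dropped, ranked
# descending with ties broken by gene identifier
.rank_universe <- function(scores) {
  if (is.data.frame(scores)) {
    col <- if ("snr" %in% names(scores)) "snr" else names(scores)[2]
    s <- scores[[col]]
    names(s) <- scores$gene_id
    scores <- s
  }
  if (is.null(names(scores))) stop("scores must be named by gene")
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no genes with defined scores")
  ord <- order(-scores, names(scores), method = "radix")
  scores[ord]
}

#' Weighted KS enrichment score of one gene-set
#'
#' Walks the ranked gene list; member genes ("hits") advance the running
#' sum by `|score|^weight_exponent` normalized to the set total, non-members
#' retreat it by `1/(N - m)`. The ES is the running-sum value of maximal
#' absolute deviation from zero (signed). `weight_exponent = 0` recovers the
#' classical unweighted KS statistic.
#'
#' @param scores named numeric vector of gene scores (any order; ranked
#'   descending internally, ties broken by gene identifier), or a
#'   data.frame with `gene_id` and `snr`.
#' @param set character vector of member genes; must be a non-empty strict
#'   subset of the scored genes.
#' @param weight_exponent hit-weight exponent, default 1.
#' @return ES in \[-1, 1\].
#' @export
enrichment_score <- function(scores, set, weight_exponent = 1) {
  ranked <- .rank_universe(scores)
  N <- length(ranked)
  hit <- names(ranked) %in% set
  m <- sum(hit)
  if (m == 0) stop("'set' shares no genes with the scored universe")
  if (m == N) stop("'set' equals the whole universe")
  pos <- which(hit)
  .es_from_pos(pos, abs(ranked[pos])^weight_exponent, N)
}

# sign-stratified NES / nominal p / pooled-null FDR q
.gsea_summarize <- function(es, null_es) {
  n_sets <- length(es)
  nes <- rep(NA_real_, n_sets)
  p <- rep(NA_real_, n_sets)
  null_nes <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    ni <- null_es[i, ]
    pos <- ni[ni >= 0]; neg <- ni[ni < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    nn <- c(if (length(pos) && !is.na(mpos) && mpos > 0) pos / mpos,
            if (length(neg) && !is.na(mneg) && mneg > 0) neg / mneg)
    null_nes[[i]] <- nn
    if (es[i] >= 0) {
      if (!is.na(mpos) && mpos > 0) {
        nes[i] <- es[i] / mpos
        p[i] <- mean(pos >= es[i])
      } else p[i] <- 1
    } else {
      if (!is.na(mneg) && mneg > 0) {
        nes[i] <- es[i] / mneg
        p[i] <- mean(neg <= es[i])
      } else p[i] <- 1
    }
  }
  pool <- unlist(null_nes)
  pool_pos <- pool[pool >= 0]; pool_neg <- pool[pool < 0]
  obs_pos <- nes[!is.na(nes) & nes >= 0]; obs_neg <- nes[!is.na(nes) & nes < 0]
  q <- rep(NA_real_, n_sets)
  for (i in seq_len(n_sets)) {
    if (is.na(nes[i])) { q[i] <- 1; next }
    if (nes[i] >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= nes[i]) else 0
      den <- mean(obs_pos >= nes[i])
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= nes[i]) else 0
      den <- mean(obs_neg <= nes[i])
    }
    q[i] <- min(1, num / den)
  }
  list(nes = nes, p = p, q = q)
}

# trim sets to the universe; drop emptied sets (warning) and full-universe
# sets (error); returns integer member indices into 'universe'
.prepare_sets <- function(sets, universe) {
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  idx <- lapply(sets, function(s) sort.int(match(unique(s), universe)))
  idx <- lapply(idx, function(i) i[!is.na(i)])
  empty <- lengths(idx) == 0
  if (any(empty)) {
    warning(sum(empty), " set(s) had no genes in the scored universe; skipped")
    idx <- idx[!empty]
  }
  if (!length(idx)) stop("no usable gene-sets")
  if (any(lengths(idx) == length(universe)))
    stop("a set equals the whole scored universe")
  idx
}

# ES of every set against a ranking given as 'rankpos' (gene index ->
# rank), weights 'w' indexed by rank
.es_all_sets <- function(set_idx, rankpos, w, N) {
  vapply(set_idx, function(members) {
    pos <- sort.int(rankpos[members])
    .es_from_pos(pos, w[pos], N)
  }, numeric(1))
}

.gsea_result <- function(set_names, sizes, es, summ) {
  data.frame(set_name = set_names, size = sizes, es = es,
             nes = summ$nes, p_nominal = summ$p, fdr_q = summ$q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Preranked (gene-permuting) GSEA
#'
#' Tests gene-sets against a fixed ranked gene list. The null distribution
#' of each set's ES comes from `n_perm` random permutations of the gene
#' labels, i.e. random sets of matching size; the observed ranking is never
#' recomputed. Because only ranks (and score magnitudes) enter, this null
#' is immune to the read count bias: a gene's large score inflates random
#' sets exactly as often as real ones.
#'
#' @param gene_scores named numeric score vector (or data.frame with
#'   `gene_id` and `snr`); `NA` scores are dropped from the universe.
#' @param sets named list of character vectors.
#' @param n_perm number of gene-label permutations, default 1000.
#' @param seed optional integer seed.
#' @param weight_exponent hit-weight exponent, default 1.
#' @return data.frame with `set_name`, `size`, `es`, `nes`, `p_nominal`,
#'   `fdr_q`.
#' @export
preranked_gsea <- function(gene_scores, sets, n_perm = 1000, seed = NULL,
                           weight_exponent = 1) {
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  ranked <- .rank_universe(gene_scores)
  N <- length(ranked)
  universe <- names(ranked)
  set_idx <- .prepare_sets(sets, universe)
  w <- abs(ranked)^weight_exponent
  ident <- seq_len(N)
  es <- .es_all_sets(set_idx, ident, w, N)
  if (!is.null(seed)) set.seed(seed)
  null_es <- matrix(NA_real_, length(set_idx), n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(N)                 # permuted gene labels
    null_es[, b] <- .es_all_sets(set_idx, perm, w, N)
  }
  summ <- .gsea_summarize(es, null_es)
  .gsea_result(names(set_idx), lengths(set_idx), es, summ)
}

# SNR for all genes from a matrix and its squared copy, given group index
# vectors; NA where both sds vanish
.snr_cols <- function(m, m2, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  a1 <- numeric(ncol(m)); a1[idx1] <- 1
  a2 <- numeric(ncol(m)); a2[idx2] <- 1
  s1 <- m %*% a1; s2 <- m %*% a2
  ss1 <- m2 %*% a1; ss2 <- m2 %*% a2
  mean1 <- s1 / n1; mean2 <- s2 / n2
  sd1 <- sqrt(pmax(ss1 - n1 * mean1^2, 0) / (n1 - 1))
  sd2 <- sqrt(pmax(ss2 - n2 * mean2^2, 0) / (n2 - 1))
  denom <- sd1 + sd2
  ifelse(denom > 0, (mean1 - mean2) / denom, NA_real_)[, 1]
}

#' Sample-permuting GSEA with the SNR gene score
#'
#' The conventional two-group GSEA: genes are ranked by SNR on normalized
#' counts, and the null ES of each set comes from `n_perm` random
#' relabelings of the sample group labels (group sizes preserved), with the
#' SNR recomputed for every relabeling. Genes whose SNR is undefined under
#' the observed labels are dropped from the universe. If fewer distinct
#' relabelings exist than `n_perm`, all distinct ones are used with a
#' warning.
#'
#' @param x normalized count matrix (genes x samples) or [count_matrix()]
#'   at the normalized scale.
#' @param group two-level sample annotation.
#' @param sets named list of character vectors.
#' @param n_perm number of label permutations, default 1000.
#' @param seed optional integer seed.
#' @param weight_exponent hit-weight exponent, default 1.
#' @return data.frame as in [preranked_gsea()].
#' @export
sample_permute_gsea <- function(x, group = NULL, sets, n_perm = 1000,
                                seed = NULL, weight_exponent = 1) {
  if (n_perm < 100) stop("'n_perm' must be >= 100")
  rg <- .resolve_matrix_group(x, group)
  g <- .two_groups(rg$group)
  m <- rg$m
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  lev <- levels(g)
  idx1 <- which(g == lev[1]); idx2 <- which(g == lev[2])
  m2 <- m * m
  snr_obs <- .snr_cols(m, m2, idx1, idx2)
  keep <- !is.na(snr_obs)
  m <- m[keep, , drop = FALSE]; m2 <- m2[keep, , drop = FALSE]
  snr_obs <- snr_obs[keep]
  # fix the universe in gene-identifier order so ranking ties are stable
  uord <- order(rownames(m), method = "radix")
  m <- m[uord, , drop = FALSE]; m2 <- m2[uord, , drop = FALSE]
  snr_obs <- snr_obs[uord]
  universe <- rownames(m)
  N <- length(universe)
  set_idx <- .prepare_sets(sets, universe)
  rank_of <- function(snr) {
    ord <- order(-snr, seq_along(snr), method = "radix")
    rp <- integer(N); rp[ord] <- seq_len(N)
    list(rp = rp, w_ranked = abs(snr[ord])^weight_exponent)
  }
  robs <- rank_of(snr_obs)
  es <- .es_all_sets(set_idx, robs$rp, robs$w_ranked, N)
  n <- ncol(m)
  n_distinct <- choose(n, length(idx1))
  if (!is.null(seed)) set.seed(seed)
  if (n_distinct < n_perm) {
    warning("only ", n_distinct, " distinct relabelings exist; using all")
    combs <- utils::combn(n, length(idx1))
    perms <- lapply(seq_len(ncol(combs)), function(j) combs[, j])
  } else {
    perms <- lapply(seq_len(n_perm), function(b) sample.int(n, length(idx1)))
  }
  null_es <- matrix(NA_real_, length(set_idx), length(perms))
  all_idx <- seq_len(n)
  for (b in seq_along(perms)) {
    p1 <- perms[[b]]
    snr_b <- .snr_cols(m, m2, p1, setdiff(all_idx, p1))
    snr_b[is.na(snr_b)] <- 0          # constant gene under this relabeling
    rb <- rank_of(snr_b)
    null_es[, b] <- .es_all_sets(set_idx, rb$rp, rb$w_ranked, N)
  }
  summ <- .gsea_summarize(es, null_es)
  .gsea_result(names(set_idx), lengths(set_idx), es, summ)
}

#' False-positive experiment over a dispersion grid
#'
#' The end-to-end null experiment: simulate counts for `n_genes` genes with
#' a fraction of randomly scattered DE genes (so no gene-set is genuinely
#' enriched), normalize, score, partition the genes into `n_sets` disjoint
#' random sets, run GSEA in the requested mode, and count sets reaching
#' `fdr_q < fdr_threshold`. Every significant set is by construction a
#' false positive. Repeats use seeds `seed + repeat_index` so cells are
#' reproducible and repeats independent.
#'
#' @param dispersions numeric vector of NB dispersions.
#' @param de_fractions numeric vector of DE-gene fractions.
#' @param modes subset of `c("sample", "preranked")`.
#' @param n_repeats repeats per cell, default 10.
#' @param fdr_threshold significance cutoff on `fdr_q`, default 0.05.
#' @param seed root seed.
#' @param n_genes,n_per_group,n_sets,fc_range,n_perm experiment dimensions:
#'   defaults 10000 genes, 10+10 samples, 100 disjoint sets, 2-fold DE,
#'   1000 permutations.
#' @return data.frame with one row per (dispersion, de_fraction, mode):
#'   mean and SD over repeats of the significant-set count.
#' @export
false_positive_experiment <- function(dispersions, de_fractions,
                                      modes = c("sample", "preranked"),
                                      n_repeats = 10, fdr_threshold = 0.05,
                                      seed = 1, n_genes = 10000,
                                      n_per_group = c(10, 10), n_sets = 100,
                                      fc_range = c(2, 2), n_perm = 1000) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (n_repeats < 1) stop("'n_repeats' must be >= 1")
  grid <- expand.grid(dispersion = dispersions, de_fraction = de_fractions,
                      mode = modes, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    counts <- vapply(seq_len(n_repeats), function(r) {
      s <- seed + r
      bm <- sample_base_means(n_genes, seed = s)
      truth <- inject_de(bm, grid$de_fraction[i], fc_range,
                         dispersion = grid$dispersion[i])
      cm <- simulate_counts(truth, n_per_group)
      norm <- normalize_counts(cm, size_factors(cm))
      sets <- make_gene_sets(truth$gene_id, n_sets)
      res <- if (grid$mode[i] == "sample") {
        sample_permute_gsea(norm, cm$group, sets, n_perm = n_perm)
      } else {
        sc <- snr_scores(norm, cm$group)
        preranked_gsea(sc, sets, n_perm = n_perm)
      }
      sum(res$fdr_q < fdr_threshold, na.rm = TRUE)
    }, numeric(1))
    data.frame(dispersion = grid$dispersion[i],
               de_fraction = grid$de_fraction[i], mode = grid$mode[i],
               mean_significant = mean(counts),
               sd_significant = stats::sd(counts),
               n_repeats = n_repeats, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
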