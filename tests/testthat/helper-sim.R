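# Small in-code fixtures shared across test files.

# a modest simulated two-group dataset at a given dispersion
sim_fixture <- function(n_genes = 2000, n_per_group = c(7, 7),
                        dispersion = 0.1, de_fraction = 0.3,
                        fc_range = c(1.3, 4), seed = 42,
                        meanlog = log(500), sdlog = 2) {
  bm <- sample_base_means(n_genes, meanlog = meanlog, sdlog = sdlog,
                          seed = seed)
  truth <- inject_de(bm, de_fraction, fc_range, dispersion = dispersion)
  cm <- simulate_counts(truth, n_per_group)
  list(truth = truth, cm = cm)
}

# brute-force weighted-KS running sum over the full ranked list; the
# independent oracle for enrichment_score
es_bruteforce <- function(scores, set, p = 1) {
  ord <- order(-scores, names(scores), method = "radix")
  s <- scores[ord]
  hit <- names(s) %in% set
  w <- abs(s)^p
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (length(s) - sum(hit)))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}
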