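# Small shared fixtures, all generated in code.

tiny_dataset <- function(n = 30L, b = 3L, effect = 5,
                         split = "redundant", seed = 7L) {
  simulate_multiomics(synthetic_spec(
    n_samples = n, n_classes = b,
    n_features = c(omA = 12L, omB = 9L, omC = 7L),
    informative_fraction = 0.25, effect_size = effect,
    information_split = split, seed = seed
  ))
}

fast_config <- function(...) {
  defaults <- list(k_neighbors = 5L, hidden_dims = c(8L, 6L), epochs = 60L)
  do.call(run_config, modifyList(defaults, list(...)))
}

random_opinion <- function(n, b) {
  # valid opinion via random non-negative evidence
  opinion_from_evidence(matrix(rexp(n * b), n, b))
}

write_omics_csv <- function(ids, mat, path, feature_prefix = "f") {
  df <- data.frame(sample_id = ids)
  colnames(mat) <- paste0(feature_prefix, seq_len(ncol(mat)))
  write.csv(cbind(df, as.data.frame(mat)), path, row.names = FALSE)
  path
}
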