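# Shared fixtures, built in code.

# Perfect stem: `n_pairs` pairs around a loop of `loop` nt.
perfect_stem <- function(n_pairs = 10, loop = 6, id = "stem") {
  arm5 <- strsplit(strrep("GCAU", ceiling(n_pairs / 4)), "")[[1]][seq_len(n_pairs)]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seq <- paste(c(arm5, rep("A", loop), rev(comp[arm5])), collapse = "")
  db <- paste0(strrep("(", n_pairs), strrep(".", loop), strrep(")", n_pairs))
  hairpin(id, seq, db)
}

# A window built directly from token vectors (both rows), for encoder tests.
toy_window <- function(arm, opp = arm, label = "unlabeled", width = length(arm)) {
  dicerscan:::new_pattern_window("toy", "5p", width, arm, opp, NA_integer_, label)
}

# Tiny trained model on synthetic data; memoised per test file.
fit_toy_model <- function(n = 40, seed = 5, scheme = "extbinary_struct") {
  spec <- synthetic_spec(n_hairpins = n, seed = seed)
  ds <- make_dataset(spec)
  ts <- build_training_set(ds$hairpins, ds$annotations, scheme = scheme)
  model <- dicer_svm(ts$x, ts$y, ids = ts$ids, families = ds$families,
                     grid = dicer_grid(g = 0.01, cost = 1, j = 1),
                     seed = seed, scheme = scheme, width = 14)
  list(model = model, data = ds, train = ts, spec = spec)
}
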