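# Shared fixtures, built in code at test time.

# a deterministic little protein with all annotations
toy_protein <- function(L = 10L, id = "toy", seed = 7L, labels = NULL) {
  set.seed(seed)
  protein_record(
    id = id,
    sequence = paste(sample(c("A", "C", "D", "E", "G"), L, TRUE), collapse = ""),
    pssm = matrix(round(rnorm(L * 20), 3), L, 20),
    pss = paste(sample(c("H", "E", "C"), L, TRUE), collapse = ""),
    shape = paste(sample(c("S", "R", "U", "V", "K", "A", "T", "G", "N"),
                         L, TRUE), collapse = ""),
    labels = if (is.null(labels)) rbinom(L, 1, 0.25) else labels)
}

# featureless dummy chains, enough for fold-assignment tests
dummy_protein <- function(id, L = 4L, n_pos = 1L) {
  protein_record(id = id, sequence = strrep("A", L),
                 pssm = matrix(0, L, 20), pss = strrep("C", L),
                 labels = c(rep(1L, n_pos), rep(0L, L - n_pos)))
}

# one small trained pipeline, built once and reused across test files
.fixture_cache <- new.env(parent = emptyenv())

small_pipeline <- function() {
  if (!is.null(.fixture_cache$pipe)) return(.fixture_cache$pipe)
  tr <- simulate_dataset(synthetic_config(n_proteins = 12,
                                          length_range = c(30L, 50L),
                                          seed = 11))
  te <- simulate_dataset(synthetic_config(n_proteins = 6,
                                          length_range = c(30L, 50L),
                                          seed = 12))
  cfg <- hsvmlr_config(grid = svm_grid(cost = 1, gamma = 2^-7),
                       inner_folds = 3, seed = 5)
  model <- suppressWarnings(hsvmlr_train(tr, cfg))
  .fixture_cache$pipe <- list(train = tr, test = te, config = cfg,
                              model = model)
  .fixture_cache$pipe
}
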