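# Shared small fixtures, built in code.

tiny_config <- function(seed = 3L, ...) {
  sim_config(seed = seed, n_mirna = 20L, n_contaminant_loci = 5L,
             genome_length = 20000L, mean_depth = 80, ...)
}

# cache the tiny bundle across tests in one session
.fixture_env <- new.env(parent = emptyenv())
tiny_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- generate_reference(tiny_config())
  }
  .fixture_env$bundle
}

# a bundle whose truth table is overridden (for count-moment checks)
truth_only_bundle <- function(n, base_mean, log2fc = 0, dispersion = 0) {
  cfg <- tiny_config()
  cfg$dispersion <- dispersion
  b <- tiny_bundle()
  b$truth <- data.frame(
    feature_id = sprintf("f%05d", seq_len(n)), class = "miRNA",
    base_mean = base_mean, true_log2FC = log2fc, stringsAsFactors = FALSE
  )
  b$config <- cfg
  b
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
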