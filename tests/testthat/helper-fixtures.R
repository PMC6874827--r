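# Shared fixtures: a desk-scale configuration small enough to keep the unit
# suite fast, plus one bundle reused across test files.

small_cfg <- function(seed = 7, ...) {
  defaults <- list(seed = seed,
                   chromosome_length = 3e5,
                   n_genes = 30,
                   array_copy_numbers = c(centromere = 100L, telomere = 10L),
                   n_markers_per_lg = 40,
                   n_sites = 800,
                   n_gene_pairs = 100)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

SMALL_BUNDLE <- simulate_truth_set(small_cfg())

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
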