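# Small simulated study shared across test files (built once per run).
tiny_cfg <- function(seed = 101,
                     traits = default_traits()[c("yield", "potential_yield")]) {
  sim_config(
    n_females = 5, n_cms = 4, n_males = 36, n_donor_families = 4,
    n_sites = 400,
    crossing = crossing_config(4, 36, 100, female_count_dist = NULL),
    traits = traits, seed = seed
  )
}

.study_cache <- new.env(parent = emptyenv())
tiny_study <- function() {
  if (is.null(.study_cache$st))
    .study_cache$st <- suppressMessages(simulate_study(tiny_cfg()))
  .study_cache$st
}

# marker_matrix from a plain dosage matrix with auto ids
mm_of <- function(d) {
  if (is.null(rownames(d))) rownames(d) <- paste0("i", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- paste0("s", seq_len(ncol(d)))
  marker_matrix(d)
}
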