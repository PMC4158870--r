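# Small event-table builders used across the suite.

# sets: named list patient_id -> character vector of AE terms (count 1 each)
events_from_sets <- function(sets, counts = NULL) {
  rows <- lapply(names(sets), function(p) {
    terms <- sets[[p]]
    cnt <- if (is.null(counts)) rep(1L, length(terms)) else counts[[p]]
    tibble::tibble(patient_id = p, term = terms, term_type = "AE",
                   count = as.integer(cnt))
  })
  do.call(rbind, rows)
}

small_cluster_config <- function(seed = 1L, ...) {
  cohort_config(n_patients = 80, n_aes = 300, n_clusters = 3,
                cluster_sizes = c(30, 20, 15), n_drugs = 0, n_diagnoses = 0,
                seed = seed, ...)
}
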