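#' Configure a synthetic EMR adverse-event cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' emulate the corpus shape of a mental-health-center EMR study population:
#' roughly 2350 patients with at least one adverse event (AE), ~1190 unique
#' AE terms, a heavy-tailed AE prevalence distribution in which close to half
#' of all AEs affect a single patient, a mean burden of ~5.2 distinct AEs per
#' patient (maximum 48, with roughly a fifth of patients carrying exactly one
#' AE), and a small number of planted patient clusters each dominated by one
#' distinguishing AE.
#'
#' @param n_patients Number of patients (every patient gets at least one AE).
#' @param n_aes Size of the AE vocabulary.
#' @param n_clusters Number of planted patient clusters (0 for none).
#' @param cluster_sizes Integer vector of length `n_clusters`; sums to at most
#'   `n_patients`. Remaining patients are unclustered background.
#' @param dominant_ae_weight Probability that an AE event drawn for a cluster
#'   member is the cluster's distinguishing AE.
#' @param secondary_ae_weight Probability for the cluster's second AE.
#' @param prevalence_tail_exponent Zipf exponent shaping background AE
#'   popularity; larger values concentrate events on fewer AEs and fatten the
#'   singleton tail.
#' @param burden_mean Target mean number of distinct AEs per patient (after
#'   zero truncation); must exceed 1.
#' @param burden_max Hard cap on distinct AEs per patient.
#' @param burden_dispersion Negative-binomial size (dispersion) parameter of
#'   the per-patient burden; small values give the long tail seen in real
#'   burden distributions.
#' @param count_mean Mean number of occurrences (the term frequency `f`) of an
#'   AE term within a patient record; occurrences are 1 + geometric.
#' @param planted_pairs List of planted correlated AE pairs; each element is a
#'   numeric triple `(ae_i, ae_j, joint_boost)` of two distinct AE indices and
#'   the probability that a latent "syndrome" adds both AEs to a patient.
#' @param n_drugs,n_diagnoses Vocabulary sizes for drug and diagnosis records
#'   (0 to omit them).
#' @param seed Integer seed; all randomness in [generate_cohort()] flows from
#'   it.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [cohort_summary()]
#' @export
cohort_config <- function(n_patients = 2347,
                          n_aes = 1190,
                          n_clusters = 3,
                          cluster_sizes = NULL,
                          dominant_ae_weight = 0.6,
                          secondary_ae_weight = 0.1,
                          prevalence_tail_exponent = 1.45,
                          burden_mean = 5.2,
                          burden_max = 48L,
                          burden_dispersion = 0.55,
                          count_mean = 1.6,
                          planted_pairs = list(),
                          n_drugs = 25L,
                          n_diagnoses = 20L,
                          seed = 1L) {
  if (is.null(cluster_sizes)) {
    cluster_sizes <- if (n_clusters == 0L) {
      integer(0)
    } else if (n_clusters == 3L) {
      c(120L, 80L, 50L)  # mirrors the size range of the large real clusters
    } else {
      stop("`cluster_sizes` must be given explicitly when n_clusters is not 0 or 3",
           call. = FALSE)
    }
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_aes = as.integer(n_aes),
    n_clusters = as.integer(n_clusters),
    cluster_sizes = as.integer(cluster_sizes),
    dominant_ae_weight = dominant_ae_weight,
    secondary_ae_weight = secondary_ae_weight,
    prevalence_tail_exponent = prevalence_tail_exponent,
    burden_mean = burden_mean,
    burden_max = as.integer(burden_max),
    burden_dispersion = burden_dispersion,
    count_mean = count_mean,
    planted_pairs = normalize_planted_pairs(planted_pairs),
    n_drugs = as.integer(n_drugs),
    n_diagnoses = as.integer(n_diagnoses),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

normalize_planted_pairs <- function(planted_pairs) {
  if (is.data.frame(planted_pairs)) {
    planted_pairs <- lapply(seq_len(nrow(planted_pairs)),
                            function(i) unlist(planted_pairs[i, 1:3]))
  }
  if (length(planted_pairs) == 0L) {
    return(tibble(ae_i = integer(), ae_j = integer(), joint_boost = numeric()))
  }
  tibble(
    ae_i = vapply(planted_pairs, function(p) as.integer(p[[1]]), integer(1)),
    ae_j = vapply(planted_pairs, function(p) as.integer(p[[2]]), integer(1)),
    joint_boost = vapply(planted_pairs, function(p) as.numeric(p[[3]]), numeric(1))
  )
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort_config field `%s`: %s", field, why), call. = FALSE)
  }
  if (cfg$n_patients < 1L) bad("n_patients", "must be a positive integer")
  if (cfg$n_aes < 1L) bad("n_aes", "must be a positive integer")
  if (cfg$n_clusters < 0L) bad("n_clusters", "must be non-negative")
  if (length(cfg$cluster_sizes) != cfg$n_clusters) {
    bad("cluster_sizes", sprintf("length %d does not match n_clusters = %d",
                                 length(cfg$cluster_sizes), cfg$n_clusters))
  }
  if (cfg$n_clusters > 0L) {
    if (any(cfg$cluster_sizes < 1L)) bad("cluster_sizes", "entries must be >= 1")
    if (sum(cfg$cluster_sizes) > cfg$n_patients) {
      bad("cluster_sizes", "sum exceeds n_patients")
    }
    # each cluster needs a distinct dominant and a distinct secondary AE
    if (cfg$n_aes < 2L * cfg$n_clusters) {
      bad("n_aes", "need at least 2 * n_clusters AEs for distinct dominant/secondary AEs")
    }
  }
  if (!(cfg$dominant_ae_weight > 0 && cfg$dominant_ae_weight < 1)) {
    bad("dominant_ae_weight", "must lie in (0, 1)")
  }
  if (!(cfg$secondary_ae_weight >= 0 && cfg$secondary_ae_weight < 1)) {
    bad("secondary_ae_weight", "must lie in [0, 1)")
  }
  if (cfg$dominant_ae_weight + cfg$secondary_ae_weight >= 1) {
    bad("secondary_ae_weight", "dominant + secondary weight must be < 1")
  }
  if (cfg$prevalence_tail_exponent <= 0) {
    bad("prevalence_tail_exponent", "must be positive")
  }
  if (cfg$burden_mean <= 1) bad("burden_mean", "must exceed 1 (burden is zero-truncated)")
  if (cfg$burden_max < 1L) bad("burden_max", "must be a positive integer")
  if (cfg$burden_dispersion <= 0) bad("burden_dispersion", "must be positive")
  if (cfg$count_mean < 1) bad("count_mean", "must be >= 1")
  pp <- cfg$planted_pairs
  if (nrow(pp) > 0L) {
    if (any(pp$ae_i == pp$ae_j)) bad("planted_pairs", "ae_i must differ from ae_j")
    if (any(c(pp$ae_i, pp$ae_j) < 1L) || any(c(pp$ae_i, pp$ae_j) > cfg$n_aes)) {
      bad("planted_pairs", "AE indices must lie in [1, n_aes]")
    }
    if (any(pp$joint_boost < 0 | pp$joint_boost >= 1)) {
      bad("planted_pairs", "joint_boost must lie in [0, 1)")
    }
  }
  if (cfg$n_drugs < 0L) bad("n_drugs", "must be non-negative")
  if (cfg$n_diagnoses < 0L) bad("n_diagnoses", "must be non-negative")
  invisible(cfg)
}

# mean of the raw negative binomial whose zero-truncated mean equals `target`
solve_ztnb_mu <- function(target, size) {
  f <- function(mu) mu / (1 - dnbinom(0L, size = size, mu = mu)) - target
  uniroot(f, c(1e-9, target), tol = 1e-10)$root
}

# zero-truncated negative binomial draws, capped at `max`
rztnb <- function(n, mu, size, max) {
  x <- rnbinom(n, size = size, mu = mu)
  while (any(z <- x == 0L)) {
    x[z] <- rnbinom(sum(z), size = size, mu = mu)
  }
  pmin(x, max)
}

#' Generate a synthetic adverse-event cohort
#'
#' Draws a long-format event table (patient, term, term type, count) with the
#' statistical structure described in [cohort_config()]: a heavy-tailed (Zipf)
#' background AE popularity, overdispersed per-patient AE burden
#' (zero-truncated negative binomial capped at `burden_max`), planted patient
#' clusters whose event stream is a mixture of the cluster's dominant AE,
#' secondary AE and background draws, and planted correlated AE pairs added by
#' a latent per-patient syndrome indicator. Per-present-AE occurrence counts
#' are 1 + geometric so term frequencies vary across patients. Drug and
#' diagnosis records are attached per patient when `n_drugs`/`n_diagnoses`
#' are positive, with 1-2 characteristic codes per cluster.
#'
#' The generator is fully deterministic for a fixed config (including its
#' `seed`).
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with columns `patient_id`, `term`, `term_type`
#'   (`"AE"`, `"drug"` or `"diagnosis"`) and `count`, one row per distinct
#'   (patient, term, type). Ground truth is attached as the `"planted"`
#'   attribute: a list with `clusters` (patient/cluster tibble),
#'   `dominant_aes`, `secondary_aes`, `pairs`, and the full `ae_terms`,
#'   `drug_terms`, `diagnosis_terms` vocabularies.
#' @examples
#' ev <- generate_cohort(cohort_config(n_patients = 50, n_aes = 40,
#'                                     n_clusters = 0, cluster_sizes = integer(),
#'                                     n_drugs = 0, n_diagnoses = 0, seed = 7))
#' cohort_summary(ev)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config object", call. = FALSE)
  }
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  V <- cfg$n_aes
  ae_terms <- sprintf("ae_%04d", seq_len(V))
  patient_ids <- sprintf("P%05d", seq_len(n))

  zipf <- seq_len(V)^(-cfg$prevalence_tail_exponent)
  zipf <- zipf / sum(zipf)

  # cluster membership: first blocks of patients; ids are opaque anyway
  n_members <- if (cfg$n_clusters > 0L) sum(cfg$cluster_sizes) else 0L
  member_cluster <- rep(NA_integer_, n)
  if (cfg$n_clusters > 0L) {
    member_cluster[seq_len(n_members)] <- rep(seq_len(cfg$n_clusters), cfg$cluster_sizes)
  }

  # distinguishing AEs sit just below the 10 most popular background ranks:
  # prevalent enough to mirror real distinguishing AEs, but with non-vanishing idf
  offset <- min(10L, max(0L, V - 2L * cfg$n_clusters))
  dom_idx <- offset + seq_len(cfg$n_clusters)
  sec_idx <- offset + cfg$n_clusters + seq_len(cfg$n_clusters)

  mu <- solve_ztnb_mu(cfg$burden_mean, cfg$burden_dispersion)
  burden <- rztnb(n, mu, cfg$burden_dispersion, cfg$burden_max)
  p_geom <- 1 / cfg$count_mean

  # latent syndrome indicators for planted pairs, drawn up-front per patient
  pp <- cfg$planted_pairs
  extra <- vector("list", n)
  if (nrow(pp) > 0L) {
    for (r in seq_len(nrow(pp))) {
      hit <- which(runif(n) < pp$joint_boost[r])
      for (p in hit) extra[[p]] <- c(extra[[p]], pp$ae_i[r], pp$ae_j[r])
    }
  }

  d <- cfg$dominant_ae_weight
  s <- cfg$secondary_ae_weight
  idx_list <- vector("list", n)
  cnt_list <- vector("list", n)
  for (p in seq_len(n)) {
    cl <- member_cluster[p]
    if (is.na(cl)) {
      idx <- sample.int(V, burden[p], prob = zipf)
      cnt <- 1L + rgeom(burden[p], p_geom)
    } else {
      # event-level mixture: each occurrence is the dominant AE w.p. d,
      # the secondary AE w.p. s, otherwise a background draw
      n_ev <- max(burden[p], as.integer(round(burden[p] * cfg$count_mean)))
      u <- runif(n_ev)
      n_bg <- sum(u >= d + s)
      ev <- c(rep.int(dom_idx[cl], sum(u < d)),
              rep.int(sec_idx[cl], sum(u >= d & u < d + s)),
              if (n_bg > 0L) sample.int(V, n_bg, prob = zipf, replace = TRUE))
      tab <- tabulate(ev, nbins = V)
      idx <- which(tab > 0L)
      cnt <- tab[idx]
    }
    if (!is.null(extra[[p]])) {
      add <- unique(extra[[p]])
      more <- 1L + rgeom(length(add), p_geom)
      both <- match(add, idx)
      new <- is.na(both)
      cnt[both[!new]] <- cnt[both[!new]] + more[!new]
      idx <- c(idx, add[new])
      cnt <- c(cnt, more[new])
    }
    idx_list[[p]] <- idx
    cnt_list[[p]] <- cnt
  }

  lens <- lengths(idx_list)
  events <- tibble(
    patient_id = rep(patient_ids, lens),
    term = ae_terms[unlist(idx_list)],
    term_type = "AE",
    count = as.integer(unlist(cnt_list))
  )

  drug_terms <- character(0)
  diagnosis_terms <- character(0)
  if (cfg$n_drugs > 0L) {
    drug_terms <- sprintf("drug_%03d", seq_len(cfg$n_drugs))
    events <- rbind(events, attach_codes(
      patient_ids, member_cluster, n_codes = cfg$n_drugs, terms = drug_terms,
      type = "drug", codes_per_cluster = 2L, bias = 0.7, mean_records = 2,
      p_geom = p_geom))
  }
  if (cfg$n_diagnoses > 0L) {
    diagnosis_terms <- sprintf("dx_%03d", seq_len(cfg$n_diagnoses))
    events <- rbind(events, attach_codes(
      patient_ids, member_cluster, n_codes = cfg$n_diagnoses, terms = diagnosis_terms,
      type = "diagnosis", codes_per_cluster = 1L, bias = 0.6, mean_records = 1,
      p_geom = p_geom))
  }

  events <- events[order(events$patient_id, events$term_type, events$term), ]
  events <- as_tibble(events)
  attr(events, "planted") <- list(
    clusters = tibble(
      patient_id = patient_ids[!is.na(member_cluster)],
      cluster = member_cluster[!is.na(member_cluster)]
    ),
    dominant_aes = tibble(cluster = seq_len(cfg$n_clusters), term = ae_terms[dom_idx]),
    secondary_aes = tibble(cluster = seq_len(cfg$n_clusters), term = ae_terms[sec_idx]),
    pairs = tibble(term_i = ae_terms[pp$ae_i], term_j = ae_terms[pp$ae_j],
                   joint_boost = pp$joint_boost),
    ae_terms = ae_terms,
    drug_terms = drug_terms,
    diagnosis_terms = diagnosis_terms
  )
  events
}

# per-patient drug/diagnosis records with cluster-specific characteristic codes
attach_codes <- function(patient_ids, member_cluster, n_codes, terms, type,
                         codes_per_cluster, bias, mean_records, p_geom) {
  n <- length(patient_ids)
  zipf <- seq_len(n_codes)^(-1)
  zipf <- zipf / sum(zipf)
  n_clusters <- max(c(member_cluster, 0L), na.rm = TRUE)
  char_codes <- lapply(seq_len(n_clusters), function(cl) {
    1L + (codes_per_cluster * (cl - 1L) + seq_len(codes_per_cluster) - 1L) %% n_codes
  })
  n_rec <- 1L + rpois(n, mean_records)
  idx_list <- vector("list", n)
  cnt_list <- vector("list", n)
  for (p in seq_len(n)) {
    cl <- member_cluster[p]
    draws <- sample.int(n_codes, n_rec[p], prob = zipf, replace = TRUE)
    if (!is.na(cl)) {
      use_char <- runif(n_rec[p]) < bias
      if (any(use_char)) {
        draws[use_char] <- sample(char_codes[[cl]], sum(use_char), replace = TRUE)
      }
    }
    tab <- tabulate(draws, nbins = n_codes)
    idx <- which(tab > 0L)
    extra <- rgeom(length(idx), p_geom)  # occurrence counts beyond first mention
    idx_list[[p]] <- idx
    cnt_list[[p]] <- tab[idx] + extra
  }
  lens <- lengths(idx_list)
  tibble(
    patient_id = rep(patient_ids, lens),
    term = terms[unlist(idx_list)],
    term_type = type,
    count = as.integer(unlist(cnt_list))
  )
}

#' Generate a cohort with independently assigned AEs
#'
#' Null model for calibrating the pairwise false-discovery behavior: each
#' patient receives each AE independently with a per-AE Bernoulli
#' probability proportional to a Zipf popularity (scaled so the expected
#' burden matches `burden_mean`). Under this model every AE pair is truly
#' independent, so any significant pair is a false positive. This differs
#' from [generate_cohort()], whose burden-first sampling reproduces the
#' positive dependence that heterogeneous record lengths induce between AEs
#' in real cohorts.
#'
#' Patients who draw no AE are absent from the returned table (the event
#' table only ever describes AE-bearing patients).
#'
#' @param n_patients,n_aes Cohort dimensions.
#' @param burden_mean Expected number of AEs per patient before
#'   zero-removal.
#' @param prevalence_tail_exponent Zipf exponent of the per-AE inclusion
#'   probabilities.
#' @param count_mean Mean occurrence count of a present AE (1 + geometric).
#' @param seed Integer seed.
#' @return An event-table tibble of AE records.
#' @export
generate_null_cohort <- function(n_patients, n_aes, burden_mean = 5.2,
                                 prevalence_tail_exponent = 1.45,
                                 count_mean = 1.6, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    zipf <- seq_len(n_aes)^(-prevalence_tail_exponent)
    q <- pmin(burden_mean * zipf / sum(zipf), 0.95)
    inc <- matrix(runif(n_patients * n_aes), n_patients, n_aes) <
      matrix(q, n_patients, n_aes, byrow = TRUE)
    sel <- which(inc, arr.ind = TRUE)
    if (nrow(sel) == 0L) stop("null cohort drew no AE records", call. = FALSE)
    tibble(
      patient_id = sprintf("P%05d", sel[, 1L]),
      term = sprintf("ae_%04d", sel[, 2L]),
      term_type = "AE",
      count = 1L + rgeom(nrow(sel), 1 / count_mean)
    )[order(sel[, 1L], sel[, 2L]), ]
  })
}

#' Summarize the marginal statistics of an event table
#'
#' Computes the corpus-shape summaries used to compare a cohort (synthetic or
#' real) against the reference population: number of AE-bearing patients,
#' number of distinct AEs, mean/max distinct AEs per patient, the fraction of
#' patients with exactly one AE, the fraction of AEs affecting exactly one
#' patient, and the mean number of patients per AE.
#'
#' @param events An event table (see [generate_cohort()] / [read_event_table()]).
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    stop("`events` is empty", call. = FALSE)
  }
  ae <- events[events$term_type == "AE", , drop = FALSE]
  if (nrow(ae) == 0L) stop("`events` contains no AE records", call. = FALSE)
  per_patient <- table(ae$patient_id)
  per_ae <- table(ae$term)
  out <- list(
    n_patients = length(per_patient),
    n_aes = length(per_ae),
    mean_aes_per_patient = as.numeric(mean(per_patient)),
    max_aes_per_patient = as.integer(max(per_patient)),
    frac_single_ae_patients = as.numeric(mean(per_patient == 1L)),
    frac_single_patient_aes = as.numeric(mean(per_ae == 1L)),
    mean_patients_per_ae = as.numeric(mean(per_ae))
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Cohort summary\n",
           "  patients with >=1 AE : %d\n",
           "  distinct AEs         : %d\n",
           "  AEs per patient      : mean %.2f, max %d\n",
           "  single-AE patients   : %.1f%%\n",
           "  single-patient AEs   : %.1f%%\n",
           "  patients per AE      : mean %.2f\n"),
    x$n_patients, x$n_aes, x$mean_aes_per_patient, x$max_aes_per_patient,
    100 * x$frac_single_ae_patients, 100 * x$frac_single_patient_aes,
    x$mean_patients_per_ae))
  invisible(x)
}
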