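#' Exhaustive patient co-affection counts for all AE pairs
#'
#' Counts, for every unordered AE pair over the vocabulary, the number of
#' patients affected by each AE alone and by both, from the binary
#' patient-by-AE incidence implied by the event table. With a vocabulary of
#' `V` terms the table has `V * (V - 1) / 2` rows, each pair once with
#' `ae_i < ae_j` in term order.
#'
#' @param events Event table; only `term_type == "AE"` records are used.
#' @param vocabulary Optional character vector of AE terms defining the pair
#'   universe; defaults to the AE terms observed in `events`. Must contain
#'   every observed term.
#' @return A tibble with columns `ae_i`, `ae_j`, `n_A`, `n_B`, `n_AB`,
#'   `n_tot` (total number of AE-bearing patients).
#' @export
pair_counts <- function(events, vocabulary = NULL) {
  ae <- events[events$term_type == "AE", , drop = FALSE]
  if (nrow(ae) == 0L) stop("no AE records in `events`", call. = FALSE)
  patients <- sort(unique(ae$patient_id))
  terms <- sort(unique(ae$term))
  if (is.null(vocabulary)) {
    vocabulary <- terms
  } else {
    vocabulary <- sort(unique(as.character(vocabulary)))
    extra <- setdiff(terms, vocabulary)
    if (length(extra) > 0L) {
      stop(sprintf("observed AE terms missing from `vocabulary`: %s",
                   paste(head(extra, 5), collapse = ", ")), call. = FALSE)
    }
  }
  V <- length(vocabulary)
  if (V < 2L) stop("need at least 2 AE terms to form pairs", call. = FALSE)
  X <- Matrix::sparseMatrix(
    i = match(ae$patient_id, patients),
    j = match(ae$term, vocabulary),
    x = 1,
    dims = c(length(patients), V)
  )
  co <- as.matrix(Matrix::crossprod(X))
  n_each <- as.integer(diag(co))
  i <- rep.int(seq_len(V - 1L), (V - 1L):1L)
  j <- sequence((V - 1L):1L, from = 2L:V)
  tibble(
    ae_i = vocabulary[i],
    ae_j = vocabulary[j],
    n_A = n_each[i],
    n_B = n_each[j],
    n_AB = as.integer(co[cbind(i, j)]),
    n_tot = length(patients)
  )
}

check_pair_counts <- function(n_AB, n_A, n_B, n_tot) {
  if (any(n_tot <= 0)) stop("`n_tot` must be positive", call. = FALSE)
  if (any(n_AB < 0 | n_A < 0 | n_B < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(n_A > n_tot) || any(n_B > n_tot)) {
    stop("marginal counts exceed `n_tot`", call. = FALSE)
  }
  if (any(n_AB > pmin(n_A, n_B))) {
    stop("`n_AB` exceeds a marginal count", call. = FALSE)
  }
  if (any(n_tot - n_A - n_B + n_AB < 0)) {
    stop("negative cell: n_tot - n_A - n_B + n_AB < 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pseudocount co-occurrence score
#'
#' Log2 ratio of the observed number of co-affected patients to the number
#' expected under independence, with a pseudocount of 1 added to numerator
#' and denominator so that pairs of very rare AEs are favored less:
#' `log2((n_AB + 1) / (n_A * n_B / n_tot + 1))`. Zero indicates perfect
#' proportionality; positive values indicate enrichment. All arguments are
#' vectorized.
#'
#' @param n_AB Patients affected by both AEs.
#' @param n_A,n_B Patients affected by each AE.
#' @param n_tot Total number of patients.
#' @return Numeric score(s).
#' @export
cooccurrence_score <- function(n_AB, n_A, n_B, n_tot) {
  check_pair_counts(n_AB, n_A, n_B, n_tot)
  log2((n_AB + 1) / (n_A * n_B / n_tot + 1))
}

#' Fisher's exact test for one AE pair
#'
#' Tests the 2x2 partition of patients (both AEs / A only / B only / neither)
#' for association. The default one-sided alternative (`"greater"`) asks for
#' more co-affected patients than expected under independence, which is the
#' relevant direction when screening for co-occurrence; the one-sided p-value
#' is the hypergeometric upper tail. `"two.sided"` delegates to
#' [stats::fisher.test()]. Vectorized over the counts.
#'
#' @inheritParams cooccurrence_score
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_pair_test <- function(n_AB, n_A, n_B, n_tot,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_pair_counts(n_AB, n_A, n_B, n_tot)
  if (alternative == "greater") {
    phyper(n_AB - 1, n_A, n_tot - n_A, n_B, lower.tail = FALSE)
  } else {
    mapply(function(ab, a, b, tot) {
      fisher.test(matrix(c(ab, a - ab, b - ab, tot - a - b + ab), 2L),
                  alternative = "two.sided")$p.value
    }, n_AB, n_A, n_B, n_tot)
  }
}

#' Benjamini-Hochberg adjustment of pair p-values
#'
#' Orders the p-values, multiplies each by the number of tests and divides by
#' its rank. The default (`mode = "standard"`) additionally enforces the
#' monotone step-up form (cumulative minimum from the largest rank down,
#' capped at 1) via [stats::p.adjust()]; `mode = "raw"` returns the plain
#' `p * m / rank` values without the monotonicity pass. The rejection set
#' `{adjusted < alpha}` is identical between the standard adjustment and the
#' classical BH step-up decision rule.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param n_tests Number of tests `m` (at least `length(pvalues)`); pairs not
#'   represented in `pvalues` are implicitly treated as non-significant.
#' @param mode `"standard"` or `"raw"`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues, n_tests = length(pvalues),
                      mode = c("standard", "raw")) {
  mode <- match.arg(mode)
  if (any(pvalues < 0 | pvalues > 1 | !is.finite(pvalues))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (n_tests < length(pvalues)) {
    stop("`n_tests` must be at least length(pvalues)", call. = FALSE)
  }
  if (mode == "standard") {
    p.adjust(pvalues, method = "BH", n = n_tests)
  } else {
    o <- order(pvalues)
    adj <- numeric(length(pvalues))
    adj[o] <- pvalues[o] * n_tests / seq_along(pvalues)
    adj
  }
}

#' Full pair statistics table
#'
#' Combines [pair_counts()], [cooccurrence_score()], [fisher_pair_test()] and
#' [bh_adjust()] into the per-pair statistics table: counts, score, raw
#' Fisher p, BH-adjusted p (both the standard monotone adjustment, `bh_p`,
#' and the plain `p * m / rank` values, `bh_raw_p`) and a significance flag
#' `bh_p < alpha`.
#'
#' @inheritParams pair_counts
#' @param alpha Significance level on the adjusted p-values.
#' @param m_mode Number of tests used in the correction: `"all_pairs"` uses
#'   all `V (V - 1) / 2` vocabulary pairs; `"observed_pairs"` corrects only
#'   over pairs with at least one co-affected patient (other pairs are never
#'   significant and get `bh_p = NA`).
#' @param alternative Passed to [fisher_pair_test()].
#' @return The [pair_counts()] tibble extended with `score`, `fisher_p`,
#'   `bh_p`, `bh_raw_p`, `significant`; the number of tests is attached as
#'   attribute `"n_tests"`.
#' @export
pair_stats <- function(events, alpha = 0.01, m_mode = c("all_pairs", "observed_pairs"),
                       alternative = c("greater", "two.sided"), vocabulary = NULL) {
  m_mode <- match.arg(m_mode)
  alternative <- match.arg(alternative)
  tab <- pair_counts(events, vocabulary = vocabulary)
  tab$score <- cooccurrence_score(tab$n_AB, tab$n_A, tab$n_B, tab$n_tot)
  tab$fisher_p <- fisher_pair_test(tab$n_AB, tab$n_A, tab$n_B, tab$n_tot,
                                   alternative = alternative)
  if (m_mode == "all_pairs") {
    m <- nrow(tab)
    tab$bh_p <- bh_adjust(tab$fisher_p, n_tests = m)
    tab$bh_raw_p <- bh_adjust(tab$fisher_p, n_tests = m, mode = "raw")
  } else {
    obs <- tab$n_AB > 0L
    m <- sum(obs)
    tab$bh_p <- NA_real_
    tab$bh_raw_p <- NA_real_
    if (m > 0L) {
      tab$bh_p[obs] <- bh_adjust(tab$fisher_p[obs], n_tests = m)
      tab$bh_raw_p[obs] <- bh_adjust(tab$fisher_p[obs], n_tests = m, mode = "raw")
    }
  }
  tab$significant <- !is.na(tab$bh_p) & tab$bh_p < alpha
  attr(tab, "n_tests") <- m
  attr(tab, "alpha") <- alpha
  attr(tab, "alternative") <- alternative
  tab
}

#' Per-AE prevalence
#'
#' @param events Event table.
#' @return Tibble with `term`, `n_patients` (distinct patients affected) and
#'   `prevalence` (fraction of all AE-bearing patients).
#' @export
ae_prevalence <- function(events) {
  ae <- events[events$term_type == "AE", , drop = FALSE]
  if (nrow(ae) == 0L) stop("no AE records in `events`", call. = FALSE)
  n_tot <- length(unique(ae$patient_id))
  cnt <- table(ae$term)
  tibble(term = names(cnt), n_patients = as.integer(cnt),
         prevalence = as.integer(cnt) / n_tot)
}

#' Significant co-occurrence score network
#'
#' Builds the AE-AE network of the co-occurrence score method: edges are AE
#' pairs whose BH-adjusted Fisher p-value is below `alpha`; nodes are the AEs
#' incident to at least one significant edge, carrying the fraction of
#' patients they affect.
#'
#' @inheritParams pair_stats
#' @param annotations Optional tibble (`term`, `anatomical_class`) used to
#'   annotate nodes.
#' @return An [ae_network()] whose edges carry `score`, `fisher_p`, `bh_p`.
#' @export
score_network <- function(events, alpha = 0.01,
                          m_mode = c("all_pairs", "observed_pairs"),
                          alternative = c("greater", "two.sided"),
                          vocabulary = NULL, annotations = NULL) {
  stats_tab <- pair_stats(events, alpha = alpha, m_mode = m_mode,
                          alternative = alternative, vocabulary = vocabulary)
  sig <- stats_tab[stats_tab$significant,
                   c("ae_i", "ae_j", "score", "fisher_p", "bh_p"), drop = FALSE]
  ae_network(edges = sig, prevalence = ae_prevalence(events),
             method = "cooccurrence_score", annotations = annotations)
}

#' Patient-normalized weighted edges between AEs
#'
#' For AEs `i != j`, `WE_ij = sum over patients p of
#' delta_i^p delta_j^p / (n_p - 1)`, where `delta_i^p` indicates whether
#' patient `p` has AE `i` and `n_p` is the patient's number of distinct AEs.
#' Each co-affected patient thus contributes `1 / (n_p - 1)`, down-weighting
#' patients with many AEs; a patient distributes a total weight of `n_p`
#' over their AE pairs. Patients with a single AE contribute to no pair.
#' `WE_ii = 0` by definition.
#'
#' @param events Event table.
#' @param vocabulary Optional AE vocabulary (as in [pair_counts()]).
#' @return Dense symmetric matrix of weights with AE terms as dimnames.
#' @export
weighted_edges <- function(events, vocabulary = NULL) {
  ae <- events[events$term_type == "AE", , drop = FALSE]
  if (nrow(ae) == 0L) stop("no AE records in `events`", call. = FALSE)
  patients <- sort(unique(ae$patient_id))
  terms <- sort(unique(ae$term))
  if (!is.null(vocabulary)) {
    vocabulary <- sort(unique(as.character(vocabulary)))
    extra <- setdiff(terms, vocabulary)
    if (length(extra) > 0L) {
      stop(sprintf("observed AE terms missing from `vocabulary`: %s",
                   paste(head(extra, 5), collapse = ", ")), call. = FALSE)
    }
    terms <- vocabulary
  }
  X <- Matrix::sparseMatrix(
    i = match(ae$patient_id, patients),
    j = match(ae$term, terms),
    x = 1,
    dims = c(length(patients), length(terms)),
    dimnames = list(patients, terms)
  )
  n_p <- Matrix::rowSums(X)
  w <- ifelse(n_p > 1, 1 / (n_p - 1), 0)
  WE <- as.matrix(Matrix::crossprod(X, Matrix::Diagonal(x = w) %*% X))
  dimnames(WE) <- list(terms, terms)
  diag(WE) <- 0
  WE
}

#' Disparity-filter significance of one node's edge weights
#'
#' For a node with `k` positive-weight edges and normalized weights
#' `p_j = w_j / sum(w)`, the probability that a uniformly random split of the
#' node's strength produces an edge at least as concentrated is
#' `alpha_j = 1 - (k - 1) * integral_0^{p_j} (1 - x)^(k - 2) dx`, which
#' evaluates in closed form to `(1 - p_j)^(k - 1)`. A node with a single
#' edge (`k = 1`) carries no evidence and gets `alpha = 1`.
#'
#' @param weights Positive edge weights emanating from one node.
#' @return Numeric vector of `alpha` values in `[0, 1]`, one per edge.
#' @export
disparity_alpha <- function(weights) {
  if (length(weights) == 0L) stop("empty weight vector", call. = FALSE)
  if (any(weights <= 0 | !is.finite(weights))) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  k <- length(weights)
  if (k == 1L) return(1)
  p <- weights / sum(weights)
  pmin(pmax((1 - p)^(k - 1), 0), 1)
}

#' Multiscale backbone of the weighted AE network
#'
#' Removes the `drop_top_prevalent` most prevalent AEs (ties broken by term
#' order), then retains an undirected edge when it is significant under the
#' disparity filter from at least one endpoint (`alpha_ij < alpha` or
#' `alpha_ji < alpha`; set `rule = "both"` to require both directions).
#' Nodes are the AEs incident to at least one retained edge.
#'
#' @param weights Symmetric weight matrix from [weighted_edges()].
#' @param alpha Disparity significance level.
#' @param drop_top_prevalent Number of most prevalent AEs to remove before
#'   extraction (0 for none).
#' @param prevalence [ae_prevalence()] tibble (or a named patient-count
#'   vector); required when `drop_top_prevalent > 0` and used for node sizes.
#' @param rule Edge retention rule: `"either"` (default) or `"both"`.
#' @param annotations Optional node annotation tibble (`term`,
#'   `anatomical_class`).
#' @return An [ae_network()] whose edges carry `weight`, `alpha_ij`,
#'   `alpha_ji`.
#' @export
extract_backbone <- function(weights, alpha = 0.01, drop_top_prevalent = 10,
                             prevalence = NULL, rule = c("either", "both"),
                             annotations = NULL) {
  rule <- match.arg(rule)
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-8))) {
    stop("`weights` must be symmetric", call. = FALSE)
  }
  terms <- rownames(weights)
  prev_counts <- NULL
  if (!is.null(prevalence)) {
    prev_counts <- if (is.data.frame(prevalence)) {
      setNames(prevalence$n_patients, prevalence$term)
    } else {
      prevalence
    }
  }
  if (drop_top_prevalent > 0L) {
    if (is.null(prev_counts)) {
      stop("`prevalence` is required when drop_top_prevalent > 0", call. = FALSE)
    }
    pc <- prev_counts[terms]
    pc[is.na(pc)] <- 0
    drop <- terms[order(-pc, terms)][seq_len(min(drop_top_prevalent, length(terms)))]
    keep <- setdiff(terms, drop)
    weights <- weights[keep, keep, drop = FALSE]
    terms <- keep
  }
  W <- weights
  rs <- rowSums(W)
  k <- rowSums(W > 0)
  P <- W / ifelse(rs > 0, rs, 1)
  A <- (1 - P)^pmax(k - 1, 0)  # k - 1 recycles down rows
  A[k <= 1, ] <- 1
  A[W <= 0] <- 1
  sig <- A < alpha
  keep_edge <- if (rule == "either") sig | t(sig) else sig & t(sig)
  sel <- which(upper.tri(W) & keep_edge & W > 0, arr.ind = TRUE)
  edges <- tibble(
    ae_i = terms[sel[, 1L]],
    ae_j = terms[sel[, 2L]],
    weight = W[sel],
    alpha_ij = A[sel],
    alpha_ji = t(A)[sel]
  )
  prev_tab <- if (is.data.frame(prevalence)) {
    prevalence
  } else if (!is.null(prev_counts)) {
    tibble(term = names(prev_counts), n_patients = as.integer(prev_counts),
           prevalence = NA_real_)
  }
  ae_network(edges = edges, prevalence = prev_tab,
             method = "multiscale_backbone", annotations = annotations)
}

#' Weighted-edge backbone network straight from an event table
#'
#' Convenience wrapper: computes [weighted_edges()] on the full patient data,
#' then applies [extract_backbone()] (prevalence-based node removal happens
#' after the weights are computed).
#'
#' @inheritParams extract_backbone
#' @param events Event table.
#' @param vocabulary Optional AE vocabulary.
#' @return An [ae_network()].
#' @export
backbone_network <- function(events, alpha = 0.01, drop_top_prevalent = 10,
                             rule = c("either", "both"), vocabulary = NULL,
                             annotations = NULL) {
  rule <- match.arg(rule)
  WE <- weighted_edges(events, vocabulary = vocabulary)
  extract_backbone(WE, alpha = alpha, drop_top_prevalent = drop_top_prevalent,
                   prevalence = ae_prevalence(events), rule = rule,
                   annotations = annotations)
}
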