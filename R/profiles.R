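#' Build tf-idf profile vectors for patients or clusters
#'
#' Represents each document (a patient, or the merged records of a patient
#' cluster) as a tf-idf weighted vector over the vocabulary of one term type.
#' For a term with occurrence count `f` in a document whose terms occur `F`
#' times in total, present in `n` of the `N` corpus documents, the value is
#' `(f / F) * ln(N / n)`. The normalized term frequency `f / F` prevents bias
#' toward patients with longer clinical histories; the log inverse document
#' frequency down-weights ubiquitous terms (a term present in every document
#' scores exactly zero). No smoothing is applied inside the idf.
#'
#' When `documents` groups patients into clusters, term and total frequencies
#' are computed over the merged counts of each cluster. By default the idf is
#' still the patient-level corpus statistic (`idf_corpus = "patients"`), so
#' cluster values remain on the same scale as patient values; set
#' `idf_corpus = "documents"` to recompute document frequency over the merged
#' documents instead.
#'
#' @param events Event table (`patient_id`, `term`, `term_type`, `count`).
#' @param term_type Which vocabulary to use: `"AE"`, `"drug"` or `"diagnosis"`.
#' @param documents Optional patient-to-document grouping: a
#'   [hierarchical_cluster()] assignment, or a named vector / two-column data
#'   frame (`patient_id`, `document`) mapping patients to document labels.
#'   Patients absent from the mapping are dropped. `NULL` treats every
#'   patient as its own document.
#' @param idf_corpus Corpus used for the document-frequency term: patient
#'   records (default) or the grouped documents.
#' @return A dense numeric matrix (documents x terms) with an `"idf"`
#'   attribute holding the idf vector used. Patients with no record of the
#'   requested type are excluded (a message reports how many).
#' @export
compute_tfidf <- function(events, term_type = c("AE", "drug", "diagnosis"),
                          documents = NULL,
                          idf_corpus = c("patients", "documents")) {
  term_type <- match.arg(term_type)
  idf_corpus <- match.arg(idf_corpus)
  ev <- events[events$term_type == term_type, , drop = FALSE]
  if (nrow(ev) == 0L) {
    stop(sprintf("no `%s` records: vocabulary is empty", term_type), call. = FALSE)
  }
  all_patients <- unique(events$patient_id)
  patients <- sort(unique(ev$patient_id))
  n_dropped <- length(all_patients) - length(patients)
  if (n_dropped > 0L) {
    message(sprintf("dropping %d patient(s) with no %s records", n_dropped, term_type))
  }
  terms <- sort(unique(ev$term))
  C <- Matrix::sparseMatrix(
    i = match(ev$patient_id, patients),
    j = match(ev$term, terms),
    x = as.numeric(ev$count),
    dims = c(length(patients), length(terms)),
    dimnames = list(patients, terms)
  )
  C <- as.matrix(C)

  doc_of <- resolve_documents(documents, patients)
  if (!is.null(doc_of)) {
    keep <- !is.na(doc_of)
    if (any(!keep)) {
      message(sprintf("dropping %d patient(s) not covered by `documents`", sum(!keep)))
    }
    M <- rowsum(C[keep, , drop = FALSE], group = doc_of[keep])
    M <- M[order(rownames(M)), , drop = FALSE]
  } else {
    M <- C
  }

  idf <- if (idf_corpus == "patients") {
    log(nrow(C) / pmax(Matrix::colSums(C > 0), 1))
  } else {
    log(nrow(M) / pmax(colSums(M > 0), 1))
  }
  tf <- M / rowSums(M)
  out <- sweep(tf, 2L, idf, `*`)
  attr(out, "idf") <- idf
  attr(out, "term_type") <- term_type
  out
}

resolve_documents <- function(documents, patients) {
  if (is.null(documents)) return(NULL)
  if (inherits(documents, "cluster_assignment")) {
    map <- setNames(as.character(documents$labels), names(documents$labels))
  } else if (is.data.frame(documents)) {
    map <- setNames(as.character(documents[[2]]), as.character(documents[[1]]))
  } else if (!is.null(names(documents))) {
    map <- setNames(as.character(documents), names(documents))
  } else {
    stop("`documents` must be a cluster assignment, named vector or data frame",
         call. = FALSE)
  }
  unname(map[patients])
}

#' Characteristic scale of a profile vector
#'
#' Normalizes a non-negative profile vector (one row of a tf-idf matrix) to
#' fractions of its sum, giving each term's share on a 0-1 scale. The largest
#' fraction identifies the document's most distinguishing term.
#'
#' @param x Non-negative numeric vector with at least one positive entry,
#'   typically named by term.
#' @return Named numeric vector of fractions summing to 1.
#' @export
characteristic_scale <- function(x) {
  if (any(x < 0) || any(!is.finite(x))) {
    stop("profile values must be finite and non-negative", call. = FALSE)
  }
  s <- sum(x)
  if (s <= 0) {
    stop("all-zero profile: document cannot be characterized", call. = FALSE)
  }
  x / s
}

#' Row-wise characteristic fractions of a profile matrix
#'
#' @param profiles Numeric matrix of non-negative profile values
#'   (documents x terms).
#' @return Matrix of the same shape with each row normalized to sum to 1.
#' @seealso [characteristic_scale()]
#' @export
characteristic_profiles <- function(profiles) {
  s <- rowSums(profiles)
  zero <- s <= 0
  if (any(zero)) {
    stop(sprintf("all-zero profile row(s): %s",
                 paste(rownames(profiles)[zero], collapse = ", ")), call. = FALSE)
  }
  profiles / s
}

#' Rank the most distinguishing terms of a document
#'
#' Orders a document's characteristic fractions in decreasing order (ties
#' broken lexicographically by term) and returns the top `k` nonzero terms.
#'
#' @param fractions Named fraction vector from [characteristic_scale()].
#' @param k Maximum number of terms to return.
#' @return A tibble with columns `term` and `fraction`.
#' @export
rank_distinguishing_terms <- function(fractions, k) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  keep <- fractions > 0
  fr <- fractions[keep]
  nm <- names(fr) %||% as.character(which(keep))
  ord <- order(-fr, nm)
  n <- min(as.integer(k), length(fr))
  tibble(term = nm[ord][seq_len(n)], fraction = unname(fr[ord][seq_len(n)]))
}
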