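#' Pairwise cosine dissimilarity between profile rows
#'
#' Computes `1 - cos(theta)` between every pair of document vectors:
#' `d(i, j) = 1 - (a . b) / (||a|| ||b||)`. The measure is independent of the
#' per-document vector length, so patients with different numbers of adverse
#' events remain comparable; for non-negative profiles it lies in `[0, 1]`
#' (0 for parallel, 1 for orthogonal supports).
#'
#' @param profiles Numeric matrix (documents x terms), e.g. from
#'   [compute_tfidf()]. Every row must have positive norm.
#' @return Symmetric numeric matrix of dissimilarities with zero diagonal.
#' @export
cosine_dissimilarity_matrix <- function(profiles) {
  nrm <- sqrt(rowSums(profiles^2))
  zero <- nrm <= 0 | !is.finite(nrm)
  if (any(zero)) {
    stop(sprintf("zero-norm profile row(s): %s",
                 paste(rownames(profiles)[zero], collapse = ", ")), call. = FALSE)
  }
  u <- profiles / nrm
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0
  d[d > 1 & d < 1 + 1e-12] <- 1
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering with a dendrogram cutoff
#'
#' Agglomerative clustering under unweighted average linkage (UPGMA: the
#' inter-cluster distance is the arithmetic mean over all cross-cluster
#' document pairs). The tree is cut so that exactly the merges with height
#' strictly below `cutoff` are applied; merges at or above the cutoff are
#' excluded, and unmerged documents form singleton clusters. Cluster ids are
#' assigned by decreasing size starting at 1 (ties broken by the smallest
#' contained document id), so cluster 1 is always the largest cluster.
#'
#' @param dist_matrix Symmetric dissimilarity matrix (or `dist` object) with
#'   document ids as labels.
#' @param cutoff Positive dendrogram cut height (0.6 is the conventional
#'   cosine-dissimilarity choice for AE profiles).
#' @return An object of class `cluster_assignment`: a list with `labels`
#'   (named integer vector document -> cluster id), `cutoff`, `linkage`,
#'   and `cluster_sizes` (named by cluster id, decreasing).
#' @export
hierarchical_cluster <- function(dist_matrix, cutoff = 0.6) {
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  d <- as.dist(dist_matrix)
  ids <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  n <- attr(d, "Size")
  if (n < 2L) {
    message("fewer than 2 documents: returning a single trivial cluster")
    labels <- setNames(rep(1L, n), ids)
    return(new_cluster_assignment(labels, cutoff, "average"))
  }
  hc <- hclust(d, method = "average")
  n_below <- sum(hc$height < cutoff)
  raw <- cutree(hc, k = n - n_below)
  names(raw) <- ids
  labels <- relabel_by_size(raw)
  new_cluster_assignment(labels, cutoff, "average")
}

# renumber clusters: 1 = largest; ties by smallest contained document id
relabel_by_size <- function(raw) {
  sizes <- table(raw)
  min_id <- tapply(names(raw), raw, min)
  ord <- order(-as.integer(sizes), min_id[names(sizes)])
  remap <- setNames(seq_along(ord), names(sizes)[ord])
  setNames(unname(remap[as.character(raw)]), names(raw))
}

new_cluster_assignment <- function(labels, cutoff, linkage) {
  sizes <- table(labels)
  sizes <- sizes[order(as.integer(names(sizes)))]
  structure(list(
    labels = labels,
    cutoff = cutoff,
    linkage = linkage,
    cluster_sizes = setNames(as.integer(sizes), names(sizes))
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d documents in %d clusters (%s linkage, cutoff %g)\n",
              length(x$labels), length(x$cluster_sizes), x$linkage, x$cutoff))
  invisible(x)
}

#' Keep only clusters of a minimum size
#'
#' Restricts a cluster assignment to clusters with at least `min_size`
#' members (retained cluster ids are unchanged). Documents in smaller
#' clusters are dropped from the assignment but remain available to the
#' co-occurrence stage, which operates on the full patient population.
#'
#' @param assignment A [hierarchical_cluster()] result.
#' @param min_size Minimum cluster size to retain.
#' @return A `cluster_assignment` restricted to qualifying clusters.
#' @export
filter_clusters <- function(assignment, min_size = 10) {
  if (min_size < 1) stop("`min_size` must be >= 1", call. = FALSE)
  keep_ids <- as.integer(names(assignment$cluster_sizes))[assignment$cluster_sizes >= min_size]
  labels <- assignment$labels[assignment$labels %in% keep_ids]
  out <- new_cluster_assignment(labels, assignment$cutoff, assignment$linkage)
  message(sprintf("retained %d cluster(s) of size >= %d, accounting for %d document(s)",
                  length(out$cluster_sizes), min_size, length(out$labels)))
  out
}

#' Patient similarity network under a dissimilarity threshold
#'
#' Links every pair of retained patients whose cosine dissimilarity is
#' strictly below `threshold`. Nodes carry their cluster id; cross-cluster
#' edges are allowed.
#'
#' @param dist_matrix Symmetric dissimilarity matrix over (at least) the
#'   retained patients.
#' @param assignment Cluster assignment restricted to the retained patients
#'   (see [filter_clusters()]).
#' @param threshold Edge-inclusion threshold (edges require `d < threshold`).
#' @return An object of class `patient_network`: a list with `nodes`
#'   (tibble `patient_id`, `cluster`) and `edges` (tibble `source`, `target`,
#'   `dissimilarity`, with `source < target`).
#' @export
build_patient_network <- function(dist_matrix, assignment, threshold = 0.6) {
  ids <- names(assignment$labels)
  missing <- setdiff(ids, rownames(dist_matrix))
  if (length(missing) > 0L) {
    stop(sprintf("documents missing from dist_matrix: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  d <- dist_matrix[ids, ids, drop = FALSE]
  sel <- which(upper.tri(d) & d < threshold, arr.ind = TRUE)
  edges <- tibble(
    source = ids[sel[, 1L]],
    target = ids[sel[, 2L]],
    dissimilarity = d[sel]
  )
  swap <- edges$source > edges$target
  if (any(swap)) {
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  structure(list(
    nodes = tibble(patient_id = ids, cluster = unname(assignment$labels)),
    edges = edges[order(edges$source, edges$target), ],
    threshold = threshold
  ), class = "patient_network")
}

#' @export
print.patient_network <- function(x, ...) {
  cat(sprintf("Patient network: %d patients, %d edges (dissimilarity < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Cluster the clusters by Euclidean distance in profile space
#'
#' Secondary clustering used to order heat-map columns: cluster documents
#' (typically the per-cluster drug or diagnosis profiles) are reduced to
#' characteristic fractions, compared by Euclidean distance, and clustered by
#' average linkage. The dendrogram leaf order places clusters with similar
#' profiles next to each other.
#'
#' @param cluster_profiles Numeric matrix (clusters x terms), e.g. cluster
#'   tf-idf vectors from [compute_tfidf()].
#' @param normalize Reduce rows to characteristic fractions first (default).
#' @param cutoff Optional cut height; when supplied, a partition of the
#'   clusters is returned alongside the ordering.
#' @return A list of class `cluster_ordering`: `order` (document ids in leaf
#'   order), `hclust` (the average-linkage tree), `distances` (the `dist`
#'   object) and, when `cutoff` is given, `assignment`.
#' @export
cluster_clusters <- function(cluster_profiles, normalize = TRUE, cutoff = NULL) {
  if (nrow(cluster_profiles) < 2L) {
    stop("need at least 2 cluster documents", call. = FALSE)
  }
  m <- if (normalize) characteristic_profiles(cluster_profiles) else cluster_profiles
  dd <- dist(m, method = "euclidean")
  hc <- hclust(dd, method = "average")
  assignment <- NULL
  if (!is.null(cutoff)) {
    n_below <- sum(hc$height < cutoff)
    raw <- cutree(hc, k = nrow(m) - n_below)
    names(raw) <- rownames(m)
    assignment <- new_cluster_assignment(relabel_by_size(raw), cutoff, "average")
  }
  structure(list(
    order = rownames(m)[hc$order],
    hclust = hc,
    distances = dd,
    assignment = assignment
  ), class = "cluster_ordering")
}
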