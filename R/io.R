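EVENT_HEADER <- c("patient_id", "term", "term_type", "count")
TERM_TYPES <- c("AE", "drug", "diagnosis")

#' Read a long-format event table
#'
#' Reads tab-separated `patient_id / term / term_type / count` records with
#' validation: the header must match the schema, `term_type` must be one of
#' `AE`, `drug`, `diagnosis`, and counts must be positive integers.
#' Duplicate (patient, term, type) rows are summed with a warning. Malformed
#' rows are reported with their line number.
#'
#' @param path Path to a tab-separated file with header.
#' @return A validated event-table tibble.
#' @export
read_event_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (!identical(fields[[1]], EVENT_HEADER)) {
    stop(sprintf("line 1: header must be `%s`", paste(EVENT_HEADER, collapse = "\\t")),
         call. = FALSE)
  }
  if (length(lines) == 1L) stop("no records in ", path, call. = FALSE)
  body <- fields[-1]
  nf <- lengths(body)
  if (any(nf != 4L)) {
    stop(sprintf("line %d: expected 4 tab-separated fields, found %d",
                 which(nf != 4L)[1] + 1L, nf[nf != 4L][1]), call. = FALSE)
  }
  m <- matrix(unlist(body), ncol = 4L, byrow = TRUE)
  bad_type <- !(m[, 3L] %in% TERM_TYPES)
  if (any(bad_type)) {
    stop(sprintf("line %d: unknown term_type `%s`",
                 which(bad_type)[1] + 1L, m[bad_type, 3L][1]), call. = FALSE)
  }
  count <- suppressWarnings(as.numeric(m[, 4L]))
  bad_count <- is.na(count) | count < 1 | count != floor(count)
  if (any(bad_count)) {
    stop(sprintf("line %d: count must be a positive integer, got `%s`",
                 which(bad_count)[1] + 1L, m[bad_count, 4L][1]), call. = FALSE)
  }
  ev <- tibble(patient_id = m[, 1L], term = m[, 2L], term_type = m[, 3L],
               count = as.integer(count))
  key <- paste(ev$patient_id, ev$term, ev$term_type, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicated (patient, term, type) record(s) summed",
                    sum(duplicated(key))), call. = FALSE)
    agg <- rowsum(ev$count, key, reorder = FALSE)
    first <- !duplicated(key)
    ev <- ev[first, , drop = FALSE]
    ev$count <- as.integer(agg[match(key[first], rownames(agg)), 1L])
  }
  ev[order(ev$patient_id, ev$term_type, ev$term), ]
}

#' Write an event table as tab-separated text
#'
#' @param events Event-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  write.table(events[, EVENT_HEADER], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an AE-to-anatomical-class annotation table
#'
#' Free-form two-column tab-separated table mapping AE terms to an anatomical
#' class label (used only to annotate network nodes).
#'
#' @param path Path to a tab-separated file with header
#'   `term / anatomical_class`.
#' @return Tibble with columns `term`, `anatomical_class`.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character")
  if (!all(c("term", "anatomical_class") %in% names(tab))) {
    stop("annotation table needs columns `term` and `anatomical_class`",
         call. = FALSE)
  }
  as_tibble(tab[, c("term", "anatomical_class")])
}

#' Write / read a pair statistics table
#'
#' Tab-separated serialization of the [pair_stats()] table; the round trip is
#' lossless for all columns.
#'
#' @param stats_tab Tibble from [pair_stats()].
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_pair_stats <- function(stats_tab, path) {
  write.table(stats_tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_stats
#' @export
read_pair_stats <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in intersect(c("n_A", "n_B", "n_AB", "n_tot"), names(tab))) {
    tab[[col]] <- as.integer(tab[[col]])
  }
  if ("significant" %in% names(tab)) tab$significant <- as.logical(tab$significant)
  as_tibble(tab)
}

#' Export an AE network
#'
#' Writes a network as GraphML (via igraph, with node prevalence/class and
#' edge metric attributes) and/or as a plain edge-list TSV.
#'
#' @param net An [ae_network()].
#' @param graphml Optional GraphML output path.
#' @param edgelist Optional edge-list TSV output path.
#' @return Invisible character vector of written paths.
#' @export
write_ae_network <- function(net, graphml = NULL, edgelist = NULL) {
  written <- character(0)
  if (!is.null(graphml)) {
    g <- as_igraph(net)
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(edgelist)) {
    write.table(net$edges, edgelist, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, edgelist)
  }
  invisible(written)
}

#' Export a patient similarity network
#'
#' @param net A [build_patient_network()] result.
#' @param graphml Optional GraphML output path.
#' @param edgelist Optional edge-list TSV path
#'   (`source / target / dissimilarity`).
#' @param clusters Optional TSV path for the `patient_id / cluster` table.
#' @return Invisible character vector of written paths.
#' @export
write_patient_network <- function(net, graphml = NULL, edgelist = NULL,
                                  clusters = NULL) {
  written <- character(0)
  if (!is.null(graphml)) {
    nodes <- as.data.frame(net$nodes)
    names(nodes)[1] <- "name"
    g <- igraph::graph_from_data_frame(as.data.frame(net$edges),
                                       directed = FALSE, vertices = nodes)
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(edgelist)) {
    write.table(net$edges, edgelist, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, edgelist)
  }
  if (!is.null(clusters)) {
    write.table(net$nodes, clusters, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, clusters)
  }
  invisible(written)
}

#' Heat-map-ready table of cluster characteristic fractions
#'
#' Builds the long table behind the cluster-composition heat maps: for each
#' cluster document, its characteristic fractions over the union of every
#' cluster's top `k` distinguishing terms. Terms are ordered by corpus
#' prevalence (most prevalent first), the layout used for the AE/drug/
#' diagnosis composition figures.
#'
#' @param cluster_profiles Cluster tf-idf matrix from [compute_tfidf()].
#' @param k Number of top distinguishing terms contributed per cluster.
#' @param prevalence Optional [ae_prevalence()]-style tibble used to order
#'   terms; unlisted terms keep their matrix order at the end.
#' @return Tibble with columns `term`, `cluster`, `fraction`, terms ordered
#'   by decreasing prevalence.
#' @export
heatmap_table <- function(cluster_profiles, k = 1, prevalence = NULL) {
  fr <- characteristic_profiles(cluster_profiles)
  top <- unique(unlist(lapply(rownames(fr), function(cl) {
    rank_distinguishing_terms(fr[cl, ], k)$term
  })))
  if (!is.null(prevalence)) {
    n_pat <- prevalence$n_patients[match(top, prevalence$term)]
    n_pat[is.na(n_pat)] <- -1
    top <- top[order(-n_pat, top)]
  }
  grid <- expand.grid(term = top, cluster = rownames(fr),
                      stringsAsFactors = FALSE)
  grid$fraction <- fr[cbind(grid$cluster, grid$term)]
  as_tibble(grid)
}
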