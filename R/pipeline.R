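#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the full analysis: the dendrogram
#' cutoff and minimum cluster size of the stratification stage, the
#' significance level shared by the Fisher/BH screen and the disparity
#' filter, the number of most-prevalent AEs removed before backbone
#' extraction, and the method variants exposed as switches.
#'
#' @param cutoff Cosine-dissimilarity dendrogram cutoff, in `(0, 1]`.
#' @param min_cluster_size Minimum cluster size retained for
#'   characterization.
#' @param alpha Significance level for both co-occurrence methods, in
#'   `(0, 1]`.
#' @param drop_top_prevalent Most-prevalent AEs removed before backbone
#'   extraction.
#' @param fisher_sided `"greater"` (one-sided enrichment, default) or
#'   `"two.sided"`.
#' @param bh_mode `"standard"` monotone BH (default) or `"raw"` per-rank
#'   values.
#' @param m_mode `"all_pairs"` or `"observed_pairs"` test count for BH.
#' @param backbone_rule `"either"` or `"both"` endpoint significance.
#' @param idf_corpus `"patients"` or `"documents"` idf for cluster profiles.
#' @param heatmap_k Top distinguishing terms per cluster in heat-map tables.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cutoff = 0.6, min_cluster_size = 10, alpha = 0.01,
                            drop_top_prevalent = 10,
                            fisher_sided = c("greater", "two.sided"),
                            bh_mode = c("standard", "raw"),
                            m_mode = c("all_pairs", "observed_pairs"),
                            backbone_rule = c("either", "both"),
                            idf_corpus = c("patients", "documents"),
                            heatmap_k = 2, seed = 1L) {
  if (!(cutoff > 0 && cutoff <= 1)) stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (min_cluster_size < 1) stop("`min_cluster_size` must be >= 1", call. = FALSE)
  structure(list(
    cutoff = cutoff,
    min_cluster_size = as.integer(min_cluster_size),
    alpha = alpha,
    drop_top_prevalent = as.integer(drop_top_prevalent),
    fisher_sided = match.arg(fisher_sided),
    bh_mode = match.arg(bh_mode),
    m_mode = match.arg(m_mode),
    backbone_rule = match.arg(backbone_rule),
    idf_corpus = match.arg(idf_corpus),
    heatmap_k = as.integer(heatmap_k),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full adverse-event analysis pipeline
#'
#' Executes, in order: patient tf-idf profiles; cosine dissimilarity;
#' average-linkage clustering at the configured cutoff; size filtering;
#' patient similarity network; cluster tf-idf profiles and heat-map tables in
#' AE, drug and diagnosis space (with secondary clustering of the clusters);
#' both co-occurrence methods over the full AE-bearing population; and the
#' cross-method network comparison. All artifacts are written to `out_dir`
#' along with a JSON manifest recording the configuration, package version
#' and the counts at each stage.
#'
#' @param events Event table (tibble) or path to one.
#' @param config A [pipeline_config()].
#' @param annotations Optional annotation tibble or path
#'   (see [read_annotation_table()]).
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(events, config = pipeline_config(), annotations = NULL,
                         out_dir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.character(events)) events <- stage("read_events", read_event_table(events))
  if (is.character(annotations)) {
    annotations <- stage("read_annotations", read_annotation_table(annotations))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(out_dir, name)
  }

  profiles <- stage("profiles", compute_tfidf(events, term_type = "AE"))
  d <- stage("dissimilarity", cosine_dissimilarity_matrix(profiles))
  assignment <- stage("clustering", hierarchical_cluster(d, cutoff = config$cutoff))
  retained <- stage("cluster_filter",
                    suppressMessages(filter_clusters(assignment,
                                                     min_size = config$min_cluster_size)))
  write.table(
    data.frame(patient_id = names(assignment$labels),
               cluster = unname(assignment$labels)),
    emit("clusters_all.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  net_counts <- list()
  if (length(retained$labels) > 0L) {
    pnet <- stage("patient_network",
                  build_patient_network(d, retained, threshold = config$cutoff))
    write_patient_network(pnet,
                          graphml = emit("patient_network.graphml"),
                          edgelist = emit("patient_network_edges.tsv"),
                          clusters = emit("clusters_retained.tsv"))
    net_counts$patient_edges <- nrow(pnet$edges)
  }

  prev <- ae_prevalence(events)
  if (length(retained$cluster_sizes) >= 1L) {
    for (tt in intersect(c("AE", "drug", "diagnosis"), unique(events$term_type))) {
      cp <- stage(paste0("cluster_profiles_", tt), suppressMessages(
        compute_tfidf(events, term_type = tt, documents = retained,
                      idf_corpus = config$idf_corpus)))
      tt_prev <- if (tt == "AE") prev else NULL
      hm <- stage(paste0("heatmap_", tt),
                  heatmap_table(cp, k = config$heatmap_k, prevalence = tt_prev))
      write.table(hm, emit(sprintf("heatmap_%s.tsv", tt)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      utils::write.csv(cp, emit(sprintf("cluster_profiles_%s.csv", tt)))
      if (nrow(cp) >= 2L && tt != "AE") {
        ord <- stage(paste0("cluster_clusters_", tt), cluster_clusters(cp))
        writeLines(ord$order, emit(sprintf("cluster_order_%s.txt", tt)))
      }
    }
  }

  stats_tab <- stage("pair_stats",
                     pair_stats(events, alpha = config$alpha, m_mode = config$m_mode,
                                alternative = config$fisher_sided))
  write_pair_stats(stats_tab, emit("pair_stats.tsv"))
  score_net <- stage("score_network", ae_network(
    edges = stats_tab[stats_tab$significant,
                      c("ae_i", "ae_j", "score", "fisher_p", "bh_p")],
    prevalence = prev, method = "cooccurrence_score", annotations = annotations))
  write_ae_network(score_net, graphml = emit("score_network.graphml"),
                   edgelist = emit("score_network_edges.tsv"))

  bb_net <- stage("backbone_network", backbone_network(
    events, alpha = config$alpha, drop_top_prevalent = config$drop_top_prevalent,
    rule = config$backbone_rule, annotations = annotations))
  write_ae_network(bb_net, graphml = emit("backbone_network.graphml"),
                   edgelist = emit("backbone_network_edges.tsv"))

  comparison <- stage("compare_networks", compare_networks(score_net, bb_net))

  summ <- cohort_summary(events)
  manifest <- list(
    package = "aenet",
    version = as.character(utils::packageVersion("aenet")),
    config = unclass(config),
    counts = list(
      patients = summ$n_patients,
      aes = summ$n_aes,
      clusters_total = length(assignment$cluster_sizes),
      clusters_retained = length(retained$cluster_sizes),
      patients_retained = length(retained$labels),
      patient_network_edges = net_counts$patient_edges %||% 0L,
      pair_rows = nrow(stats_tab),
      score_network = list(nodes = nrow(score_net$nodes),
                           edges = nrow(score_net$edges)),
      backbone_network = list(nodes = nrow(bb_net$nodes),
                              edges = nrow(bb_net$edges))
    ),
    comparison = unclass(comparison),
    artifacts = c(artifacts, "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
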