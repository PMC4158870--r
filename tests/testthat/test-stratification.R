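test_that("cosine dissimilarity matches hand evaluation and its invariants", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 0), c = c(0, 0, 2), a2 = c(2, 2, 0))
  d <- cosine_dissimilarity_matrix(m)
  expect_equal(d["a", "b"], 1 - 1 / sqrt(2))
  expect_equal(d["a", "a2"], 0)          # identical direction
  expect_equal(d["b", "c"], 1)           # disjoint support
  expect_equal(diag(d), setNames(rep(0, 4), rownames(m)))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  bad <- rbind(x = c(0, 0), y = c(1, 1))
  expect_error(cosine_dissimilarity_matrix(bad), "x")
})

test_that("average-linkage cutoff semantics follow the strict-below rule", {
  d3 <- matrix(0.1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  a3 <- hierarchical_cluster(d3, cutoff = 0.6)
  expect_equal(length(a3$cluster_sizes), 1L)

  two_groups <- rbind(c(0, 0.05, 0.9, 0.9), c(0.05, 0, 0.9, 0.9),
                      c(0.9, 0.9, 0, 0.05), c(0.9, 0.9, 0.05, 0))
  dimnames(two_groups) <- list(letters[1:4], letters[1:4])
  a4 <- hierarchical_cluster(two_groups, cutoff = 0.6)
  expect_equal(length(a4$cluster_sizes), 2L)

  # a merge at exactly the cutoff height is NOT applied
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(length(hierarchical_cluster(d2, cutoff = 0.6)$cluster_sizes), 2L)
  expect_equal(length(hierarchical_cluster(d2, cutoff = 0.61)$cluster_sizes), 1L)
})

test_that("cluster ids are numbered by decreasing size from 1", {
  m <- rbind(a = c(1, 0), b = c(1, 0.01), e = c(0, 1), f = c(0.01, 1),
             g = c(0.02, 1), z = c(1, 1))
  d <- cosine_dissimilarity_matrix(m)
  asg <- hierarchical_cluster(d, cutoff = 0.3)
  sizes <- asg$cluster_sizes
  expect_equal(as.integer(names(sizes)), seq_along(sizes))
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_equal(unname(asg$labels[c("e", "f", "g")]), rep(1L, 3))  # largest first
})

test_that("the tree cut matches a naive O(n^3) agglomerative reference", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(5:15, 1)
      d <- matrix(0, n, n)
      d[upper.tri(d)] <- runif(n * (n - 1) / 2)
      d <- d + t(d)
      ids <- sprintf("d%02d", seq_len(n))
      dimnames(d) <- list(ids, ids)
      got <- hierarchical_cluster(d, cutoff = 0.5)$labels[ids]
      want <- naive_average_linkage(d, cutoff = 0.5)
      expect_identical(canonical_partition(unname(got)),
                       canonical_partition(want))
    })
  }
})

test_that("document order does not affect the partition or the edge set", {
  ev <- generate_cohort(small_cluster_config(seed = 31))
  pr <- compute_tfidf(ev, "AE")
  d <- cosine_dissimilarity_matrix(pr)
  perm <- withr::with_seed(1, sample(rownames(d)))
  dp <- d[perm, perm]
  a1 <- hierarchical_cluster(d, 0.6)
  a2 <- hierarchical_cluster(dp, 0.6)
  ids <- rownames(d)
  expect_identical(canonical_partition(unname(a1$labels[ids])),
                   canonical_partition(unname(a2$labels[ids])))
  r1 <- suppressMessages(filter_clusters(a1, 10))
  r2 <- suppressMessages(filter_clusters(a2, 10))
  n1 <- build_patient_network(d, r1, 0.6)
  n2 <- build_patient_network(dp, r2, 0.6)
  expect_identical(n1$edges[, c("source", "target")],
                   n2$edges[, c("source", "target")])
})

test_that("size filtering keeps qualifying clusters and reports retention", {
  labels <- setNames(c(rep(1L, 12), rep(2L, 9)), sprintf("p%02d", 1:21))
  asg <- aenet:::new_cluster_assignment(labels, 0.6, "average")
  kept <- suppressMessages(filter_clusters(asg, min_size = 10))
  expect_equal(names(kept$cluster_sizes), "1")
  expect_equal(length(kept$labels), 12L)
  expect_message(filter_clusters(asg, min_size = 10), "12 document")
  ident <- suppressMessages(filter_clusters(asg, min_size = 1))
  expect_identical(ident$labels, asg$labels)
  expect_error(filter_clusters(asg, min_size = 0), "min_size")
})

test_that("planted clusters survive the size filter on a seeded cohort", {
  ev <- generate_cohort(small_cluster_config(seed = 41))
  pr <- compute_tfidf(ev, "AE")
  d <- cosine_dissimilarity_matrix(pr)
  asg <- hierarchical_cluster(d, 0.6)
  kept <- suppressMessages(filter_clusters(asg, 10))
  expect_equal(length(kept$cluster_sizes), 3L)
  planted <- attr(ev, "planted")
  tab <- table(planted$clusters$cluster,
               kept$labels[planted$clusters$patient_id])
  # every planted cluster maps onto exactly one retained cluster
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
})

test_that("patient network edges are exactly the sub-threshold pairs", {
  ev <- generate_cohort(cohort_config(n_patients = 100, n_aes = 120,
                                      n_clusters = 2, cluster_sizes = c(30, 25),
                                      n_drugs = 0, n_diagnoses = 0, seed = 51))
  pr <- compute_tfidf(ev, "AE")
  d <- cosine_dissimilarity_matrix(pr)
  asg <- hierarchical_cluster(d, 0.6)
  kept <- suppressMessages(filter_clusters(asg, 10))
  net <- build_patient_network(d, kept, threshold = 0.6)
  ids <- names(kept$labels)
  brute <- 0L
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && d[ids[i], ids[j]] < 0.6) brute <- brute + 1L
    }
  }
  expect_equal(nrow(net$edges), brute)
  expect_true(all(net$edges$dissimilarity < 0.6))
  expect_true(all(net$edges$source < net$edges$target))
  # threshold monotonicity: edges at 0.4 are a subset of edges at 0.6
  net4 <- build_patient_network(d, kept, threshold = 0.4)
  key <- function(n) paste(n$edges$source, n$edges$target)
  expect_true(all(key(net4) %in% key(net)))
  # degenerate threshold
  net0 <- build_patient_network(d, kept, threshold = 0)
  expect_equal(nrow(net0$edges), 0L)
})

test_that("cluster-of-clusters ordering groups similar profiles", {
  m <- rbind(c1 = c(0, 0), c2 = c(3, 4))
  ord <- cluster_clusters(m, normalize = FALSE)
  expect_equal(as.numeric(ord$distances), 5)

  twins <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0), e = c(0.1, 0.9, 0))
  o2 <- cluster_clusters(twins, normalize = TRUE)
  # identical fraction vectors merge first, at height zero
  expect_equal(o2$hclust$height[1], 0)
  first <- o2$hclust$merge[1, ]
  expect_true(all(first < 0))
  expect_equal(sort(rownames(twins)[-first]), c("a", "b"))
  # leaf adjacency of the identical pair
  pos <- match(c("a", "b"), o2$order)
  expect_equal(abs(diff(pos)), 1L)
  expect_error(cluster_clusters(m[1, , drop = FALSE]), "at least 2")
})

test_that("clusters sharing drug profiles become adjacent in the leaf order", {
  # with 4 drug codes and 3 clusters, clusters 1 and 3 share characteristic
  # drugs (codes wrap around), so their drug profiles sit together
  ev <- generate_cohort(cohort_config(n_patients = 75, n_aes = 100, n_clusters = 3,
                                      cluster_sizes = c(25, 25, 25),
                                      n_drugs = 4, n_diagnoses = 0, seed = 61))
  planted <- attr(ev, "planted")
  grouping <- setNames(as.character(planted$clusters$cluster),
                       planted$clusters$patient_id)
  dp <- suppressMessages(compute_tfidf(ev, "drug", documents = grouping))
  ord <- cluster_clusters(dp)
  pos <- match(c("1", "3"), ord$order)
  expect_equal(abs(diff(pos)), 1L)
})
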