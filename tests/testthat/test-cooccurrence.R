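test_that("pair counts come from exact set intersections", {
  ev <- events_from_sets(list(p1 = c("ae_a", "ae_b"), p2 = "ae_a"))
  tab <- pair_counts(ev)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_A, 2L)   # ae_a
  expect_equal(tab$n_B, 1L)   # ae_b
  expect_equal(tab$n_AB, 1L)
  expect_equal(tab$n_tot, 2L)

  disjoint <- events_from_sets(list(p1 = "ae_a", p2 = "ae_b"))
  expect_equal(pair_counts(disjoint)$n_AB, 0L)

  # exhaustive mode over a supplied vocabulary enumerates V(V-1)/2 rows
  vocab <- sprintf("ae_%03d", 1:40)
  tab40 <- pair_counts(ev[1, ] |> transform(term = "ae_001"), vocabulary = vocab)
  expect_equal(nrow(tab40), 40 * 39 / 2)
  expect_error(pair_counts(ev, vocabulary = "ae_a"), "missing from")
})

test_that("the pseudocount score matches hand arithmetic and is monotone", {
  expect_equal(cooccurrence_score(0, 0, 0, 10), 0)
  expect_equal(cooccurrence_score(3, 4, 5, 20), 1)          # log2(4/2)
  expect_equal(cooccurrence_score(2, 4, 10, 20), 0)         # proportional case
  expect_equal(cooccurrence_score(3, 4, 5, 20),
               cooccurrence_score(3, 5, 4, 20))             # symmetric in margins
  sc <- cooccurrence_score(0:4, 4, 5, 20)
  expect_true(all(diff(sc) > 0))                            # strict in n_AB
  expect_error(cooccurrence_score(5, 4, 5, 20), "exceeds")
  expect_error(cooccurrence_score(0, 21, 5, 20), "exceed")
})

test_that("one-sided Fisher p agrees with hypergeometric enumeration", {
  expect_equal(fisher_pair_test(0, 5, 7, 20), 1)  # boundary: full upper mass
  # all-or-none table (both AEs affect the same 5 of 10 patients)
  expect_equal(fisher_pair_test(5, 5, 5, 10), enum_fisher_greater(5, 5, 5, 10))
  withr::with_seed(7, {
    for (rep in 1:50) {
      tot <- sample(2:20, 1)
      a <- sample(0:tot, 1)
      b <- sample(0:tot, 1)
      ab_range <- max(0, a + b - tot):min(a, b)
      ab <- ab_range[sample.int(length(ab_range), 1)]
      expect_equal(fisher_pair_test(ab, a, b, tot),
                   enum_fisher_greater(ab, a, b, tot))
      # and the two-sided variant matches fisher.test
      expect_equal(fisher_pair_test(ab, a, b, tot, alternative = "two.sided"),
                   stats::fisher.test(matrix(c(ab, a - ab, b - ab,
                                               tot - a - b + ab), 2))$p.value)
    }
  })
  expect_error(fisher_pair_test(0, 8, 8, 10), "negative cell")
})

test_that("doubling an enriched table never increases the one-sided p", {
  for (tot in c(10, 16, 20)) {
    for (a in 2:6) {
      for (ab in seq(ceiling(a * a / tot + 1), a)) {
        if (ab > a) next
        p1 <- fisher_pair_test(ab, a, a, tot)
        p2 <- fisher_pair_test(2 * ab, 2 * a, 2 * a, 2 * tot)
        expect_lte(p2, p1 + 1e-12)
      }
    }
  }
})

test_that("BH adjustment reproduces hand values and the step-up rule", {
  expect_equal(bh_adjust(0.005, n_tests = 1), 0.005)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03), n_tests = 3), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # raw per-rank values skip the monotonicity pass
  expect_equal(bh_adjust(c(0.03, 0.01), n_tests = 2, mode = "raw"),
               c(0.03, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, 0.1), n_tests = 1), "n_tests")
  withr::with_seed(11, {
    for (rep in 1:25) {
      p <- runif(30)^sample(1:3, 1)
      m <- 30 + sample(0:20, 1)
      alpha <- sample(c(0.01, 0.05, 0.2), 1)
      expect_identical(bh_adjust(p, n_tests = m) <= alpha,
                       bh_reject_bruteforce(p, m, alpha))
    }
  })
})

test_that("weighted edges follow the 1/(n_p - 1) patient normalization", {
  one_pair <- events_from_sets(list(p1 = c("ae_i", "ae_j")))
  WE <- weighted_edges(one_pair)
  expect_equal(WE["ae_i", "ae_j"], 1)
  expect_equal(diag(WE), setNames(c(0, 0), c("ae_i", "ae_j")))

  triple <- events_from_sets(list(p1 = c("ae_i", "ae_j", "ae_k")))
  WE3 <- weighted_edges(triple)
  expect_true(all(WE3[upper.tri(WE3)] == 0.5))

  # a single-AE patient contributes nothing
  with_singleton <- events_from_sets(list(p1 = c("ae_i", "ae_j"), p2 = "ae_i"))
  expect_equal(weighted_edges(with_singleton)["ae_i", "ae_j"], 1)

  # conservation: each patient with n_p >= 2 distributes total weight n_p
  ev <- generate_cohort(cohort_config(n_patients = 120, n_aes = 60, n_clusters = 0,
                                      n_drugs = 0, n_diagnoses = 0, seed = 71))
  WE <- weighted_edges(ev)
  ae <- ev[ev$term_type == "AE", ]
  n_p <- table(ae$patient_id)
  expect_equal(sum(WE), sum(n_p[n_p >= 2]))
  expect_equal(WE, t(WE))
})

test_that("disparity alpha matches the closed form and its limits", {
  expect_equal(disparity_alpha(c(1, 1)), c(0.5, 0.5))       # k = 2, p = 1/2
  expect_equal(disparity_alpha(5), 1)                        # k = 1: no evidence
  a <- disparity_alpha(c(1000, 0.001, 0.001))
  expect_lt(a[1], 1e-6)                                      # p -> 1 gives alpha -> 0
  expect_gt(min(a[2:3]), 1 - 1e-2)                           # p -> 0 gives alpha -> 1
  expect_error(disparity_alpha(numeric(0)), "empty")
  expect_error(disparity_alpha(c(1, 0)), "positive")
  # closed form vs numerical quadrature of the defining integral
  for (k in c(2, 3, 7, 25)) {
    for (p in c(0.01, 0.2, 0.5, 0.9)) {
      quad <- 1 - (k - 1) * stats::integrate(function(x) (1 - x)^(k - 2),
                                             0, p, rel.tol = 1e-12)$value
      w <- c(p, rep((1 - p) / (k - 1), k - 1))
      expect_lt(abs(disparity_alpha(w)[1] - quad), 1e-10)
    }
  }
})

test_that("backbone extraction keeps concentrated edges and obeys its flags", {
  # star: node h splits weight over 6 edges, one of them dominant
  terms <- c("ae_h", sprintf("ae_l%02d", 1:6))
  W <- matrix(0, 7, 7, dimnames = list(terms, terms))
  W["ae_h", "ae_l01"] <- W["ae_l01", "ae_h"] <- 100
  for (i in 2:6) {
    W["ae_h", terms[i + 1]] <- W[terms[i + 1], "ae_h"] <- 0.05
  }
  net <- extract_backbone(W, alpha = 0.01, drop_top_prevalent = 0)
  key <- paste(net$edges$ae_i, net$edges$ae_j)
  expect_true("ae_h ae_l01" %in% key)
  expect_equal(nrow(net$edges), 1L)  # uniform leaf edges are not significant

  all_kept <- extract_backbone(W, alpha = 1, drop_top_prevalent = 0)
  expect_equal(nrow(all_kept$edges), sum(W[upper.tri(W)] > 0))

  # "both" rule is a subset of "either"
  either <- extract_backbone(W, alpha = 0.3, drop_top_prevalent = 0)
  both <- extract_backbone(W, alpha = 0.3, drop_top_prevalent = 0, rule = "both")
  expect_true(all(paste(both$edges$ae_i, both$edges$ae_j) %in%
                    paste(either$edges$ae_i, either$edges$ae_j)))

  # prevalence-based removal drops the most prevalent terms before extraction
  prev <- tibble::tibble(term = terms, n_patients = c(10L, 9L, rep(1L, 5)),
                         prevalence = NA_real_)
  dropped <- extract_backbone(W, alpha = 1, drop_top_prevalent = 2,
                              prevalence = prev)
  expect_false(any(c("ae_h", "ae_l01") %in% dropped$nodes$term))
  expect_error(extract_backbone(W, drop_top_prevalent = 2), "prevalence")
  expect_error(extract_backbone(W[, c(2:7, 1)]), "symmetric")
})

test_that("the score network flags a planted pair and respects alpha", {
  cfg <- cohort_config(n_patients = 300, n_aes = 60, n_clusters = 0,
                       planted_pairs = list(c(20, 25, 0.15)),
                       n_drugs = 0, n_diagnoses = 0, seed = 81)
  ev <- generate_cohort(cfg)
  net <- score_network(ev, alpha = 0.01)
  expect_true("ae_0020\rae_0025" %in%
                paste(net$edges$ae_i, net$edges$ae_j, sep = "\r"))
  # nodes are exactly the incident AEs, sized by prevalence fraction
  expect_setequal(net$nodes$term, unique(c(net$edges$ae_i, net$edges$ae_j)))
  prev <- ae_prevalence(ev)
  expect_equal(net$nodes$prevalence,
               prev$prevalence[match(net$nodes$term, prev$term)])
  empty <- score_network(ev, alpha = 0)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("observed-pairs correction only tests co-occurring pairs", {
  ev <- generate_null_cohort(80, 25, seed = 5)
  st <- pair_stats(ev, m_mode = "observed_pairs")
  expect_true(all(is.na(st$bh_p[st$n_AB == 0])))
  expect_equal(attr(st, "n_tests"), sum(st$n_AB > 0))
  expect_false(any(st$significant[st$n_AB == 0]))
  st_all <- pair_stats(ev, m_mode = "all_pairs")
  expect_equal(attr(st_all, "n_tests"), nrow(st_all))
})
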