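# Independent reference implementations used to cross-check the package.

# One-sided (enrichment) Fisher p by explicit hypergeometric enumeration.
enum_fisher_greater <- function(n_AB, n_A, n_B, n_tot) {
  lo <- max(0L, n_A + n_B - n_tot)
  hi <- min(n_A, n_B)
  support <- lo:hi
  mass <- choose(n_A, support) * choose(n_tot - n_A, n_B - support) /
    choose(n_tot, n_B)
  sum(mass[support >= n_AB])
}

# Classical BH step-up decision rule: reject the k smallest p-values where
# k is the largest rank with p_(k) <= k * alpha / m.
bh_reject_bruteforce <- function(p, m, alpha) {
  o <- order(p)
  ps <- p[o]
  ok <- ps <= seq_along(ps) * alpha / m
  k <- if (any(ok)) max(which(ok)) else 0L
  reject <- logical(length(p))
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Naive O(n^3) UPGMA agglomeration: repeatedly merge the pair of clusters
# with the smallest mean inter-cluster distance while it is below `cutoff`.
naive_average_linkage <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL
    bestv <- Inf
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        v <- mean(d[clusters[[i]], clusters[[j]]])
        if (v < bestv) {
          bestv <- v
          best <- c(i, j)
        }
      }
    }
    if (bestv >= cutoff) break
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# Label-invariant partition fingerprint.
canonical_partition <- function(labels) {
  groups <- split(seq_along(labels), labels)
  unname(sort(vapply(groups, function(g) paste(g, collapse = ","), character(1)),
              method = "radix"))
}
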