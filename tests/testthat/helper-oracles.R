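# Independent oracles used to cross-check the implementation.

# Connected components by brute-force transitive closure: boolean adjacency
# matrix powered until a fixed point, then rows compared for identity.
oracle_components <- function(rsids, pairs, r2_min) {
  n <- length(rsids)
  A <- diag(TRUE, n)
  dimnames(A) <- list(rsids, rsids)
  keep <- pairs$r2 >= r2_min & pairs$rsid_a %in% rsids & pairs$rsid_b %in% rsids
  for (i in which(keep)) {
    A[pairs$rsid_a[i], pairs$rsid_b[i]] <- TRUE
    A[pairs$rsid_b[i], pairs$rsid_a[i]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  # canonical partition: each variant keyed by the sorted member set it reaches
  split(rsids, apply(A, 1L, function(r) paste(sort(rsids[r]), collapse = "|")))
}

# canonical form of a partition (set of sorted member vectors, sorted)
canonical_partition <- function(groups) {
  unname(lapply(
    groups[order(vapply(lapply(groups, sort), paste, character(1), collapse = "|"))],
    sort
  ))
}

# AUC by exhaustive pair counting, ties at one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# random graph for clumping tests
random_ld_graph <- function(n, p_edge = 0.03) {
  rsids <- sprintf("rs%03d", seq_len(n))
  m <- max(1L, rbinom(1L, n * (n - 1L) / 2L, p_edge))
  data.frame(
    rsid_a = sample(rsids, m, replace = TRUE),
    rsid_b = sample(rsids, m, replace = TRUE),
    r2 = runif(m)
  )
}

variants_for <- function(rsids) {
  data.frame(
    rsid = rsids, chrom = "1",
    pos = seq(1e6, by = 1000, length.out = length(rsids))
  )
}
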