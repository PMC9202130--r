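test_that("FDR cutoffs reproduce exhaustive cutoff scans", {
  # pos {0.9, 0.8, 0.7}, neg {0.6, 0.5}: at t = 0.7 the empirical FDR is 0/3
  ft <- calibrate_fdr(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 1, 0, 0), levels = 0.01)
  expect_equal(ft$cutoff, 0.7)
  expect_equal(ft$achieved_fdr, 0)
  expect_equal(ft$n_called, 3L)

  # pos {0.9}, neg {0.95}: FDR at 0.9 is 1/2 -> 0.25 unattainable
  ft2 <- calibrate_fdr(c(0.9, 0.95), c(1, 0), levels = 0.25)
  expect_false(ft2$attainable)
  expect_true(is.na(ft2$cutoff))

  # all positives above all negatives: cutoff at the minimal positive score
  s <- c(0.8, 0.7, 0.6, 0.3, 0.2)
  ft3 <- calibrate_fdr(s, c(1, 1, 1, 0, 0), levels = 0.01)
  expect_equal(ft3$cutoff, 0.6)
  expect_equal(ft3$achieved_fdr, 0)
})

test_that("achieved FDR at each attainable cutoff satisfies its level", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- round(runif(n), 2)
    ft <- calibrate_fdr(s, y, levels = c(0.01, 0.1, 0.25, 0.5))
    for (j in which(ft$attainable)) {
      called <- s >= ft$cutoff[j]
      expect_lte(sum(called & y == 0) / sum(called), ft$level[j])
      # recomputation matches the stored achieved FDR
      expect_equal(sum(called & y == 0) / sum(called), ft$achieved_fdr[j])
    }
    # cutoffs monotone non-increasing in level
    ct <- ft$cutoff[ft$attainable]
    expect_true(all(diff(ct) <= 0))
  }
})

test_that("hit selection respects the cutoff boundary and exclusions", {
  ft <- calibrate_fdr(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 1, 0, 0), levels = c(0.01, 0.25))
  scores <- data.frame(
    rsid = c("a", "b", "c"), chrom = "1", pos = 1:3,
    score = c(0.95, 0.7, 0.69)
  )
  hits <- select_genomewide_hits(scores, ft, 0.01, training_positive_rsids = character())
  expect_setequal(hits$rsid, c("a", "b")) # score exactly at cutoff included
  hits2 <- select_genomewide_hits(scores, ft, 0.01, training_positive_rsids = "a")
  expect_setequal(hits2$rsid, "b")
  expect_equal(nrow(select_genomewide_hits(scores[0, ], ft, 0.01)), 0L)
  # unattainable level: empty with warning
  ft_un <- calibrate_fdr(c(0.9, 0.95), c(1, 0), levels = 0.01)
  expect_warning(h <- select_genomewide_hits(scores, ft_un, 0.01), "unattainable")
  expect_equal(nrow(h), 0L)
})

make_credsets <- function(sizes, scores_fun) {
  sets <- lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    data.frame(
      trait_group = "t", lead_rsid = sprintf("lead%d", i),
      member_rsid = sprintf("m%d_%d", i, seq_len(n)),
      chrom = "1", pos = seq_len(n)
    )
  })
  cs <- do.call(rbind, sets)
  list(cs = cs, scores = data.frame(rsid = cs$member_rsid, score = scores_fun(nrow(cs))))
}

test_that("credible-set reduction counts sets with a strict subset prioritized", {
  ft <- data.table::data.table(
    level = c(0.10, 0.25, 0.50), cutoff = c(0.8, 0.5, 0.2),
    achieved_fdr = c(0.1, 0.25, 0.5), n_called = 1:3, attainable = TRUE
  )
  # a set of 85 members with 3 above the 0.10 cutoff is reduced to 3
  x <- make_credsets(c(85, 3, 1), function(n) rep(0.1, n))
  x$scores$score[x$cs$lead_rsid == "lead1"][1:3] <- 0.9
  x$scores$score[x$cs$lead_rsid == "lead2"] <- 0.95 # all above: not reduced
  x$scores$score[x$cs$lead_rsid == "lead3"] <- 0.99 # singleton: not counted
  pr <- prioritize_credible_sets(x$cs, x$scores, ft, levels = c(0.10, 0.25, 0.50))
  s10 <- pr$summary[pr$summary$level == 0.10, ]
  expect_equal(s10$n_multi, 2L)
  expect_equal(s10$n_reduced, 1L)
  expect_equal(s10$fraction_reduced, 0.5)
  big <- pr$members[pr$members$lead_rsid == "lead1", ]
  expect_equal(sum(big$prioritized_0.1), 3L)
})

test_that("prioritized members are nested across FDR levels", {
  set.seed(31)
  ft <- data.table::data.table(
    level = c(0.10, 0.25, 0.50), cutoff = c(0.7, 0.45, 0.25),
    achieved_fdr = c(0.1, 0.25, 0.5), n_called = 1:3, attainable = TRUE
  )
  x <- make_credsets(sample(2:12, 8, TRUE), function(n) runif(n))
  pr <- prioritize_credible_sets(x$cs, x$scores, ft)
  m <- pr$members
  expect_true(all(!m$prioritized_0.1 | m$prioritized_0.25))
  expect_true(all(!m$prioritized_0.25 | m$prioritized_0.5))
})

test_that("reduction fraction is invariant to rsID relabeling", {
  set.seed(33)
  ft <- data.table::data.table(
    level = 0.25, cutoff = 0.5, achieved_fdr = 0.2, n_called = 5L, attainable = TRUE
  )
  x <- make_credsets(c(4, 6, 2), function(n) runif(n))
  pr1 <- prioritize_credible_sets(x$cs, x$scores, ft, levels = 0.25)
  relab <- function(v) paste0("X_", v)
  cs2 <- transform(x$cs,
    lead_rsid = relab(lead_rsid), member_rsid = relab(member_rsid)
  )
  sc2 <- transform(x$scores, rsid = relab(rsid))
  pr2 <- prioritize_credible_sets(cs2, sc2, ft, levels = 0.25)
  expect_equal(pr1$summary$fraction_reduced, pr2$summary$fraction_reduced)
})

test_that("members without scores are never prioritized", {
  ft <- data.table::data.table(
    level = 0.25, cutoff = 0.5, achieved_fdr = 0.2, n_called = 5L, attainable = TRUE
  )
  cs <- data.frame(
    trait_group = "t", lead_rsid = "lead1",
    member_rsid = c("a", "b"), chrom = "1", pos = 1:2
  )
  pr <- prioritize_credible_sets(cs, data.frame(rsid = "a", score = 0.9), ft, levels = 0.25)
  m <- pr$members
  expect_true(m$prioritized_0.25[m$member_rsid == "a"])
  expect_false(m$prioritized_0.25[m$member_rsid == "b"])
})

test_that("single-SNP scoring equals the singleton-locus encoding", {
  pl <- small_pipeline()
  b <- small_bundle()
  tr <- pl$traits$trait1
  # take singleton loci from the pipeline itself
  singles <- pl$loci$loci[pl$loci$loci$variant_count == 1L, ]$locus_id[1:10]
  mem <- pl$loci$members[pl$loci$members$locus_id %in% singles, ]
  snps <- data.frame(rsid = mem$rsid, chrom = mem$chrom, pos = mem$pos)
  sc <- score_snps(tr$model, snps, b$tracks, b$expr, b$cons,
    norm_constants = pl$features$norm_constants
  )
  locus_scores <- predict_scores(tr$model, pl$features$X[mem$locus_id, , drop = FALSE])
  expect_equal(
    sc$score[match(mem$rsid, sc$rsid)],
    unname(locus_scores),
    tolerance = 1e-12
  )
})

test_that("SNP scores increase with positively weighted track overlap", {
  pl <- small_pipeline()
  b <- small_bundle()
  model <- pl$traits$trait1$model
  beta_tracks <- model$beta[grep("^track", names(model$beta))]
  pos_tracks <- names(beta_tracks)[beta_tracks > 0]
  skip_if(length(pos_tracks) == 0, "model selected no positive track weights")
  # two synthetic SNPs far from all real loci: one overlapping every
  # positively weighted track, one overlapping nothing
  tracks <- rbind(
    as.data.frame(b$tracks),
    data.frame(track = pos_tracks, chrom = "21", start = 899999, end = 900001)
  )
  snps <- data.frame(rsid = c("hit", "nohit"), chrom = "21", pos = c(900000, 950000))
  sc <- score_snps(model, snps, tracks, b$expr, b$cons,
    norm_constants = pl$features$norm_constants
  )
  expect_gt(sc$score[sc$rsid == "hit"], sc$score[sc$rsid == "nohit"])
})
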