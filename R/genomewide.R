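#' Score individual SNPs with a trait model
#'
#' Each SNP is encoded as a one-variant locus: per-track overlap bits at the
#' SNP position, nearest-gene tissue bits at the SNP position, the SNP's own
#' conservation score (missing treated as 0), and the standardized variant
#' count of 1 under the training normalization constants. The encoding of a
#' singleton locus at the same position is identical, so locus and SNP
#' scores are mutually consistent.
#'
#' @param model A `tsabl_model`.
#' @param snps data.table `rsid`, `chrom`, `pos` (optionally `is_indel`).
#'   SNPs with missing chromosome or position are skipped with a warning.
#' @param tracks,expr,cons Annotation inputs as in [build_feature_matrix()].
#' @param norm_constants Variant-count normalization constants from the
#'   training feature build (`tsabl_features$norm_constants`).
#' @param config A [tsabl_config()].
#' @return data.table `rsid`, `chrom`, `pos`, `score`.
#' @export
score_snps <- function(model, snps, tracks, expr = NULL, cons = NULL,
                       norm_constants, config = tsabl_config()) {
  stopifnot(inherits(model, "tsabl_model"))
  sn <- as.data.table(snps)
  bad <- is.na(sn$chrom) | is.na(sn$pos)
  if (any(bad)) {
    warning(sprintf("score_snps: skipping %d SNPs with missing coordinates", sum(bad)))
    sn <- sn[!bad]
  }
  loci <- snps_as_singleton_loci(sn)
  feats <- build_feature_matrix(loci, tracks, expr, cons,
    config = config, norm_constants = norm_constants,
    track_names = model_track_names(model)
  )
  sc <- predict_scores(model, feats$X)
  out <- loci$loci[, .(locus_id, chrom, pos = span_min)]
  out[, rsid := loci$members$rsid[match(locus_id, loci$members$locus_id)]]
  out[, score := sc[locus_id]]
  out[order(chrom, pos), .(rsid, chrom, pos, score)]
}

# treat each SNP as its own locus (ids keep input identity)
snps_as_singleton_loci <- function(sn) {
  sn <- as.data.table(sn)
  if (!"is_indel" %in% names(sn)) sn[, is_indel := FALSE]
  sn[, chrom := norm_chrom(chrom)]
  ids <- sprintf("SNP%07d", seq_len(nrow(sn)))
  structure(list(
    members = data.table(
      locus_id = ids, rsid = sn$rsid, chrom = sn$chrom,
      pos = sn$pos, is_indel = sn$is_indel
    ),
    loci = data.table(
      locus_id = ids, chrom = sn$chrom, span_min = sn$pos,
      span_max = sn$pos, variant_count = 1L
    )
  ), class = "tsabl_loci")
}

# track feature names a model was trained with (so SNP encoding reproduces
# the training columns even for tracks absent near the scored SNPs)
model_track_names <- function(model) {
  setdiff(
    model$feature_names,
    c(
      "max_phastcons", "norm_variant_count",
      grep("^expr_", model$feature_names, value = TRUE)
    )
  )
}

#' Calibrate empirical FDR score cutoffs on the holdout
#'
#' For every candidate cutoff t (the distinct holdout scores, scanned from
#' high to low), the empirical FDR is the fraction of negatives among
#' holdout loci scoring at or above t. The cutoff for a level is the
#' smallest t whose empirical FDR does not exceed the level (the most
#' permissive calibrated threshold); a level with no such t is marked
#' unattainable. Cutoffs are computed from holdout data only.
#'
#' @param scores Holdout scores.
#' @param labels Holdout 0/1 labels (1 = positive).
#' @param levels FDR levels.
#' @return Object of class `tsabl_fdr`: data.table `level`, `cutoff`,
#'   `achieved_fdr`, `n_called`, `attainable`. Cutoffs are non-increasing
#'   in level.
#' @export
calibrate_fdr <- function(scores, labels, levels = c(0.01, 0.10, 0.25, 0.50)) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% 0:1))
  if (!any(y == 1L) || !any(y == 0L)) stop("calibrate_fdr: both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  neg <- cumsum(y[ord] == 0L)
  n_ge <- seq_along(s)
  # last index per distinct score = counts at threshold "score >= t"
  last <- which(!duplicated(s, fromLast = TRUE))
  t_vals <- s[last]
  fdr_hat <- neg[last] / n_ge[last]
  out <- rbindlist(lapply(sort(levels), function(a) {
    ok <- which(fdr_hat <= a)
    if (!length(ok)) {
      data.table(
        level = a, cutoff = NA_real_, achieved_fdr = NA_real_,
        n_called = 0L, attainable = FALSE
      )
    } else {
      i <- max(ok) # smallest qualifying t (t_vals is descending)
      data.table(
        level = a, cutoff = t_vals[i], achieved_fdr = fdr_hat[i],
        n_called = n_ge[last][i], attainable = TRUE
      )
    }
  }))
  structure(out, class = c("tsabl_fdr", class(out)))
}

fdr_cutoff <- function(fdr_table, level) {
  sel <- which(abs(fdr_table$level - level) < 1e-12)
  if (!length(sel)) stop(sprintf("FDR level %g not present in table", level))
  as.list(as.data.frame(fdr_table)[sel[1L], ])
}

#' Genome-wide hits at an FDR level
#'
#' SNPs scoring at or above the calibrated cutoff for `level`, excluding any
#' rsID used as a positive in model building.
#'
#' @param scores data.table from [score_snps()].
#' @param fdr_table A `tsabl_fdr` table.
#' @param level FDR level (must be present in the table).
#' @param training_positive_rsids rsIDs of model-building positives to
#'   exclude.
#' @return data.table subset of `scores`; empty (with a warning) when the
#'   level is unattainable.
#' @export
select_genomewide_hits <- function(scores, fdr_table, level = 0.01,
                                   training_positive_rsids = character()) {
  sc <- as.data.table(scores)
  row <- fdr_cutoff(fdr_table, level)
  if (!row$attainable) {
    warning(sprintf("FDR level %g unattainable on the calibration holdout", level))
    return(sc[0L])
  }
  sc[score >= row$cutoff & !rsid %in% training_positive_rsids]
}

#' Prioritize credible-set members
#'
#' For each credible set and FDR level, members scoring at or above the
#' calibrated cutoff are prioritized. A set is "reduced" at a level iff at
#' least one but fewer than all of its members are prioritized; the summary
#' reports the reduced fraction among multi-SNP sets (singleton sets are
#' excluded from the denominator). Members are also ranked by score within
#' each set for threshold-free use.
#'
#' @param credible_sets data.table `trait_group`, `lead_rsid`,
#'   `member_rsid`, `pos` (one row per member; the lead is among the
#'   members).
#' @param snp_scores data.table `rsid`, `score` (typically [score_snps()]
#'   output). Members without a score are never prioritized.
#' @param fdr_table A `tsabl_fdr` table.
#' @param levels FDR levels to apply (each present in the table).
#' @return List of class `tsabl_credsets`: `members` (input plus `score`,
#'   `rank` and one logical `prioritized_<level>` column per level) and
#'   `summary` (data.table `level`, `cutoff`, `n_sets`, `n_multi`,
#'   `n_reduced`, `fraction_reduced`).
#' @export
prioritize_credible_sets <- function(credible_sets, snp_scores, fdr_table,
                                     levels = c(0.10, 0.25, 0.50)) {
  cs <- as.data.table(credible_sets)
  stopifnot(all(c("trait_group", "lead_rsid", "member_rsid") %in% names(cs)))
  sc <- as.data.table(snp_scores)[, .(member_rsid = rsid, score)]
  cs <- sc[cs, on = "member_rsid"]
  cs[, rank := frank(-score, ties.method = "min", na.last = "keep"),
    by = .(trait_group, lead_rsid)
  ]
  summary <- vector("list", length(levels))
  for (k in seq_along(levels)) {
    lv <- levels[k]
    row <- fdr_cutoff(fdr_table, lv)
    col <- sprintf("prioritized_%g", lv)
    if (!row$attainable) {
      cs[, (col) := FALSE]
    } else {
      cs[, (col) := !is.na(score) & score >= row$cutoff]
    }
    per_set <- cs[, .(
      n_members = .N, n_prioritized = sum(.SD[[1L]])
    ), by = .(trait_group, lead_rsid), .SDcols = col]
    per_set[, reduced := n_prioritized >= 1L & n_prioritized < n_members]
    multi <- per_set[n_members > 1L]
    summary[[k]] <- data.table(
      level = lv, cutoff = row$cutoff, n_sets = nrow(per_set),
      n_multi = nrow(multi), n_reduced = sum(multi$reduced),
      fraction_reduced = if (nrow(multi)) mean(multi$reduced) else NA_real_
    )
  }
  setcolorder(cs, c("trait_group", "lead_rsid", "member_rsid"))
  structure(list(members = cs[], summary = rbindlist(summary)),
    class = "tsabl_credsets"
  )
}

#' @export
print.tsabl_credsets <- function(x, ...) {
  cat("<tsabl_credsets>\n")
  print(x$summary)
  invisible(x)
}
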