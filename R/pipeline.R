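#' Run the full trait-model pipeline on an input bundle
#'
#' Convenience driver covering the whole workflow for one or more trait
#' groups: association filtering, LD clumping, oversized-locus removal,
#' per-trait labeling, feature encoding, the constrained train/holdout
#' split, variant-count-matched designs in both partitions, repeated-trial
#' LASSO training, evaluation, and holdout FDR calibration.
#'
#' @param bundle A list with elements `variants`, `associations`,
#'   `ld_pairs`, `tracks`, `expr`, `cons`, `sumstats` (a
#'   [simulate_dataset()] bundle, or the same tables read from files).
#' @param trait_groups Trait groups to model; default: every group present
#'   in the filtered associations except `"other"`.
#' @param config A [tsabl_config()].
#' @param seed Seed for the split, the matching draws and the trial seeds.
#' @return List of class `tsabl_pipeline`: `loci`, `labels`, `features`,
#'   `split`, and per trait under `traits[[tg]]`: `design_train`,
#'   `design_holdout`, `model`, `training_auc`, `holdout_auc`, `fdr_table`,
#'   plus `evaluation` across traits.
#' @export
run_trait_pipeline <- function(bundle, trait_groups = NULL,
                               config = tsabl_config(), seed = config$rng_seed) {
  assoc <- filter_associations(bundle$associations, config)
  if (is.null(trait_groups)) {
    trait_groups <- setdiff(sort(unique(assoc$trait_group)), "other")
  }
  loci <- clump_loci(bundle$variants, bundle$ld_pairs, config$r2_clump)
  loci <- remove_large_loci(loci, config)
  labels <- rbindlist(lapply(trait_groups, function(tg) {
    label_loci(loci, assoc, bundle$sumstats, tg, config)
  }))
  features <- build_feature_matrix(loci, bundle$tracks, bundle$expr, bundle$cons, config)
  split <- split_train_holdout(loci, labels, config, seed = seed)

  counts <- loci$loci[, .(locus_id, variant_count)]
  traits <- setNames(lapply(trait_groups, function(tg) {
    lb <- labels[trait_group == tg]
    res <- list(trait_group = tg)
    designs <- lapply(c(train = "train", holdout = "holdout"), function(pt) {
      ids <- split[partition == pt, locus_id]
      match_negatives(
        counts[locus_id %in% intersect(ids, lb[label == "positive", locus_id])],
        counts[locus_id %in% intersect(ids, lb[label == "negative", locus_id])],
        tg, config,
        seed = seed + if (pt == "train") 1L else 2L, partition = pt
      )
    })
    res$design_train <- designs$train
    res$design_holdout <- designs$holdout
    xy_train <- design_xy(designs$train, features)
    xy_holdout <- design_xy(designs$holdout, features)
    res$model <- train_trait_model(xy_train$X, xy_train$y, config,
      base_seed = seed + 10L, trait_group = tg
    )
    res$training_auc <- res$model$training_auc
    holdout_scores <- predict_scores(res$model, xy_holdout$X)
    res$holdout_auc <- compute_auc(holdout_scores, xy_holdout$y)
    res$fdr_table <- calibrate_fdr(
      holdout_scores, xy_holdout$y,
      levels = sort(unique(c(config$genomewide_fdr, config$credset_fdr_levels)))
    )
    res$xy_holdout <- xy_holdout
    res
  }), trait_groups)

  evaluation <- evaluate_models(
    lapply(traits, `[[`, "model"),
    lapply(traits, `[[`, "xy_holdout"),
    config
  )
  structure(list(
    loci = loci, labels = labels, features = features, split = split,
    traits = traits, evaluation = evaluation, config = config, seed = seed
  ), class = "tsabl_pipeline")
}

#' @export
print.tsabl_pipeline <- function(x, ...) {
  cat(sprintf("<tsabl_pipeline> %d loci, %d traits (seed %d)\n",
              nrow(x$loci$loci), length(x$traits), x$seed))
  print(x$evaluation$summary)
  invisible(x)
}
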