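#' One LASSO model-building trial
#'
#' Standardizes the feature columns (constants kept), fits an L1-penalized
#' binomial logistic path over a geometric lambda grid (100 points from the
#' data-derived maximal lambda down four orders of magnitude), estimates the
#' per-lambda cross-validated AUC (mean and standard error over
#' class-stratified folds), selects the largest lambda whose mean CV AUC is
#' within one standard error of the maximum, and reports the full-data
#' coefficients at that lambda. The intercept is unpenalized.
#'
#' Folds are stratified by class; if a fold still misses a class the folds
#' are reshuffled with the next seed, up to 5 attempts.
#'
#' @param X Numeric feature matrix (rows = design loci).
#' @param y 0/1 labels.
#' @param folds Number of CV folds.
#' @param seed Integer seed for the fold assignment.
#' @param nlambda,lambda_min_ratio Lambda grid controls.
#' @param thresh Coordinate-descent convergence threshold; the default
#'   `1e-5` selects the same lambda and support as glmnet's stricter
#'   default on designs of this kind at roughly half the cost.
#' @return List with `intercept`, `beta` (named coefficient vector on the
#'   standardized scale, all features), `lambda_selected`, `lambda_best`
#'   (CV-AUC maximizer), `cv_curve` (data.table `lambda`, `auc_mean`,
#'   `auc_se`), `center`, `scale`, `seed`.
#' @export
fit_lasso_trial <- function(X, y, folds = 10L, seed = 1L,
                            nlambda = 100L, lambda_min_ratio = 1e-4,
                            thresh = 1e-5) {
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("fit_lasso_trial: both classes required")
  foldid <- make_stratified_folds(y, folds, seed)
  # the binary feature matrix is sparse; glmnet standardizes internally and
  # the fit is re-parameterized below onto the standardized scale, so the
  # stored center/scale reproduce the identical linear predictor
  cv <- glmnet::cv.glmnet(
    Matrix::Matrix(X, sparse = TRUE), y,
    family = "binomial", type.measure = "auc", foldid = foldid,
    standardize = TRUE, nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
    thresh = thresh
  )
  co <- as.numeric(stats::coef(cv, s = "lambda.1se"))
  names(co) <- c("(Intercept)", colnames(X))
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1 # constant columns pass through
  beta_raw <- co[-1L]
  list(
    intercept = co[[1L]] + sum(center * beta_raw),
    beta = beta_raw * scale,
    lambda_selected = cv$lambda.1se,
    lambda_best = cv$lambda.min,
    cv_curve = data.table(lambda = cv$lambda, auc_mean = cv$cvm, auc_se = cv$cvsd),
    center = center, scale = scale, seed = seed
  )
}

make_stratified_folds <- function(y, folds, seed) {
  for (attempt in 0:4) {
    rng <- local_rng(seed + 100L * attempt)
    foldid <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- rep_len(seq_len(folds), length(idx))[rng$sample_int(length(idx))]
    }
    ok <- all(vapply(
      split(y, foldid), function(yy) length(unique(yy)) == 2L, logical(1)
    ))
    if (ok) return(foldid)
  }
  stop("make_stratified_folds: could not build folds containing both classes")
}

#' Train a trait model over repeated trials
#'
#' Runs `n_trials` cross-validated LASSO trials (seeds `base_seed`,
#' `base_seed + 1`, ...), computes each trial's in-sample training AUC on the
#' full design, and returns the trial with the median training AUC (lower
#' median for an even count). Trials that fail are excluded; fewer than 3
#' surviving trials is an error.
#'
#' @param X,y Design matrix and 0/1 labels (see [design_xy()]).
#' @param config A [tsabl_config()].
#' @param base_seed First trial seed.
#' @param trait_group Trait group name recorded in the model.
#' @return Object of class `tsabl_model`: the selected trial's coefficients
#'   plus `training_auc`, `trials` (data.table `trial`, `seed`,
#'   `training_auc`, `selected`), `trait_group`, `feature_names`.
#' @export
train_trait_model <- function(X, y, config = tsabl_config(),
                              base_seed = config$rng_seed, trait_group = NA_character_) {
  seeds <- base_seed + seq_len(config$n_trials) - 1L
  fits <- vector("list", length(seeds))
  aucs <- rep(NA_real_, length(seeds))
  for (i in seq_along(seeds)) {
    fit <- tryCatch(
      fit_lasso_trial(X, y, folds = config$cv_folds, seed = seeds[i]),
      error = function(e) {
        warning(sprintf("trial %d failed: %s", i, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) next
    fits[[i]] <- fit
    aucs[i] <- compute_auc(predict_linear(fit, X), y)
  }
  ok <- which(!is.na(aucs))
  if (length(ok) < 3) stop("train_trait_model: fewer than 3 surviving trials")
  # ties broken by seed so selection does not depend on trial order
  sel <- ok[order(aucs[ok], seeds[ok])][lower_median_index(length(ok))]
  fit <- fits[[sel]]
  model <- structure(list(
    trait_group = trait_group,
    intercept = fit$intercept,
    beta = fit$beta,
    lambda_selected = fit$lambda_selected,
    lambda_best = fit$lambda_best,
    cv_curve = fit$cv_curve,
    center = fit$center, scale = fit$scale,
    feature_names = names(fit$beta),
    training_auc = aucs[sel],
    trials = data.table(
      trial = seq_along(seeds), seed = seeds,
      training_auc = aucs, selected = seq_along(seeds) == sel
    ),
    base_seed = base_seed
  ), class = "tsabl_model")
  model
}

# index of the median element in a sorted vector of length n (lower median
# for even n): 8th of 15, 2nd of 4
lower_median_index <- function(n) as.integer(floor((n + 1) / 2))

#' @export
print.tsabl_model <- function(x, ...) {
  cat(sprintf(
    "<tsabl_model> %s: %d nonzero of %d features, lambda = %.4g, training AUC = %.3f\n",
    x$trait_group, sum(x$beta != 0), length(x$beta), x$lambda_selected, x$training_auc
  ))
  invisible(x)
}

#' Nonzero coefficients of a trait model
#'
#' @param object A `tsabl_model`.
#' @param ... Unused.
#' @return data.table `feature`, `coefficient` (standardized scale),
#'   sorted by absolute value, nonzero entries only.
#' @export
coef.tsabl_model <- function(object, ...) {
  nz <- which(object$beta != 0)
  data.table(feature = names(object$beta)[nz], coefficient = object$beta[nz])[
    order(-abs(coefficient))
  ]
}

predict_linear <- function(model, X) {
  nz <- which(model$beta != 0)
  if (length(nz)) {
    feats <- names(model$beta)[nz]
    missing <- setdiff(feats, colnames(X))
    if (length(missing)) {
      stop("predict: feature columns missing from X: ", paste(missing, collapse = ", "))
    }
    Xs <- sweep(sweep(X[, feats, drop = FALSE], 2L, model$center[feats]),
      2L, model$scale[feats], "/"
    )
    drop(model$intercept + Xs %*% model$beta[nz])
  } else {
    rep(model$intercept, nrow(X))
  }
}

#' Score loci or SNPs with a trait model
#'
#' Applies the model's standardization constants and returns the logistic
#' probability `plogis(intercept + sum(coef * x))` per row.
#'
#' @param model A `tsabl_model`.
#' @param X Feature matrix whose columns include every nonzero-coefficient
#'   feature of the model (a missing one is a hard error naming it).
#' @return Numeric vector of scores in (0, 1), named by rownames of `X`.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "tsabl_model"))
  setNames(stats::plogis(predict_linear(model, X)), rownames(X))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, ties counting one half. Computed from rank sums.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% 0:1))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("compute_auc: both classes required")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate trait models on holdout designs
#'
#' Flags each model as informative when its own-trait holdout AUC is at
#' least `auc_pass` and the absolute training/holdout AUC difference is at
#' most `gap_pass`, and computes the full cross-trait AUC matrix (every
#' model scored on every trait's holdout design).
#'
#' @param models Named list of `tsabl_model` (names = trait groups).
#' @param holdout_xy Named list (same traits) of `list(X, y)` holdout
#'   designs (see [design_xy()]).
#' @param config A [tsabl_config()].
#' @return List of class `tsabl_evaluation`: `summary` (data.table
#'   `trait_group`, `training_auc`, `holdout_auc`, `gap`, `pass`) and
#'   `cross_auc` (matrix models x holdout traits).
#' @export
evaluate_models <- function(models, holdout_xy, config = tsabl_config()) {
  traits <- names(models)
  stopifnot(!is.null(traits), all(traits %in% names(holdout_xy)))
  cross <- matrix(NA_real_, length(traits), length(holdout_xy),
    dimnames = list(model = traits, holdout = names(holdout_xy))
  )
  for (m in traits) {
    for (h in names(holdout_xy)) {
      hx <- holdout_xy[[h]]
      cross[m, h] <- compute_auc(predict_scores(models[[m]], hx$X), hx$y)
    }
  }
  summary <- data.table(
    trait_group = traits,
    training_auc = vapply(models, `[[`, numeric(1), "training_auc"),
    holdout_auc = cross[cbind(traits, traits)]
  )
  summary[, gap := abs(training_auc - holdout_auc)]
  summary[, pass := is_informative(training_auc, holdout_auc, config)]
  structure(list(summary = summary, cross_auc = cross), class = "tsabl_evaluation")
}

#' @export
print.tsabl_evaluation <- function(x, ...) {
  cat("<tsabl_evaluation>\n")
  print(x$summary)
  invisible(x)
}

#' Coefficient report
#'
#' Tabulates a model's nonzero coefficients together with the feature class
#' and, when a track manifest is given, the annotation's source and tissue.
#'
#' @param model A `tsabl_model`.
#' @param features Optional `tsabl_features` the model was trained on
#'   (supplies the feature class column).
#' @param manifest Optional track manifest (`name`, and any of `source`,
#'   `type`, `sample`, `tissue`) merged onto track features.
#' @return data.table `feature`, `type`, (manifest columns,) `coefficient`,
#'   sorted by absolute coefficient.
#' @export
coefficient_report <- function(model, features = NULL, manifest = NULL) {
  out <- coef(model)
  if (!is.null(features)) {
    out[, type := unname(features$feature_type[feature])]
  }
  if (!is.null(manifest)) {
    mf <- as.data.table(manifest)
    keep <- intersect(c("name", "source", "type", "sample", "tissue"), names(mf))
    out <- merge(out, mf[, keep, with = FALSE],
      by.x = "feature", by.y = "name", all.x = TRUE, sort = FALSE
    )
  }
  out[order(-abs(coefficient))]
}

#' ROC curve points
#'
#' True- and false-positive rates at every distinct score threshold,
#' suitable for plotting holdout ROC curves.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return data.table `threshold`, `tpr`, `fpr` (thresholds descending,
#'   starting from above the maximum score).
#' @export
roc_points <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% 0:1))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tp <- cumsum(y[ord] == 1L)
  fp <- cumsum(y[ord] == 0L)
  last <- which(!duplicated(s, fromLast = TRUE))
  data.table(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp[last] / sum(y == 1L)),
    fpr = c(0, fp[last] / sum(y == 0L))
  )
}

#' Informativeness rule
#'
#' A model is informative when its holdout AUC reaches `auc_pass` and the
#' absolute training/holdout gap is at most `gap_pass`; both comparisons are
#' inclusive (a tiny epsilon guards against floating-point noise at the
#' boundary).
#'
#' @param training_auc,holdout_auc AUCs of the model.
#' @param config A [tsabl_config()].
#' @return Logical (vectorized).
#' @export
is_informative <- function(training_auc, holdout_auc, config = tsabl_config()) {
  eps <- 1e-9
  holdout_auc >= config$auc_pass - eps &
    abs(training_auc - holdout_auc) <= config$gap_pass + eps
}

#' Overlap-removed holdout loci
#'
#' For cross-trait comparison on a trait's holdout, removes loci that are
#' positive for both the in-focus trait and at least one other passing
#' trait (pleiotropic loci that would inflate cross-model agreement).
#' Negatives are untouched.
#'
#' @param trait_group In-focus trait.
#' @param labels Stacked per-trait labels (`locus_id`, `trait_group`,
#'   `label`).
#' @param passing_traits Traits whose models passed evaluation.
#' @param holdout_ids Locus ids of the in-focus trait's holdout design.
#' @return Character vector: `holdout_ids` minus the cross-positive loci.
#' @export
overlap_removed_holdout <- function(trait_group, labels, passing_traits, holdout_ids) {
  lb <- as.data.table(labels)
  tg <- trait_group
  focal_pos <- lb[trait_group == tg & label == "positive", locus_id]
  other_pos <- lb[trait_group %in% setdiff(passing_traits, tg) & label == "positive", locus_id]
  drop <- intersect(intersect(focal_pos, other_pos), holdout_ids)
  setdiff(holdout_ids, drop)
}

#' Locus-level aggregation of per-variant baseline scores
#'
#' Aggregates trait-agnostic per-variant scores (CADD/GWAVA/DeepSEA style)
#' to the locus level for benchmarking. `"max"` takes the highest member
#' score, with missing scores set to 0. `"one_minus_min"` is for scores
#' where smaller means more functional (DeepSEA e-values): the lowest member
#' score subtracted from 1, so all baselines share the higher-is-functional
#' orientation; members without a score are ignored, and a locus with no
#' scored member returns 0.
#'
#' @param locus_members data.table of the locus' variants (needs `rsid`).
#' @param scores data.table `rsid`, `score`.
#' @param mode `"max"` or `"one_minus_min"`.
#' @return A single locus-level score.
#' @export
baseline_locus_score <- function(locus_members, scores, mode = c("max", "one_minus_min")) {
  mode <- match.arg(mode)
  m <- as.data.table(locus_members)
  s <- as.data.table(scores)
  v <- s[m, on = "rsid"]$score
  if (mode == "max") {
    v[is.na(v)] <- 0
    if (!length(v)) 0 else max(v)
  } else {
    v <- v[!is.na(v)]
    if (!length(v)) 0 else 1 - min(v)
  }
}
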