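#' Constrained train/holdout split
#'
#' Splits loci into training and holdout sets while (1) preserving the
#' variant-count distribution — within every exact variant-count stratum,
#' `floor(train_frac * n)` loci go to training and the remainder to holdout —
#' and (2) keeping, for every trait, the number of training positives within
#' one locus of `train_frac` of that trait's positives. The stratum
#' assignment is randomized (seeded); a repair pass then swaps same-count
#' loci between the sets until every trait's constraint holds or a swap
#' budget of 10,000 is exhausted (then a warning). The result is
#' deterministic given the seed.
#'
#' @param loci A `tsabl_loci` object.
#' @param labels data.table of per-trait labels (rows `locus_id`,
#'   `trait_group`, `label`), e.g. stacked [label_loci()] output for every
#'   trait to be modeled.
#' @param config A [tsabl_config()].
#' @param seed Integer seed.
#' @return data.table `locus_id`, `partition` (`"train"` or `"holdout"`),
#'   covering every locus exactly once.
#' @export
split_train_holdout <- function(loci, labels, config = tsabl_config(),
                                seed = config$rng_seed) {
  stopifnot(inherits(loci, "tsabl_loci"))
  ls <- copy(loci$loci)[order(locus_id)]
  lb <- as.data.table(labels)

  # stage 1: per-stratum floor assignment, seeded order
  rng <- local_rng(seed)
  ls[, partition := {
    n_train <- floor(config$train_frac * .N)
    p <- rep("holdout", .N)
    p[rng$sample_int(.N, n_train)] <- "train"
    p
  }, by = variant_count]

  # stage 2: repair per-trait positive ratios by same-count swaps
  pos <- lb[label == "positive", .(locus_id, trait_group)]
  traits <- unique(pos$trait_group)
  small <- pos[, .N, by = trait_group][N < 3, trait_group]
  if (length(small)) {
    warning(sprintf(
      "split_train_holdout: traits with < 3 positives, ratio constraint skipped: %s",
      paste(small, collapse = ", ")
    ))
    traits <- setdiff(traits, small)
  }
  if (length(traits)) {
    part <- setNames(ls$partition, ls$locus_id)
    count <- setNames(ls$variant_count, ls$locus_id)
    pos_by_trait <- split(pos$locus_id, pos$trait_group)[traits]
    target <- vapply(pos_by_trait, function(id) config$train_frac * length(id), numeric(1))
    dev <- function() vapply(pos_by_trait, function(id) {
      abs(sum(part[id] == "train") - config$train_frac * length(id))
    }, numeric(1))
    swaps <- 0L
    repeat {
      d <- dev()
      bad <- names(d)[d > 1]
      if (!length(bad) || swaps >= 10000L) break
      tr <- bad[order(-d[bad])][1L]
      id <- pos_by_trait[[tr]]
      n_train <- sum(part[id] == "train")
      if (n_train < target[[tr]]) {
        from <- "holdout"; to <- "train"
      } else {
        from <- "train"; to <- "holdout"
      }
      # move a positive of tr from `from` to `to`, swapping with a same-count
      # locus not positive for tr; accept the first candidate (sorted order)
      # that lowers the total deviation
      cand_pos <- sort(id[part[id] == from])
      done <- FALSE
      for (cp in cand_pos) {
        others <- names(part)[part == to & count == count[[cp]] & !names(part) %in% id]
        for (co in sort(others)) {
          old <- c(part[[cp]], part[[co]])
          part[[cp]] <- to; part[[co]] <- from
          if (sum(dev()) < sum(d)) {
            done <- TRUE
            break
          }
          part[[cp]] <- old[1L]; part[[co]] <- old[2L]
        }
        if (done) break
      }
      if (!done) break
      swaps <- swaps + 1L
    }
    if (any(dev() > 1)) {
      warning("split_train_holdout: ratio constraint unmet for some traits after repair pass")
    }
    ls[, partition := part[locus_id]]
  }
  ls[order(locus_id), .(locus_id, partition)]
}

#' Variant-count-matched negative design
#'
#' Ties each positive locus to `negatives_per_positive` negatives of similar
#' variant count: a negative is eligible when the absolute count difference
#' is at most `match_tol_small` (positive count below `match_count_cutoff`)
#' or `match_tol_large` (at or above it). Positives are processed in
#' ascending variant-count order (ties by locus id); eligible negatives are
#' drawn uniformly without replacement (seeded), and each negative is used
#' at most once within the design. Positives with too few eligible negatives
#' are dropped and reported.
#'
#' @param positives data.table `locus_id`, `variant_count` of positive loci.
#' @param negative_pool data.table `locus_id`, `variant_count` of candidate
#'   negatives (same partition, same trait).
#' @param trait_group Trait group name (carried into the output).
#' @param config A [tsabl_config()].
#' @param seed Integer seed for the draws.
#' @param partition Partition tag carried into the output.
#' @return Object of class `tsabl_design`: list with `entries` (data.table
#'   `positive_id`, `negative_id`, one row per matched negative), `roles`
#'   (data.table `locus_id`, `role` in `{"positive","negative"}`),
#'   `dropped` (positive ids without a full match), `trait_group`,
#'   `partition`.
#' @export
match_negatives <- function(positives, negative_pool, trait_group,
                            config = tsabl_config(), seed = config$rng_seed,
                            partition = NA_character_) {
  pdt <- as.data.table(positives)[order(variant_count, locus_id)]
  pool <- as.data.table(negative_pool)
  if (!nrow(pool)) {
    warning("match_negatives: empty negative pool")
    return(empty_design(trait_group, partition, pdt$locus_id))
  }
  k <- config$negatives_per_positive
  rng <- local_rng(seed)
  avail <- setNames(pool$variant_count, pool$locus_id)
  entries <- vector("list", nrow(pdt))
  dropped <- character()
  for (i in seq_len(nrow(pdt))) {
    cp <- pdt$variant_count[i]
    tol <- if (cp < config$match_count_cutoff) config$match_tol_small else config$match_tol_large
    elig <- sort(names(avail)[abs(avail - cp) <= tol])
    if (length(elig) < k) {
      dropped <- c(dropped, pdt$locus_id[i])
      next
    }
    pick <- elig[rng$sample_int(length(elig), k)]
    avail <- avail[!names(avail) %in% pick]
    entries[[i]] <- data.table(positive_id = pdt$locus_id[i], negative_id = pick)
  }
  entries <- rbindlist(entries)
  if (!nrow(entries)) {
    entries <- data.table(positive_id = character(), negative_id = character())
  }
  if (length(dropped)) {
    message(sprintf("match_negatives [%s/%s]: dropped %d positives without %d eligible negatives",
                    trait_group, partition, length(dropped), k))
  }
  roles <- rbind(
    data.table(locus_id = unique(entries$positive_id), role = "positive"),
    data.table(locus_id = entries$negative_id, role = "negative")
  )
  structure(list(
    entries = entries, roles = roles[order(locus_id)], dropped = dropped,
    trait_group = trait_group, partition = partition
  ), class = "tsabl_design")
}

empty_design <- function(trait_group, partition, dropped) {
  structure(list(
    entries = data.table(positive_id = character(), negative_id = character()),
    roles = data.table(locus_id = character(), role = character()),
    dropped = dropped, trait_group = trait_group, partition = partition
  ), class = "tsabl_design")
}

#' @export
print.tsabl_design <- function(x, ...) {
  cat(sprintf(
    "<tsabl_design> %s/%s: %d positives x %d matched negatives (%d dropped)\n",
    x$trait_group, x$partition, length(unique(x$entries$positive_id)),
    nrow(x$entries) / max(1L, length(unique(x$entries$positive_id))),
    length(x$dropped)
  ))
  invisible(x)
}

#' Extract the model matrix and labels for a design
#'
#' @param design A `tsabl_design`.
#' @param features A `tsabl_features` built on a locus set covering the
#'   design's loci.
#' @return List `X` (matrix rows in design order), `y` (0/1 integer vector),
#'   `locus_id`.
#' @export
design_xy <- function(design, features) {
  stopifnot(inherits(design, "tsabl_design"), inherits(features, "tsabl_features"))
  ids <- c(unique(design$entries$positive_id), design$entries$negative_id)
  y <- c(
    rep(1L, length(unique(design$entries$positive_id))),
    rep(0L, nrow(design$entries))
  )
  missing <- setdiff(ids, rownames(features$X))
  if (length(missing)) stop("design loci missing from feature matrix: ", paste(head(missing), collapse = ", "))
  list(X = features$X[ids, , drop = FALSE], y = y, locus_id = ids)
}

# seeded RNG helper that does not disturb the global stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    sample_int = function(n, size = n) with_state(sample.int(n, size)),
    runif = function(n, ...) with_state(runif(n, ...))
  )
}
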