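#' Readers and writers for the tab-delimited file dialects
#'
#' All pipeline inputs and outputs are plain tab-delimited text with
#' headers. `read_associations` expects `rsid`, `chrom`, `pos`, `phenotype`,
#' `trait_group`, `pvalue` (optional `description`); `read_ld_pairs` accepts
#' PLINK `--r2`-style columns (`SNP_A`, `SNP_B`, `R2`; extra columns
#' ignored) or `rsid_a`/`rsid_b`/`r2`; `read_bed_track` reads BED3+ with a
#' supplied track name; `read_track_manifest` reads a manifest TSV (`name`,
#' `file`, optional `source`, `type`, `sample`, `tissue`) and loads every
#' listed BED file relative to the manifest's directory; `read_expression`
#' reads `gene_id`, `chrom`, `start` plus one numeric column per tissue;
#' `read_conservation` reads `rsid`, `score`; `read_credible_sets` reads
#' `trait_group`, `lead_rsid`, `member_rsid`, `chrom`, `pos`;
#' `read_sumstats` reads `rsid`, `trait_group`, `phenotype`, `pvalue`.
#'
#' @param path File path.
#' @return A data.table (see above for the columns of each reader).
#' @name tsabl_io
NULL

#' @rdname tsabl_io
#' @export
read_associations <- function(path) fread_checked(path, c("rsid", "chrom", "pos", "phenotype", "trait_group", "pvalue"))

#' @rdname tsabl_io
#' @export
read_ld_pairs <- function(path) {
  dt <- fread(path)
  map <- c(SNP_A = "rsid_a", SNP_B = "rsid_b", R2 = "r2")
  for (from in names(map)) {
    if (from %in% names(dt) && !map[[from]] %in% names(dt)) setnames(dt, from, map[[from]])
  }
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(dt)))
  dt[, .(rsid_a, rsid_b, r2)]
}

#' @rdname tsabl_io
#' @param track_name Track label attached to the intervals.
#' @export
read_bed_track <- function(path, track_name) {
  dt <- fread(path, header = FALSE)
  stopifnot(ncol(dt) >= 3L)
  setnames(dt, 1:3, c("chrom", "start", "end"))
  dt[, .(track = track_name, chrom = as.character(chrom), start, end)]
}

#' @rdname tsabl_io
#' @export
read_track_manifest <- function(path) {
  mf <- fread(path)
  stopifnot(all(c("name", "file") %in% names(mf)))
  if (anyDuplicated(mf$name)) stop("duplicate track names in manifest")
  base <- dirname(path)
  rbindlist(lapply(seq_len(nrow(mf)), function(i) {
    f <- mf$file[i]
    if (!file.exists(f)) f <- file.path(base, f)
    read_bed_track(f, mf$name[i])
  }))
}

#' @rdname tsabl_io
#' @export
read_expression <- function(path) fread_checked(path, c("gene_id", "chrom", "start"))

#' @rdname tsabl_io
#' @export
read_conservation <- function(path) fread_checked(path, c("rsid", "score"))

#' @rdname tsabl_io
#' @export
read_credible_sets <- function(path) fread_checked(path, c("trait_group", "lead_rsid", "member_rsid", "pos"))

#' @rdname tsabl_io
#' @export
read_sumstats <- function(path) fread_checked(path, c("rsid", "trait_group", "pvalue"))

fread_checked <- function(path, need) {
  dt <- fread(path)
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  dt
}

#' Write the locus table
#'
#' One row per variant: `locus_id`, `rsid`, `chrom`, `pos`.
#'
#' @param loci A `tsabl_loci` object.
#' @param path Output TSV path.
#' @export
write_locus_table <- function(loci, path) {
  fwrite(loci$members[, .(locus_id, rsid, chrom, pos)], path, sep = "\t")
  invisible(path)
}

#' Write a feature matrix as TSV
#'
#' Loci in rows (first column `locus_id`), features in columns.
#'
#' @param features A `tsabl_features` object.
#' @param path Output TSV path.
#' @export
write_feature_matrix <- function(features, path) {
  dt <- data.table(locus_id = rownames(features$X))
  fwrite(cbind(dt, as.data.table(features$X)), path, sep = "\t")
  invisible(path)
}

#' Save / load a trait model as JSON
#'
#' The artifact stores the intercept, the full coefficient vector,
#' the selected lambda, standardization and variant-count normalization
#' constants, seeds and AUCs — everything needed to score new loci or SNPs.
#'
#' @param model A `tsabl_model`.
#' @param path JSON path.
#' @param norm_constants Optional variant-count normalization constants to
#'   store alongside the model.
#' @export
write_model_json <- function(model, path, norm_constants = NULL) {
  obj <- list(
    trait_group = model$trait_group,
    intercept = model$intercept,
    beta = as.list(model$beta[model$beta != 0]),
    feature_names = model$feature_names,
    lambda_selected = model$lambda_selected,
    lambda_best = model$lambda_best,
    center = as.list(model$center),
    scale = as.list(model$scale),
    training_auc = model$training_auc,
    trials = model$trials,
    base_seed = model$base_seed,
    norm_constants = norm_constants
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- setNames(rep(0, length(obj$feature_names)), obj$feature_names)
  beta[names(obj$beta)] <- unlist(obj$beta)
  structure(list(
    trait_group = obj$trait_group,
    intercept = obj$intercept,
    beta = beta,
    lambda_selected = obj$lambda_selected,
    lambda_best = obj$lambda_best,
    cv_curve = NULL,
    center = unlist(obj$center),
    scale = unlist(obj$scale),
    feature_names = obj$feature_names,
    training_auc = obj$training_auc,
    trials = as.data.table(obj$trials),
    base_seed = obj$base_seed,
    norm_constants = obj$norm_constants
  ), class = "tsabl_model")
}

#' Write a simulated bundle to disk
#'
#' Writes every component of a [simulate_dataset()] bundle in the file
#' dialects the pipeline readers consume: `associations.tsv`,
#' `ld_pairs.tsv`, `variants.tsv`, one BED file per track plus
#' `tracks_manifest.tsv`, `expression.tsv`, `conservation.tsv`,
#' `sumstats.tsv`, `credible_sets.tsv`, and `ground_truth.json`.
#'
#' @param bundle A `tsabl_sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "tsabl_sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(bundle$associations, file.path(dir, "associations.tsv"), sep = "\t")
  fwrite(bundle$ld_pairs, file.path(dir, "ld_pairs.tsv"), sep = "\t")
  fwrite(bundle$variants, file.path(dir, "variants.tsv"), sep = "\t")
  fwrite(bundle$expr, file.path(dir, "expression.tsv"), sep = "\t")
  fwrite(bundle$cons, file.path(dir, "conservation.tsv"), sep = "\t")
  fwrite(bundle$sumstats, file.path(dir, "sumstats.tsv"), sep = "\t")
  fwrite(bundle$credible_sets, file.path(dir, "credible_sets.tsv"), sep = "\t")
  bed_dir <- file.path(dir, "tracks")
  dir.create(bed_dir, showWarnings = FALSE)
  tr <- split(bundle$tracks, bundle$tracks$track)
  for (nm in names(tr)) {
    fwrite(tr[[nm]][, .(chrom, start, end)], file.path(bed_dir, paste0(nm, ".bed")),
      sep = "\t", col.names = FALSE
    )
  }
  manifest <- data.table(
    name = names(tr),
    file = file.path("tracks", paste0(names(tr), ".bed"))
  )
  fwrite(manifest, file.path(dir, "tracks_manifest.tsv"), sep = "\t")
  jsonlite::write_json(
    list(
      membership = bundle$truth$membership,
      labels = bundle$truth$labels,
      informative_tracks = bundle$truth$informative_tracks,
      trait_tissue = bundle$truth$trait_tissue,
      causal = bundle$truth$causal
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
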