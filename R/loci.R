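#' Filter raw association records
#'
#' Applies the association-level filters used to define lead GWAS variants:
#' records are removed when the p-value is missing or above the genome-wide
#' threshold, the rsID is missing or lists multiple identifiers, the
#' chromosome is X, missing, non-autosomal or lists multiple chromosomes,
#' the description marks an interaction effect, or the position falls inside
#' the HLA region. Survivors are de-duplicated to one record per
#' (rsID, phenotype), keeping the smallest p-value.
#'
#' @param records data.frame/data.table with columns `rsid`, `chrom`, `pos`,
#'   `phenotype`, `trait_group`, `pvalue` and optionally `description`.
#'   Malformed rows are dropped with a message, never an error.
#' @param config A [tsabl_config()].
#' @return data.table of surviving association records (columns `rsid`,
#'   `chrom`, `pos`, `phenotype`, `trait_group`, `pvalue`).
#' @export
filter_associations <- function(records, config = tsabl_config()) {
  dt <- as.data.table(records)
  need <- c("rsid", "chrom", "pos", "phenotype", "trait_group", "pvalue")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing association columns: ", paste(miss, collapse = ", "))
  n0 <- nrow(dt)
  dt[, pvalue := suppressWarnings(as.numeric(pvalue))]
  dt[, pos := suppressWarnings(as.integer(pos))]
  dt[, chrom := norm_chrom(chrom)]

  bad_p <- is.na(dt$pvalue) | dt$pvalue > config$p_positive | dt$pvalue <= 0
  multi_re <- "[;,[:space:]]"
  bad_rs <- is.na(dt$rsid) | dt$rsid == "" | grepl(multi_re, dt$rsid)
  bad_chr <- is.na(dt$chrom) | dt$chrom == "" | toupper(dt$chrom) %in% c("X", "Y", "MT", "NA") |
    grepl(multi_re, dt$chrom) | is.na(dt$pos)
  desc <- if ("description" %in% names(dt)) paste(dt$description, dt$phenotype) else dt$phenotype
  kw <- paste(config$interaction_keywords, collapse = "|")
  bad_int <- grepl(kw, desc, ignore.case = TRUE)
  bad_hla <- !is.na(dt$pos) & !is.na(dt$chrom) & dt$chrom == config$hla_chrom &
    dt$pos >= config$hla_start & dt$pos <= config$hla_end

  drop <- bad_p | bad_rs | bad_chr | bad_int | bad_hla
  if (any(drop)) {
    message(sprintf(
      "filter_associations: dropped %d/%d records (p-value %d, rsID %d, chromosome %d, interaction %d, HLA %d)",
      sum(drop), n0, sum(bad_p), sum(bad_rs & !bad_p),
      sum(bad_chr & !bad_p & !bad_rs), sum(bad_int & !bad_p & !bad_rs & !bad_chr),
      sum(bad_hla & !bad_p & !bad_rs & !bad_chr & !bad_int)
    ))
  }
  dt <- dt[!drop]
  # one record per rsID-phenotype, keeping the strongest association
  dt <- dt[order(pvalue)][, head(.SD, 1L), by = .(rsid, phenotype)]
  setcolorder(dt, need)
  dt[order(chrom, pos, rsid)]
}

#' Build loci by transitive LD clumping
#'
#' Variants belong to the same locus when they are connected, directly or
#' transitively, by pairwise LD with R-squared at or above `r2_min`. Loci are
#' the connected components of the graph on the supplied variants with an
#' edge for every qualifying LD pair; variants with no qualifying pair form
#' singleton loci.
#'
#' @param variants data.frame/data.table with columns `rsid`, `chrom`, `pos`
#'   and optionally `is_indel` — the lead variants plus all proxies.
#' @param ld_pairs data.frame/data.table with columns `rsid_a`, `rsid_b`,
#'   `r2` (PLINK `--r2` style; extra columns ignored). Pairs referencing an
#'   rsID absent from `variants` are ignored with a warning.
#' @param r2_min Minimum R-squared for an edge.
#' @return An object of class `tsabl_loci`: a list with `members`
#'   (data.table `locus_id`, `rsid`, `chrom`, `pos`, `is_indel`) and `loci`
#'   (data.table `locus_id`, `chrom`, `span_min`, `span_max`,
#'   `variant_count`). Locus identifiers are assigned in genome order, so
#'   the result is independent of input row order.
#' @export
clump_loci <- function(variants, ld_pairs, r2_min = 0.7) {
  v <- as.data.table(variants)
  stopifnot(all(c("rsid", "chrom", "pos") %in% names(v)))
  v <- unique(v, by = "rsid")
  v[, chrom := norm_chrom(chrom)]
  if (!"is_indel" %in% names(v)) v[, is_indel := FALSE]

  p <- as.data.table(ld_pairs)
  plink_names <- c(SNP_A = "rsid_a", SNP_B = "rsid_b", R2 = "r2")
  for (nm in names(plink_names)) {
    if (nm %in% names(p) && !plink_names[[nm]] %in% names(p)) {
      setnames(p, nm, plink_names[[nm]])
    }
  }
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(p)))
  p <- p[r2 >= r2_min, .(rsid_a, rsid_b)]
  known <- p$rsid_a %in% v$rsid & p$rsid_b %in% v$rsid
  if (any(!known)) {
    warning(sprintf("clump_loci: ignoring %d LD pairs referencing unknown rsIDs", sum(!known)))
    p <- p[known]
  }

  g <- igraph::graph_from_data_frame(p[, .(rsid_a, rsid_b)],
    directed = FALSE, vertices = v$rsid
  )
  comp <- igraph::components(g)$membership[v$rsid]
  v[, locus_id := comp]
  loci <- v[, .(
    chrom = chrom[1L], span_min = min(pos), span_max = max(pos),
    variant_count = .N, multi_chrom = uniqueN(chrom) > 1L
  ), by = locus_id]
  if (any(loci$multi_chrom)) {
    warning("clump_loci: some loci span multiple chromosomes; span uses the first")
  }
  loci[, multi_chrom := NULL]
  # deterministic genome-order identifiers
  setorder(loci, chrom, span_min, span_max, locus_id)
  new_ids <- sprintf("L%05d", seq_len(nrow(loci)))
  v[, locus_id := new_ids[match(locus_id, loci$locus_id)]]
  loci[, locus_id := new_ids]
  setcolorder(loci, c("locus_id", "chrom", "span_min", "span_max", "variant_count"))
  members <- v[order(locus_id, pos, rsid), .(locus_id, rsid, chrom, pos, is_indel)]
  structure(list(members = members, loci = loci[order(locus_id)]), class = "tsabl_loci")
}

#' @export
print.tsabl_loci <- function(x, ...) {
  cat(sprintf(
    "<tsabl_loci> %d loci, %d variants (median %d variants/locus)\n",
    nrow(x$loci), nrow(x$members), as.integer(median(x$loci$variant_count))
  ))
  invisible(x)
}

#' Label loci for a trait group
#'
#' A locus is `positive` for a trait group when any member variant has a
#' filtered association with any phenotype of the group (p below the
#' genome-wide threshold). A non-positive locus is `excluded` when any member
#' shows even modest association (p below `p_negative`) in available summary
#' statistics of the group, and `negative` otherwise. When no summary
#' statistics are supplied for the group, no modest-association removals are
#' possible and all non-positive loci are negative.
#'
#' @param loci A `tsabl_loci` object.
#' @param associations Filtered association records ([filter_associations()]).
#' @param sumstats Optional data.table of per-phenotype summary statistics
#'   with columns `rsid`, `trait_group`, `pvalue` (a `phenotype` column is
#'   allowed and ignored for labeling).
#' @param trait_group Trait group to label.
#' @param config A [tsabl_config()].
#' @return data.table `locus_id`, `trait_group`, `label` with exactly one row
#'   per locus; `label` is one of `"positive"`, `"negative"`, `"excluded"`.
#' @export
label_loci <- function(loci, associations, sumstats = NULL, trait_group,
                       config = tsabl_config()) {
  stopifnot(inherits(loci, "tsabl_loci"))
  tg <- trait_group
  assoc <- as.data.table(associations)[trait_group == tg & pvalue < config$p_positive]
  pos_ids <- unique(loci$members[assoc, on = "rsid", nomatch = NULL]$locus_id)

  excl_ids <- character()
  if (!is.null(sumstats)) {
    ss <- as.data.table(sumstats)
    ss <- ss[trait_group == tg & !is.na(pvalue)]
    if (nrow(ss)) {
      modest <- ss[pvalue < config$p_negative]
      excl_ids <- setdiff(unique(loci$members[modest, on = "rsid", nomatch = NULL]$locus_id), pos_ids)
    }
  }
  out <- data.table(locus_id = loci$loci$locus_id, trait_group = tg, label = "negative")
  out[locus_id %in% excl_ids, label := "excluded"]
  out[locus_id %in% pos_ids, label := "positive"]
  out[order(locus_id)]
}

#' Remove oversized loci
#'
#' Drops loci whose variant count exceeds `max_locus_variants` (typically
#' very long-range LD regions that would dominate interval overlap).
#'
#' @param loci A `tsabl_loci` object.
#' @param config A [tsabl_config()].
#' @return A `tsabl_loci` object without the oversized loci.
#' @export
remove_large_loci <- function(loci, config = tsabl_config()) {
  stopifnot(inherits(loci, "tsabl_loci"))
  big <- loci$loci[variant_count > config$max_locus_variants, locus_id]
  if (length(big)) {
    message(sprintf("remove_large_loci: removed %d loci with > %d variants",
                    length(big), config$max_locus_variants))
  }
  structure(list(
    members = loci$members[!locus_id %in% big],
    loci = loci$loci[!locus_id %in% big]
  ), class = "tsabl_loci")
}
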