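#' Variant-in-track overlap test
#'
#' A variant at 1-based position `pos` overlaps a 0-based half-open BED
#' interval `[start, end)` iff `pos - 1` falls inside it (bedtools
#' semantics). For indels only the start position is tested — the same rule,
#' applied to the recorded position, so deletions never pick up overlaps
#' downstream of their start.
#'
#' @param variant One-row data.frame/list with `chrom`, `pos` (and optionally
#'   `is_indel`, which does not change the test).
#' @param track data.frame/data.table of intervals with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return 1L if any interval contains the position, else 0L.
#' @export
variant_overlaps <- function(variant, track) {
  tr <- as.data.table(track)
  p0 <- as.integer(variant$pos) - 1L
  ch <- norm_chrom(variant$chrom)
  as.integer(any(norm_chrom(tr$chrom) == ch & tr$start <= p0 & p0 < tr$end))
}

#' Locus-level track bit
#'
#' A locus is coded 1 for a track iff any member variant overlaps any of the
#' track's intervals (logical OR over members).
#'
#' @param locus_members data.frame/data.table of the locus' variants
#'   (`chrom`, `pos`).
#' @param track Interval table as in [variant_overlaps()].
#' @return 1L or 0L.
#' @export
locus_track_bit <- function(locus_members, track) {
  m <- as.data.table(locus_members)
  as.integer(any(vapply(
    seq_len(nrow(m)), function(i) variant_overlaps(m[i], track), integer(1)
  ) == 1L))
}

# vectorized overlap: members (locus_id, chrom, pos) x intervals
# (track, chrom, start, end) -> unique (locus_id, track) hits
overlap_hits <- function(members, intervals) {
  m <- as.data.table(members)[, .(locus_id, chrom = norm_chrom(chrom), pos)]
  iv <- as.data.table(intervals)[, .(track, chrom = norm_chrom(chrom), start, end)]
  if (!nrow(iv) || !nrow(m)) {
    return(data.table(locus_id = character(), track = character()))
  }
  # closed-interval join on integer coordinates: point pos-1 in [start, end-1]
  m[, `:=`(pos0 = pos - 1L, pos1 = pos - 1L)]
  iv <- iv[, .(track, chrom, start = as.integer(start), end = as.integer(end) - 1L)]
  setkey(iv, chrom, start, end)
  hits <- foverlaps(m, iv,
    by.x = c("chrom", "pos0", "pos1"),
    by.y = c("chrom", "start", "end"), nomatch = NULL
  )
  unique(hits[, .(locus_id, track)])
}

#' Nearest-gene tissue-expression bits
#'
#' For each locus, the nearest gene is the expression-table gene on the same
#' chromosome whose start position is closest to the locus center (the
#' integer midpoint of the variant span; ties broken toward the smaller
#' start, then gene id). The locus gets a 1 in a tissue iff that gene's
#' specificity t-statistic ranks in the top `expr_top_fraction` of the
#' tissue's column (rank at most `ceiling(frac * n_genes)` by descending
#' t-statistic, ties broken by gene id).
#'
#' @param loci_summary data.table with `locus_id`, `chrom`, `span_min`,
#'   `span_max` (a single-SNP "locus" has `span_min == span_max == pos`).
#' @param expr Expression table: `gene_id`, `chrom`, `start`, then one
#'   numeric t-statistic column per tissue.
#' @param config A [tsabl_config()].
#' @return Integer matrix loci x tissues (rownames locus ids, colnames
#'   tissue names, sorted). Loci on chromosomes with no gene get all-zero
#'   rows with a warning.
#' @export
nearest_gene_bits <- function(loci_summary, expr, config = tsabl_config()) {
  ls <- as.data.table(loci_summary)
  ex <- as.data.table(expr)
  stopifnot(nrow(ex) > 0, all(c("gene_id", "chrom", "start") %in% names(ex)))
  tissues <- sort(setdiff(names(ex), c("gene_id", "chrom", "start")))
  ex <- ex[order(gene_id)]
  ex[, chrom := norm_chrom(chrom)]

  # top-decile membership per tissue: rank <= ceiling(frac * n)
  n_top <- ceiling(config$expr_top_fraction * nrow(ex))
  topmat <- sapply(tissues, function(tn) {
    r <- order(-ex[[tn]], ex$gene_id)
    bit <- integer(nrow(ex))
    bit[r[seq_len(n_top)]] <- 1L
    bit
  })
  rownames(topmat) <- ex$gene_id

  center <- as.integer(round((as.numeric(ls$span_min) + as.numeric(ls$span_max)) / 2))
  ch <- norm_chrom(ls$chrom)
  out <- matrix(0L, nrow(ls), length(tissues),
    dimnames = list(ls$locus_id, tissues)
  )
  orphan <- FALSE
  for (cc in unique(ch)) {
    gi <- which(ex$chrom == cc)
    li <- which(ch == cc)
    if (!length(gi)) {
      orphan <- TRUE
      next
    }
    gs <- ex$start[gi]
    ord <- order(gs, ex$gene_id[gi])
    gi <- gi[ord]; gs <- gs[ord]
    for (j in li) {
      d <- abs(gs - center[j])
      out[j, ] <- topmat[gi[which.min(d)], ]
    }
  }
  if (orphan) warning("nearest_gene_bits: loci on chromosomes without genes get all-zero expression bits")
  out
}

#' Maximum conservation score of a locus
#'
#' The locus score is the maximum per-variant conservation score over its
#' members; variants without a score contribute 0.
#'
#' @param locus_members data.table of the locus' variants (needs `rsid`).
#' @param scores data.frame/data.table `rsid`, `score`.
#' @return A single score (0 when no member has a score).
#' @export
locus_phastcons <- function(locus_members, scores) {
  m <- as.data.table(locus_members)
  s <- as.data.table(scores)
  v <- s[m, on = "rsid"]$score
  v[is.na(v)] <- 0
  if (!length(v)) 0 else max(v)
}

#' Standardize locus variant counts
#'
#' Z-scores the variant counts over the supplied locus set. The mean and
#' standard deviation are returned so later single-SNP scoring can encode a
#' SNP as a 1-variant locus under the same constants.
#'
#' @param counts Integer vector of per-locus variant counts.
#' @param constants Optional list `mean`, `sd` from a previous call; when
#'   supplied, counts are standardized with these instead of refitting.
#' @return List with `z` (standardized counts) and `constants`
#'   (`list(mean, sd)`). A zero or undefined standard deviation yields all
#'   zeros (with `sd` stored as 0).
#' @export
normalize_variant_counts <- function(counts, constants = NULL) {
  if (is.null(constants)) {
    m <- mean(counts)
    # population-style guard: single locus or constant counts give sd 0
    s <- if (length(counts) >= 2) sd(counts) else 0
    if (is.na(s)) s <- 0
    constants <- list(mean = m, sd = s)
  }
  z <- if (constants$sd > 0) (counts - constants$mean) / constants$sd else rep(0, length(counts))
  list(z = z, constants = constants)
}

#' Build the locus feature matrix
#'
#' Encodes each locus as: one binary overlap bit per annotation track
#' (logical OR over member variants), one binary bit per tissue from the
#' nearest gene's expression specificity, the maximum member conservation
#' score, and the standardized variant count. Columns are sorted by name
#' within each block (tracks, then tissues, then `max_phastcons`,
#' `norm_variant_count`), so the matrix is independent of input order.
#'
#' @param loci A `tsabl_loci` object.
#' @param tracks Interval table `track`, `chrom`, `start`, `end` (0-based
#'   half-open), all annotation tracks stacked; or a named list of per-track
#'   interval tables.
#' @param expr Expression table (see [nearest_gene_bits()]); `NULL` omits
#'   the tissue block.
#' @param cons Conservation scores `rsid`, `score`; `NULL` scores all loci 0.
#' @param config A [tsabl_config()].
#' @param norm_constants Optional variant-count normalization constants from
#'   a previous build (used when encoding SNPs under a trained model).
#' @param track_names Optional character vector of all track names, so
#'   tracks with no interval near any locus still get (all-zero) columns.
#' @return An object of class `tsabl_features`: list with `X` (numeric
#'   matrix, rownames locus ids), `feature_type` (named vector:
#'   `"track"`, `"expression"`, `"conservation"`, `"variant_count"`) and
#'   `norm_constants`.
#' @export
build_feature_matrix <- function(loci, tracks, expr = NULL, cons = NULL,
                                 config = tsabl_config(), norm_constants = NULL,
                                 track_names = NULL) {
  stopifnot(inherits(loci, "tsabl_loci"))
  if (is.list(tracks) && !is.data.frame(tracks)) {
    if (anyDuplicated(names(tracks))) stop("duplicate track names")
    tracks <- rbindlist(lapply(seq_along(tracks), function(i) {
      data.table(track = names(tracks)[i], as.data.table(tracks[[i]]))
    }))
  }
  tracks <- as.data.table(tracks)
  tnames <- sort(unique(c(as.character(tracks$track), track_names)))
  ids <- loci$loci$locus_id

  Xtr <- matrix(0L, length(ids), length(tnames), dimnames = list(ids, tnames))
  hits <- overlap_hits(loci$members, tracks)
  if (nrow(hits)) Xtr[cbind(hits$locus_id, hits$track)] <- 1L

  Xex <- NULL
  if (!is.null(expr)) {
    Xex <- nearest_gene_bits(loci$loci, expr, config)
    colnames(Xex) <- paste0("expr_", colnames(Xex))
  }

  pc <- rep(0, length(ids))
  if (!is.null(cons)) {
    cs <- as.data.table(cons)
    mx <- cs[loci$members, on = "rsid"][, .(m = max(c(score, 0), na.rm = TRUE)), by = locus_id]
    pc[match(mx$locus_id, ids)] <- mx$m
  }

  nv <- normalize_variant_counts(loci$loci$variant_count, norm_constants)
  X <- cbind(Xtr, Xex, max_phastcons = pc, norm_variant_count = nv$z)
  ftype <- c(
    setNames(rep("track", length(tnames)), tnames),
    if (!is.null(Xex)) setNames(rep("expression", ncol(Xex)), colnames(Xex)),
    max_phastcons = "conservation", norm_variant_count = "variant_count"
  )
  structure(list(X = X, feature_type = ftype[colnames(X)], norm_constants = nv$constants),
    class = "tsabl_features"
  )
}

#' @export
print.tsabl_features <- function(x, ...) {
  tab <- table(x$feature_type)
  cat(sprintf(
    "<tsabl_features> %d loci x %d features (%s)\n",
    nrow(x$X), ncol(x$X),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}
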