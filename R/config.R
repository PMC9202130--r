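#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline, with defaults
#' matching the published workflow. All downstream functions take a `config`
#' argument so alternative thresholds can be explored without touching code.
#'
#' @param r2_clump LD threshold: variants belong to one locus when connected
#'   (transitively) by pairwise R-squared at or above this value.
#' @param p_positive Genome-wide significance threshold; a locus is positive
#'   for a trait group if any member variant has an association p-value below
#'   this for any phenotype in the group.
#' @param p_negative Nominal association threshold; a non-positive locus is
#'   excluded from the negative pool when any member has p below this in the
#'   available summary statistics of the group.
#' @param hla_chrom,hla_start,hla_end HLA exclusion region (1-based
#'   inclusive, hg19 in the published analysis); associations inside it are
#'   dropped.
#' @param max_locus_variants Loci with more variants than this are removed.
#' @param negatives_per_positive Number of variant-count-matched negatives
#'   per positive locus in a design.
#' @param match_tol_small,match_tol_large,match_count_cutoff A negative
#'   matches a positive when the absolute variant-count difference is at most
#'   `match_tol_small` (positive count below `match_count_cutoff`) or
#'   `match_tol_large` (at or above it).
#' @param train_frac Fraction of loci assigned to training (the remainder is
#'   holdout).
#' @param cv_folds Folds for cross-validated lambda selection.
#' @param n_trials Number of model-building trials; the median-training-AUC
#'   trial becomes the trait model.
#' @param auc_pass,gap_pass A model is informative when its holdout AUC is at
#'   least `auc_pass` and |training AUC - holdout AUC| is at most `gap_pass`.
#' @param expr_top_fraction Fraction of genes counted as "specifically
#'   expressed" in a tissue (top of the tissue's t-statistic column).
#' @param genomewide_fdr FDR level for genome-wide SNP hit lists.
#' @param credset_fdr_levels FDR levels at which credible-set members are
#'   prioritized.
#' @param interaction_keywords Keywords (case-insensitive, matched against
#'   the phenotype/description fields) marking interaction-effect
#'   associations for removal.
#' @param rng_seed Default seed for seeded operations when none is given.
#'
#' @return A list of class `tsabl_config`.
#' @export
#' @examples
#' cfg <- tsabl_config()
#' cfg$r2_clump
tsabl_config <- function(r2_clump = 0.7,
                         p_positive = 5e-8,
                         p_negative = 0.05,
                         hla_chrom = "6",
                         hla_start = 29670261L,
                         hla_end = 33104175L,
                         max_locus_variants = 1000L,
                         negatives_per_positive = 6L,
                         match_tol_small = 10L,
                         match_tol_large = 50L,
                         match_count_cutoff = 100L,
                         train_frac = 2 / 3,
                         cv_folds = 10L,
                         n_trials = 15L,
                         auc_pass = 0.7,
                         gap_pass = 0.02,
                         expr_top_fraction = 0.10,
                         genomewide_fdr = 0.01,
                         credset_fdr_levels = c(0.10, 0.25, 0.50),
                         interaction_keywords = "interaction",
                         rng_seed = 1L) {
  cfg <- list(
    r2_clump = r2_clump, p_positive = p_positive, p_negative = p_negative,
    hla_chrom = norm_chrom(hla_chrom), hla_start = hla_start,
    hla_end = hla_end, max_locus_variants = max_locus_variants,
    negatives_per_positive = negatives_per_positive,
    match_tol_small = match_tol_small, match_tol_large = match_tol_large,
    match_count_cutoff = match_count_cutoff, train_frac = train_frac,
    cv_folds = cv_folds, n_trials = n_trials, auc_pass = auc_pass,
    gap_pass = gap_pass, expr_top_fraction = expr_top_fraction,
    genomewide_fdr = genomewide_fdr,
    credset_fdr_levels = sort(credset_fdr_levels),
    interaction_keywords = interaction_keywords, rng_seed = rng_seed
  )
  stopifnot(
    cfg$r2_clump > 0, cfg$r2_clump <= 1,
    cfg$p_positive > 0, cfg$p_negative > 0,
    cfg$train_frac > 0, cfg$train_frac < 1,
    cfg$negatives_per_positive >= 1, cfg$n_trials >= 1,
    cfg$expr_top_fraction > 0, cfg$expr_top_fraction < 1
  )
  structure(cfg, class = "tsabl_config")
}

# strip a leading "chr" so "chr6" and "6" compare equal
norm_chrom <- function(x) sub("^chr", "", as.character(x))
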