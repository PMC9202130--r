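# Shared fixtures: a small simulated bundle and a trained small pipeline,
# built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, expr, .fixture_env)
  get(key, .fixture_env)
}

small_sim_config <- function(seed = 42L, ...) {
  sim_config(
    n_pos_per_trait = 60L, n_neg_pool = 600L, n_excluded = 30L,
    n_tracks = 40L, n_informative = 8L, enrich_odds = 5,
    n_tissues = 10L, n_bg_genes = 100L, seed = seed, ...
  )
}

small_bundle <- function() memo("small_bundle", simulate_dataset(small_sim_config()))

# pipeline on the small bundle with a reduced trial count (enough structure
# for the unit tests; the acceptance suite runs the full protocol)
small_pipeline <- function() {
  memo("small_pipeline", {
    cfg <- tsabl_config(n_trials = 5L)
    suppressMessages(run_trait_pipeline(small_bundle(), config = cfg, seed = 42L))
  })
}

# map pipeline locus ids to generator locus keys via shared member rsids
sim_locus_of <- function(loci, truth) {
  m <- merge(loci$members[, c("locus_id", "rsid")], truth$membership, by = "rsid")
  unique(m[, c("locus_id", "sim_locus")])
}

# tiny deterministic locus set: k singleton "loci" at given positions
toy_loci <- function(pos, chrom = "1", prefix = "rs") {
  v <- data.frame(
    rsid = paste0(prefix, seq_along(pos)), chrom = chrom, pos = pos
  )
  clump_loci(v, data.frame(rsid_a = character(), rsid_b = character(), r2 = numeric()))
}
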