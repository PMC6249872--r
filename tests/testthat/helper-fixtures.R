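# Shared fixtures, built once per test run and memoised here.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, envir = .fx_cache))
    assign(key, builder(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# 3 genes + 1 decoy, SNVs concentrated in primer-prone exon ends
fx_small <- function() fx_memo("small", function()
  generate_fixture(fixture_spec(seed = 7, n_genes = 3, n_planted_snvs = 10,
                                snv_placement = "primer_window",
                                n_decoy_paralogs = 1)))

# 5 genes, used for pipeline-level tests
fx_medium <- function() fx_memo("medium", function()
  generate_fixture(fixture_spec(seed = 11, n_genes = 5, n_planted_snvs = 20,
                                snv_placement = "primer_window",
                                n_decoy_paralogs = 1)))

# short transcripts (<= 1 kb) for exhaustive-oracle comparisons
fx_short_tx <- function() fx_memo("short_tx", function()
  generate_fixture(fixture_spec(seed = 13, n_genes = 4,
                                gene_length = c(700, 1000),
                                n_planted_snvs = 6, n_decoy_paralogs = 1)))

# 50-gene run used by the selection-optimality and conservation checks
pipeline_50 <- function() fx_memo("pipeline_50", function() {
  tr <- generate_fixture(fixture_spec(seed = 707, n_genes = 50,
                                      variants_per_gene = c(1, 3),
                                      n_planted_snvs = 120,
                                      snv_placement = "primer_window",
                                      n_decoy_paralogs = 5))
  cfg <- run_config(targets = tr$targets,
                    generation = generation_config(n_pairs_requested = 30),
                    structure_backend = "vienna", workers = 1L, seed = 6L)
  run_pipeline(cfg, bundle = tr$bundle)
})

rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# target record for generate_candidates without a bundle
fake_target <- function(sequence, id = "TX1", gene = "G1") {
  list(transcript_id = id, gene_id = gene, sequence = sequence)
}

# one-row candidate "pair" for screen-level unit tests
fake_pair <- function(fwd_seq, rev_seq, product_size,
                      pair_id = "T:P0001", target_id = "T",
                      gene_id = "G", penalty_rank = 0L) {
  data.frame(pair_id = pair_id, target_id = target_id, gene_id = gene_id,
             fwd_seq = fwd_seq, rev_seq = rev_seq,
             fwd_start = 1L, fwd_end = nchar(fwd_seq),
             rev_start = product_size - nchar(rev_seq) + 1L,
             rev_end = product_size, product_size = product_size,
             tm_fwd = 60, tm_rev = 60, penalty_rank = penalty_rank,
             crosshyb_fail = FALSE, snp_fail = FALSE,
             generation_fail = FALSE, stringsAsFactors = FALSE)
}

# genomic footprint of a primer binding site on its target transcript:
# maps the transcript interval through the exon chain; NULL when the
# interval spans an exon junction (no contiguous genomic site)
primer_genomic_interval <- function(tx_start, tx_end, exons) {
  exons <- exons[order(exons$exon), , drop = FALSE]
  widths <- exons$end - exons$start + 1L
  tx_off <- cumsum(c(0L, widths))[seq_len(nrow(exons))]
  for (i in seq_len(nrow(exons))) {
    lo <- tx_off[i] + 1L; hi <- tx_off[i] + widths[i]
    if (tx_start >= lo && tx_end <= hi) {
      return(c(exons$start[i] + (tx_start - lo),
               exons$start[i] + (tx_end - lo)))
    }
  }
  NULL
}
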