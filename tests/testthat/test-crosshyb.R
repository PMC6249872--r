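mini_bundle <- function() {
  fx_memo("mini_bundle", function() {
    genome <- c(chrT = rand_dna(400, seed = 31), chrU = rand_dna(400, seed = 32))
    genes <- data.frame(gene_id = c("G", "G9"), chrom = c("chrT", "chrU"),
                        strand = "+", start = 1L, end = 400L,
                        stringsAsFactors = FALSE)
    tx <- data.frame(transcript_id = c("T1", "T2", "T3", "X1"),
                     gene_id = c("G", "G", "G", "G9"),
                     stringsAsFactors = FALSE)
    seqs <- c(T1 = rand_dna(300, seed = 33), T2 = rand_dna(280, seed = 34),
              T3 = rand_dna(260, seed = 35), X1 = rand_dna(300, seed = 36))
    reference_bundle(genome, genes, tx, seqs)
  })
}

mutate_at <- function(seq, positions) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  paste(b, collapse = "")
}

test_that("a primer identical to a transcript substring gives one exact plus-strand match", {
  tx <- c(TX = rand_dna(500, seed = 41))
  primer <- substr(tx[["TX"]], 101, 120)
  m <- find_matches(primer, tx)
  hit <- m[m$start == 101 & m$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$similarity, 1.0)
  expect_equal(hit$end, 120L)
})

test_that("similarity is strict: 15/20 identities reported, 14/20 suppressed", {
  tx_seq <- rand_dna(300, seed = 42)
  primer <- rand_dna(20, seed = 43)
  plant <- function(n_mm) {
    site <- mutate_at(primer, seq_len(n_mm))
    c(TX = paste0(substr(tx_seq, 1, 100), site, substr(tx_seq, 121, 300)))
  }
  m15 <- find_matches(primer, plant(5))
  expect_true(any(m15$start == 101 & m15$identities == 15L))
  m14 <- find_matches(primer, plant(6))
  expect_false(any(m14$start == 101))
})

test_that("the scanner equals the exhaustive all-offset oracle on random and near-site primers", {
  tr <- fx_short_tx()
  txs <- tr$bundle$transcript_seqs
  expect_true(all(Biostrings::width(txs) <= 1000))
  idx <- build_tx_index(txs)
  withr::with_seed(44, {
    for (i in 1:25) {
      L <- sample(18:27, 1)
      primer <- if (i <= 12) {
        paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      } else {
        # primer derived from a real site with a few substitutions
        src <- as.character(txs[[sample(length(txs), 1)]])
        st <- sample(nchar(src) - L, 1)
        mutate_at(substr(src, st, st + L - 1L), sample(L, sample(0:6, 1)))
      }
      got <- find_matches(primer, txs, index = idx)
      want <- oracle_find_matches(primer, txs)
      expect_equal(got[, c("transcript_id", "strand", "start", "end",
                           "identities")],
                   want[, c("transcript_id", "strand", "start", "end",
                            "identities")],
                   info = sprintf("primer %d", i))
    }
  })
})

test_that("lowering min_similarity never shrinks the match set", {
  tr <- fx_short_tx()
  txs <- tr$bundle$transcript_seqs
  primer <- substr(as.character(txs[[1]]), 50, 71)
  sims <- c(0.95, 0.85, 0.75, 0.7)
  counts <- vapply(sims, function(s)
    nrow(find_matches(primer, txs, crosshyb_config(min_similarity = s))),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("hit assembly enforces opposite strands and the 20x product bound", {
  b <- mini_bundle()
  pair <- fake_pair(rand_dna(20, seed = 45), rand_dna(20, seed = 46),
                    product_size = 115L, gene_id = "G", target_id = "T1")
  mk <- function(tx, strand, start, L = 20L)
    data.frame(transcript_id = tx, strand = strand, start = start,
               end = start + L - 1L, identities = L, similarity = 1,
               stringsAsFactors = FALSE)
  # + / - geometry, 300 bp product: retained (300 < 20 * 115 = 2300)
  h <- pair_matches_to_hits(pair, mk("X1", "+", 1), mk("X1", "-", 281), b)
  expect_equal(nrow(h), 1L)
  expect_equal(h$implied_product_size, 300L)
  expect_false(h$same_gene)
  # 2400 bp rejected, 2299 retained (strict < 2300)
  big <- reference_bundle(
    c(chrB = rand_dna(100, seed = 47)),
    data.frame(gene_id = "GB", chrom = "chrB", strand = "+", start = 1L,
               end = 100L, stringsAsFactors = FALSE),
    data.frame(transcript_id = "B1", gene_id = "GB", stringsAsFactors = FALSE),
    c(B1 = rand_dna(3000, seed = 48)))
  h2400 <- pair_matches_to_hits(pair, mk("B1", "+", 1), mk("B1", "-", 2381), big)
  expect_equal(nrow(h2400), 0L)
  h2299 <- pair_matches_to_hits(pair, mk("B1", "+", 1), mk("B1", "-", 2280), big)
  expect_equal(nrow(h2299), 1L)
  expect_equal(h2299$implied_product_size, 2299L)
  # same strand: no hit regardless of distance
  h_same <- pair_matches_to_hits(pair, mk("X1", "+", 1), mk("X1", "+", 200), b)
  expect_equal(nrow(h_same), 0L)
  # physically impossible amplicon (shorter than the two primers): no hit
  h_tiny <- pair_matches_to_hits(pair, mk("X1", "+", 1), mk("X1", "-", 11), b)
  expect_equal(nrow(h_tiny), 0L)
})

test_that("classification covers clean, sibling-variant and mixed situations", {
  b <- mini_bundle()
  pair <- fake_pair(rand_dna(20, seed = 49), rand_dna(20, seed = 50),
                    product_size = 115L, gene_id = "G", target_id = "T1")
  mk_hit <- function(tx, same)
    data.frame(transcript_id = tx, gene_id = if (same) "G" else "G9",
               same_gene = same, fwd_strand = "+", fwd_start = 1L,
               fwd_end = 20L, fwd_similarity = 1, rev_strand = "-",
               rev_start = 96L, rev_end = 115L, rev_similarity = 1,
               implied_product_size = 115L, stringsAsFactors = FALSE)
  v <- classify_crosshyb(pair, qpcrdesign:::hit_frame(), b)
  expect_identical(v$status, "clean")
  expect_identical(v$amplified, "T1")
  expect_false(v$crosshyb_fail)
  # hits confined to the intended transcript stay clean
  v_self <- classify_crosshyb(pair, mk_hit("T1", TRUE), b)
  expect_identical(v_self$status, "clean")
  v2 <- classify_crosshyb(pair, mk_hit("T2", TRUE), b)
  expect_identical(v2$status, "variants_only")
  expect_setequal(v2$amplified, c("T1", "T2"))
  expect_false(v2$crosshyb_fail)
  v_all <- classify_crosshyb(pair, rbind(mk_hit("T2", TRUE), mk_hit("T3", TRUE)), b)
  expect_identical(v_all$status, "all_variants")
  v3 <- classify_crosshyb(pair, rbind(mk_hit("T2", TRUE), mk_hit("X1", FALSE)), b)
  expect_identical(v3$status, "mixed")
  expect_true(v3$crosshyb_fail)
  v4 <- classify_crosshyb(pair, mk_hit("X1", FALSE), b)
  expect_identical(v4$status, "other_gene")
  expect_true(v4$crosshyb_fail)
})

test_that("planted decoys are recovered and their removal restores specificity", {
  tr <- fx_small()
  b <- tr$bundle
  decoy_tid <- tr$decoy_map$decoy_transcript_id[1]
  src_tid <- tr$decoy_map$source_transcript_id[1]
  rec <- transcript_record(b, src_tid)
  pairs <- generate_candidates(rec, generation_config(n_pairs_requested = 25))
  scr <- screen_crosshyb(pairs, b)
  hit_pairs <- unique(scr$hits$pair_id[scr$hits$transcript_id == decoy_tid])
  expect_gt(length(hit_pairs), 0)
  affected <- scr$pairs$pair_id %in% hit_pairs
  expect_true(all(scr$pairs$crosshyb_fail[affected]))
  expect_true(all(scr$verdicts$status[match(hit_pairs, scr$verdicts$pair_id)]
                  %in% c("other_gene", "mixed")))
  # removing the decoy restores clean / sibling-variant outcomes
  no_decoy <- b$transcript_seqs[setdiff(names(b$transcript_seqs),
                                        tr$decoy_map$decoy_transcript_id)]
  scr2 <- screen_crosshyb(pairs, b, transcriptome = no_decoy)
  expect_true(all(scr2$verdicts$status %in%
                    c("clean", "variants_only", "all_variants")))
  expect_false(any(scr2$pairs$crosshyb_fail))
})

test_that("a decoy below the similarity detection floor is not flagged", {
  tr_lo <- fx_memo("low_decoy", function()
    generate_fixture(fixture_spec(seed = 19, n_genes = 2,
                                  n_planted_snvs = 0, n_decoy_paralogs = 1,
                                  decoy_identity = 0.5)))
  b <- tr_lo$bundle
  rec <- transcript_record(b, tr_lo$decoy_map$source_transcript_id[1])
  pairs <- generate_candidates(rec, generation_config(n_pairs_requested = 15))
  scr <- screen_crosshyb(pairs, b)
  expect_false(any(scr$hits$transcript_id ==
                     tr_lo$decoy_map$decoy_transcript_id[1]))
})

test_that("the optional blastn backend agrees on exact binding sites", {
  tr <- fx_short_tx()
  txs <- tr$bundle$transcript_seqs
  primer <- substr(as.character(txs[[2]]), 120, 143)
  internal <- find_matches(primer, txs)
  blast <- find_matches_blast(primer, txs)
  exact_i <- internal[internal$similarity == 1, c("transcript_id", "strand",
                                                  "start", "end")]
  expect_gt(nrow(exact_i), 0)
  merged <- merge(exact_i, blast)
  expect_equal(nrow(merged), nrow(exact_i))
})
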