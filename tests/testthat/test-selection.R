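scored_pairs <- function(n, dimer, ranks = seq_len(n) - 1L) {
  p <- do.call(rbind, lapply(seq_len(n), function(i)
    fake_pair(rand_dna(20, seed = 300 + i), rand_dna(20, seed = 400 + i),
              product_size = 115L, pair_id = sprintf("T:P%04d", i),
              penalty_rank = ranks[i])))
  p$hairpin_fwd_mfe <- 0; p$hairpin_rev_mfe <- 0
  p$dimer_mfe <- dimer
  p
}

test_that("quality criteria drop every flagged pair and only those", {
  p <- scored_pairs(6, dimer = rep(-2, 6))
  p$snp_fail[2] <- TRUE
  p$crosshyb_fail[3] <- TRUE
  p$generation_fail[4] <- TRUE
  p$snp_fail[5] <- TRUE; p$crosshyb_fail[5] <- TRUE
  surv <- apply_quality_criteria(p)
  expect_setequal(surv$pair_id, p$pair_id[c(1, 6)])
  # set arithmetic: survivors = n_p - |pairs with >= 1 flag|
  flagged <- p$crosshyb_fail | p$snp_fail | p$generation_fail
  expect_equal(nrow(surv), nrow(p) - sum(flagged))
})

test_that("categorisation partitions survivors by amplified subset", {
  p <- scored_pairs(5, dimer = rep(-1, 5))
  v <- data.frame(pair_id = p$pair_id,
                  status = c("clean", "clean", "variants_only", "clean",
                             "variants_only"),
                  amplified = c("T", "T", "T,T2", "T", "T,T2"),
                  n_amplified = c(1, 1, 2, 1, 2), stringsAsFactors = FALSE)
  cats <- categorise_pairs(p, v)
  expect_equal(nrow(cats), 2L)
  expect_setequal(cats$category_key, c("T", "T,T2"))
  expect_equal(sum(cats$n_members), nrow(p))
  expect_equal(sum(lengths(cats$members)), nrow(p))
  # all pairs amplifying only the target collapse to one category
  v1 <- v; v1$amplified <- "T"; v1$n_amplified <- 1
  expect_equal(nrow(categorise_pairs(p, v1)), 1L)
  # every category key contains the intended target
  expect_true(all(vapply(strsplit(cats$category_key, ","),
                         function(k) "T" %in% k, logical(1))))
})

test_that("selection takes the maximum dimer MFE with deterministic tie-breaking", {
  target <- fake_target(rand_dna(300, seed = 99), id = "T", gene = "G")
  p <- scored_pairs(3, dimer = c(-11.4, -7.5, -3.2))
  cats <- categorise_pairs(p, data.frame(pair_id = p$pair_id, status = "clean",
                                         amplified = "T", n_amplified = 1,
                                         stringsAsFactors = FALSE))
  a <- select_best(cats[1, , drop = FALSE], p, target)
  expect_equal(a$dimer_mfe, -3.2)
  expect_identical(a$pair_id, p$pair_id[3])
  # MFE tie at 0.0: lower penalty rank wins
  p2 <- scored_pairs(2, dimer = c(0, 0), ranks = c(17L, 3L))
  cats2 <- categorise_pairs(p2, data.frame(pair_id = p2$pair_id,
                                           status = "clean", amplified = "T",
                                           n_amplified = 1,
                                           stringsAsFactors = FALSE))
  a2 <- select_best(cats2[1, , drop = FALSE], p2, target)
  expect_equal(a2$pair_id, p2$pair_id[2])
  # single-member category returns that member
  p3 <- scored_pairs(1, dimer = -5)
  cats3 <- categorise_pairs(p3, data.frame(pair_id = p3$pair_id,
                                           status = "clean", amplified = "T",
                                           n_amplified = 1,
                                           stringsAsFactors = FALSE))
  expect_identical(select_best(cats3[1, , drop = FALSE], p3, target)$pair_id,
                   p3$pair_id[1])
})

test_that("assay records carry the amplicon delimited by the selected pair", {
  tr <- fx_small()
  rec <- transcript_record(tr$bundle, tr$targets[2])
  pairs <- generate_candidates(rec, generation_config(n_pairs_requested = 10))
  scored <- score_structures(pairs, structure_backend_stub())
  v <- data.frame(pair_id = scored$pair_id, status = "clean",
                  amplified = rec$transcript_id, n_amplified = 1,
                  stringsAsFactors = FALSE)
  cats <- categorise_pairs(scored, v)
  a <- select_best(cats[1, , drop = FALSE], scored, rec)
  expect_equal(nchar(a$amplicon_seq), a$product_size)
  expect_identical(substr(a$amplicon_seq, 1, nchar(a$fwd_seq)), a$fwd_seq)
  expect_identical(revcomp(substr(a$amplicon_seq,
                                  nchar(a$amplicon_seq) - nchar(a$rev_seq) + 1,
                                  nchar(a$amplicon_seq))), a$rev_seq)
  expect_identical(a$amplified_variants, rec$transcript_id)
  expect_identical(a$quality_label, "supported")
})

test_that("gene outcomes follow the three-way classification", {
  empty <- categorise_pairs(qpcrdesign:::candidate_frame(0L), NULL)
  o1 <- summarise_gene("G1", empty, too_short = TRUE)
  expect_identical(o1$status, "too_short")
  o2 <- summarise_gene("G2", empty)
  expect_identical(o2$status, "no_valid_pair")
  expect_equal(o2$n_categories, 0L)
  p <- scored_pairs(2, dimer = c(-1, -2))
  cats <- categorise_pairs(p, data.frame(pair_id = p$pair_id,
                                         status = "clean",
                                         amplified = c("T", "T,T2"),
                                         n_amplified = c(1, 2),
                                         stringsAsFactors = FALSE))
  o3 <- summarise_gene("G3", cats)
  expect_identical(o3$status, "assays_generated")
  expect_equal(o3$n_categories, 2L)
})
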