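test_that("corona geometry: 53 bp around an SNV, clipped at chromosome edges, genome-faithful", {
  tr <- fx_small()
  b <- tr$bundle
  for (g in tr$bundle$genes$gene_id[1:3]) {
    co <- build_coronas(g, b)
    if (!nrow(co)) next
    # interval arithmetic and byte-for-byte genome fidelity
    for (i in seq_len(nrow(co))) {
      expect_identical(co$seq[i],
                       as.character(Biostrings::subseq(
                         b$genome[[co$chrom[i]]], co$start[i], co$end[i])))
      if (!co$clipped[i]) {
        expect_equal(nchar(co$seq[i]), 2L * 26L + co$var_len[i])
        expect_equal(co$var_start[i], 27L)
      }
    }
  }
  # forced arithmetic: SNV at chr1:1000 with flank 26 spans 974..1026
  v <- b$variants[b$variants$chrom == "chr1", ][1, ]
  one <- b
  one$variants <- transform(v, pos = 1000L,
                            ref = substr(as.character(b$genome[["chr1"]]),
                                         1000, 1000))
  gene1 <- b$genes$gene_id[b$genes$chrom == "chr1"][1]
  co <- build_coronas(gene1, one)
  expect_equal(co$start, 974L)
  expect_equal(co$end, 1026L)
  expect_equal(nchar(co$seq), 53L)
})

test_that("edge clipping shortens the corona and records the clip", {
  genome <- c(chrE = rand_dna(500, seed = 61))
  b <- reference_bundle(
    genome,
    data.frame(gene_id = "GE", chrom = "chrE", strand = "+", start = 1L,
               end = 400L, stringsAsFactors = FALSE),
    data.frame(transcript_id = "E1", gene_id = "GE", stringsAsFactors = FALSE),
    c(E1 = rand_dna(200, seed = 62)),
    data.frame(variant_id = "v1", chrom = "chrE", pos = 11L,
               ref = substr(genome[["chrE"]], 11, 11), alt = "T",
               af = 0.2, stringsAsFactors = FALSE))
  if (b$variants$ref == "T") b$variants$alt <- "G"
  co <- build_coronas("GE", b)
  expect_true(co$clipped)
  # 10 bases left of the SNV survive the clip: 10 + 1 + 26
  expect_equal(nchar(co$seq), 10L + 1L + 26L)
  expect_equal(co$var_start, 11L)
})

test_that("corona count per gene equals the interval-overlap oracle", {
  tr <- fx_small()
  b <- tr$bundle
  for (gi in seq_len(nrow(b$genes))) {
    g <- b$genes[gi, ]
    want <- sum(b$variants$chrom == g$chrom &
                  b$variants$pos >= g$start & b$variants$pos <= g$end)
    expect_equal(nrow(build_coronas(g$gene_id, b)), want, info = g$gene_id)
  }
})

test_that("hits require a full-length exact occurrence covering the variant", {
  corona_seq <- rand_dna(53, seed = 63)
  co <- data.frame(variant_id = "v", chrom = "c", start = 1L, end = 53L,
                   seq = corona_seq, var_start = 27L, var_len = 1L,
                   clipped = FALSE, usable = TRUE, stringsAsFactors = FALSE)
  # occurrence at 10..29 covers position 27
  p_cover <- substr(corona_seq, 10, 29)
  h <- match_primer_to_coronas(p_cover, co)
  expect_gte(nrow(h), 1L)
  expect_true(any(h$match_start <= 27 & h$match_end >= 27))
  # occurrence at 30..49 misses the variant
  p_miss <- substr(corona_seq, 30, 49)
  expect_equal(nrow(match_primer_to_coronas(p_miss, co)), 0L)
  # reverse-complement occurrences count too
  h_rc <- match_primer_to_coronas(revcomp(p_cover), co)
  expect_gte(nrow(h_rc), 1L)
  expect_true(all(h_rc$strand == "-"))
  # a single mismatch breaks the exact match
  b <- strsplit(p_cover, "")[[1]]
  b[18] <- setdiff(c("A", "C", "G", "T"), b[18])[1]  # covers the variant pos
  expect_equal(nrow(match_primer_to_coronas(paste(b, collapse = ""), co)), 0L)
  # unusable coronas never match
  co_n <- co; co_n$usable <- FALSE
  expect_equal(nrow(match_primer_to_coronas(p_cover, co_n)), 0L)
})

test_that("planted SNVs are recovered exactly: full sensitivity, no false flags", {
  tr <- fx_medium()
  b <- tr$bundle
  checked <- 0L
  for (tid in tr$targets) {
    rec <- transcript_record(b, tid)
    pairs <- generate_candidates(rec, generation_config(n_pairs_requested = 40))
    coronas <- build_coronas(rec$gene_id, b)
    scr <- screen_snps(pairs, coronas)
    ex <- tr$variant_structure[tr$variant_structure$transcript_id == tid, ]
    chrom <- b$genes$chrom[match(rec$gene_id, b$genes$gene_id)]
    snv_pos <- b$variants$pos[b$variants$chrom == chrom]
    for (i in seq_len(nrow(pairs))) {
      covers <- FALSE
      junction <- FALSE
      for (role in c("fwd", "rev")) {
        gi <- primer_genomic_interval(pairs[[paste0(role, "_start")]][i],
                                      pairs[[paste0(role, "_end")]][i], ex)
        if (is.null(gi)) junction <- TRUE
        else if (any(snv_pos >= gi[1] & snv_pos <= gi[2])) covers <- TRUE
      }
      if (junction && !covers) next  # no contiguous genomic site: undetectable
      expect_identical(scr$pairs$snp_fail[i], covers,
                       info = pairs$pair_id[i])
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("adding variants never decreases the number of flagged pairs", {
  tr <- fx_medium()
  b <- tr$bundle
  rec <- transcript_record(b, tr$targets[1])
  pairs <- generate_candidates(rec, generation_config(n_pairs_requested = 40))
  co_all <- build_coronas(rec$gene_id, b)
  n_flags <- function(co) sum(screen_snps(pairs, co)$pairs$snp_fail)
  counts <- vapply(seq_len(nrow(co_all)),
                   function(k) n_flags(co_all[seq_len(k), , drop = FALSE]),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], n_flags(co_all))
})
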