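test_that("a clean fixture bundle loads with all records preserved", {
  tr <- fx_small()
  dir <- withr::local_tempdir()
  write_reference_bundle(tr$bundle, dir)
  b2 <- load_references(file.path(dir, "genome.fa"),
                        file.path(dir, "genes.gff3"),
                        file.path(dir, "transcripts.fa"),
                        file.path(dir, "snps.vcf"))
  expect_equal(length(b2$genome), length(tr$bundle$genome))
  expect_equal(nrow(b2$genes), nrow(tr$bundle$genes))
  expect_equal(nrow(b2$transcripts), nrow(tr$bundle$transcripts))
  expect_equal(nrow(b2$variants), nrow(tr$bundle$variants))
})

test_that("write + reload round-trips the bundle exactly", {
  b <- fx_small()$bundle
  dir <- withr::local_tempdir()
  write_reference_bundle(b, dir)
  b2 <- load_references(file.path(dir, "genome.fa"),
                        file.path(dir, "genes.gff3"),
                        file.path(dir, "transcripts.fa"),
                        file.path(dir, "snps.vcf"))
  expect_identical(as.character(b2$genome), as.character(b$genome))
  expect_identical(as.character(b2$transcript_seqs),
                   as.character(b$transcript_seqs))
  ord <- function(df, key) {
    df <- df[order(df[[key]]), , drop = FALSE]; rownames(df) <- NULL; df
  }
  expect_equal(ord(b2$genes, "gene_id"), ord(b$genes, "gene_id"))
  expect_equal(ord(b2$transcripts, "transcript_id"),
               ord(b$transcripts, "transcript_id"))
  expect_equal(ord(b2$variants, "variant_id"), ord(b$variants, "variant_id"))
})

test_that("annotated transcripts missing from the transcriptome are dropped with a warning", {
  b <- fx_small()$bundle
  tx <- rbind(b$transcripts[, c("transcript_id", "gene_id")],
              data.frame(transcript_id = "NM_999",
                         gene_id = b$genes$gene_id[1],
                         stringsAsFactors = FALSE))
  expect_warning(
    b2 <- reference_bundle(b$genome, b$genes, tx, b$transcript_seqs,
                           b$variants),
    "NM_999")
  expect_false("NM_999" %in% b2$transcripts$transcript_id)
  expect_equal(nrow(b2$transcripts), nrow(b$transcripts))
})

test_that("an empty VCF yields an empty variant table without error", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "empty.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), vcf)
  tr <- fx_small()
  write_reference_bundle(tr$bundle, dir)
  b2 <- load_references(file.path(dir, "genome.fa"),
                        file.path(dir, "genes.gff3"),
                        file.path(dir, "transcripts.fa"), vcf)
  expect_equal(nrow(b2$variants), 0L)
})

test_that("multi-allelic rows split per ALT and CAF-style frequencies are understood", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##INFO=<ID=CAF,Number=.,Type=String,Description=\"caf\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tC,G\t.\t.\tAF=0.10,0.20",
    "chr1\t200\trs2\tT\tA\t.\t.\tAF=0.05"), vcf)
  v <- qpcrdesign:::read_vcf_variants(vcf, info_key = "AF")
  expect_equal(nrow(v), 3L)
  expect_equal(v$alt[v$variant_id == "rs1_1"], "C")
  expect_equal(v$af[v$variant_id == "rs1_2"], 0.2)

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CAF,Number=.,Type=String,Description=\"caf\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs9\tA\tC\t.\t.\tCAF=0.9,0.1"), vcf)
  v <- qpcrdesign:::read_vcf_variants(vcf, info_key = "CAF")
  expect_equal(v$af, 0.1)  # first entry is the REF frequency
})

test_that("REF-allele consistency checking matches brute-force lookup", {
  b <- fx_small()$bundle
  expect_equal(nrow(check_variant_consistency(b)), 0L)

  # corrupt two REF alleles
  bad <- b
  idx <- c(2L, 7L)
  for (i in idx) {
    old <- bad$variants$ref[i]
    bad$variants$ref[i] <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  rep <- check_variant_consistency(bad)
  expect_setequal(rep$variant_id, bad$variants$variant_id[idx])
  expect_setequal(rep$variant_id, oracle_inconsistent_variants(bad))

  # out-of-range locus is an inconsistency, not an exception
  bad2 <- b
  bad2$variants$pos[1] <- Biostrings::width(b$genome[bad2$variants$chrom[1]]) + 50L
  rep2 <- check_variant_consistency(bad2)
  expect_true(bad2$variants$variant_id[1] %in% rep2$variant_id)
})

test_that("frequency filtering is inclusive at the cut, idempotent and monotone", {
  b <- fx_small()$bundle
  b$variants$af[1] <- 0.005
  b$variants$af[2] <- 0.01
  b$variants$af[3] <- NA_real_
  f <- filter_variants_by_frequency(b, 0.01)
  expect_false(b$variants$variant_id[1] %in% f$variants$variant_id)
  expect_true(b$variants$variant_id[2] %in% f$variants$variant_id)
  expect_true(b$variants$variant_id[3] %in% f$variants$variant_id)  # kept
  strict <- filter_variants_by_frequency(b, 0.01, keep_missing = FALSE)
  expect_false(b$variants$variant_id[3] %in% strict$variants$variant_id)

  expect_equal(filter_variants_by_frequency(b, 0)$variants, b$variants)
  expect_equal(filter_variants_by_frequency(f, 0.01)$variants, f$variants)
  counts <- vapply(c(0, 0.01, 0.1, 0.3, 1),
                   function(m) nrow(filter_variants_by_frequency(b, m)$variants),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("transcript records resolve and unknown ids error", {
  tr <- fx_small()
  rec <- transcript_record(tr$bundle, tr$targets[1])
  expect_identical(rec$sequence,
                   as.character(tr$bundle$transcript_seqs[[tr$targets[1]]]))
  expect_error(transcript_record(tr$bundle, "nope"), "unknown transcript")
})
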