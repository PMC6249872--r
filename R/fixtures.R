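#' Specification for a synthetic reference fixture
#'
#' Describes a seeded toy reference set: a multi-chromosome genome carrying
#' multi-exon genes, several exon-skipping splice variants per gene,
#' near-identical decoy paralogs on separate chromosomes (to trigger
#' off-target screening) and planted SNVs at known coordinates. The same
#' spec and seed always reproduce byte-identical files.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of real (non-decoy) genes.
#' @param variants_per_gene integer range `c(min, max)` of splice variants
#'   per gene (the full-length master transcript counts as one).
#' @param gene_length bp range `c(min, max)` of the genomic gene span.
#' @param n_planted_snvs total SNVs planted in exonic sequence.
#' @param snv_placement `"uniform"` over exonic bases, or `"primer_window"`
#'   to concentrate plants within 30 bp of exon 3' ends where primers are
#'   likely to land.
#' @param n_decoy_paralogs number of decoy paralog genes.
#' @param decoy_identity per-base copy fidelity of each decoy in `[0, 1]`.
#' @param gc_content GC fraction of the generated sequence.
#' @param intron_length bp range of intron lengths.
#' @param min_exon_length shortest exon allowed.
#' @return list of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 3L, variants_per_gene = c(1L, 3L),
                         gene_length = c(1500L, 3000L), n_planted_snvs = 10L,
                         snv_placement = c("uniform", "primer_window"),
                         n_decoy_paralogs = 1L, decoy_identity = 0.95,
                         gc_content = 0.5, intron_length = c(60L, 150L),
                         min_exon_length = 80L) {
  snv_placement <- match.arg(snv_placement)
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               variants_per_gene = as.integer(variants_per_gene),
               gene_length = as.integer(gene_length),
               n_planted_snvs = as.integer(n_planted_snvs),
               snv_placement = snv_placement,
               n_decoy_paralogs = as.integer(n_decoy_paralogs),
               decoy_identity = decoy_identity, gc_content = gc_content,
               intron_length = as.integer(intron_length),
               min_exon_length = as.integer(min_exon_length))
  validate_fixture_spec(spec)
  structure(spec, class = "FixtureSpec")
}

validate_fixture_spec <- function(spec) {
  stopifnot(spec$n_genes >= 1L, spec$n_planted_snvs >= 0L,
            spec$n_decoy_paralogs >= 0L,
            spec$decoy_identity >= 0, spec$decoy_identity <= 1,
            spec$gc_content > 0, spec$gc_content < 1)
  k_min <- 3L
  need <- k_min * spec$min_exon_length + (k_min - 1L) * spec$intron_length[1]
  if (spec$gene_length[1] < need)
    stop(sprintf(
      "impossible fixture spec: gene_length minimum %d cannot host %d exons of >=%d bp with introns of >=%d bp (needs >= %d bp)",
      spec$gene_length[1], k_min, spec$min_exon_length,
      spec$intron_length[1], need), call. = FALSE)
  invisible(spec)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

runif_int <- function(n, range) {
  if (range[1] >= range[2]) return(rep(range[1], n))
  as.integer(range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1L)))
}

#' Plant a single SNV inside a genomic window
#'
#' Chooses a position uniformly within `[start, end]` on `chrom`, takes the
#' genome base there as the REF allele and a different base as ALT. Uses the
#' current RNG state; identical state gives an identical variant.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param chrom chromosome id.
#' @param start,end 1-based inclusive window inside the chromosome.
#' @param variant_id id for the returned record.
#' @param af alternative-allele frequency to record (may be `NA`).
#' @return one-row data.frame (`variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `af`).
#' @export
plant_snv_in_window <- function(genome, chrom, start, end,
                                variant_id = "snv", af = NA_real_) {
  stopifnot(chrom %in% names(genome))
  len <- Biostrings::width(genome[chrom])
  stopifnot(start >= 1L, end <= len, start <= end)
  window <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  bases <- strsplit(window, "", fixed = TRUE)[[1]]
  ok <- which(bases %in% c("A", "C", "G", "T"))
  if (!length(ok)) stop("window contains only N bases", call. = FALSE)
  at <- ok[runif_int(1L, c(1L, length(ok)))]
  ref <- bases[at]
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  data.frame(variant_id = variant_id, chrom = chrom,
             pos = as.integer(start + at - 1L), ref = ref, alt = alt,
             af = af, stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic reference fixture
#'
#' Builds a fully self-consistent toy reference set according to a
#' [fixture_spec()]: every emitted variant's REF allele matches the genome
#' ([check_variant_consistency()] on the result is empty by construction),
#' every splice variant is an exon-skipping product of its gene's master
#' exon chain, and every decoy paralog is a point-mutated copy of a real
#' master transcript annotated as a distinct gene on its own chromosome.
#'
#' @param spec a `FixtureSpec`.
#' @param out_dir optional directory; when given, `genome.fa`, `genes.gff3`,
#'   `transcripts.fa`, `snps.vcf` and `fixture_truth.json` are written there.
#' @return list of class `FixtureTruth` with elements `bundle`
#'   (the in-memory `ReferenceBundle`), `planted_snvs`, `decoy_map`,
#'   `variant_structure` (per-transcript exon table, genomic coordinates),
#'   and `targets` (the master transcript of each real gene).
#' @export
generate_fixture <- function(spec, out_dir = NULL) {
  validate_fixture_spec(spec)
  truth <- with_seed(spec$seed, build_fixture(spec))
  if (!is.null(out_dir)) {
    write_reference_bundle(truth$bundle, out_dir)
    ser <- truth[c("planted_snvs", "decoy_map", "variant_structure", "targets")]
    jsonlite::write_json(ser, file.path(out_dir, "fixture_truth.json"),
                         dataframe = "columns", pretty = TRUE, digits = NA,
                         auto_unbox = FALSE)
  }
  truth
}

build_fixture <- function(spec) {
  pad <- 200L
  genome <- character(0)
  genes <- list(); transcripts <- list(); seqs <- character(0)
  exons <- list(); targets <- character(0)

  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("G%02d", g)
    chrom <- sprintf("chr%d", g)
    L <- runif_int(1L, spec$gene_length)
    k <- max(3L, min(7L, L %/% 400L))
    repeat {
      introns <- runif_int(k - 1L, spec$intron_length)
      exon_total <- L - sum(introns)
      if (exon_total >= k * spec$min_exon_length) break
      k <- k - 1L
      if (k < 3L) stop("gene_length too short for exon structure", call. = FALSE)
    }
    w <- stats::runif(k) + 0.2
    ex_len <- pmax(spec$min_exon_length,
                   as.integer(floor(exon_total * w / sum(w))))
    # put the rounding remainder on the last exon, keep total = exon_total
    ex_len[k] <- exon_total - sum(ex_len[-k])
    if (ex_len[k] < spec$min_exon_length) {
      ex_len <- rep(exon_total %/% k, k)
      ex_len[k] <- exon_total - sum(ex_len[-k])
    }
    gene_seq <- random_dna(L, spec$gc_content)
    gene_start <- pad + 1L
    genome[[chrom]] <- paste0(random_dna(pad, spec$gc_content), gene_seq,
                              random_dna(pad, spec$gc_content))
    # exon coordinates on the chromosome
    ex_start <- integer(k); ex_end <- integer(k); cur <- gene_start
    for (e in seq_len(k)) {
      ex_start[e] <- cur; ex_end[e] <- cur + ex_len[e] - 1L
      cur <- ex_end[e] + 1L + if (e < k) introns[e] else 0L
    }
    gene_end <- ex_end[k]
    genes[[gid]] <- data.frame(gene_id = gid, chrom = chrom, strand = "+",
                               start = gene_start, end = gene_end,
                               stringsAsFactors = FALSE)

    n_var <- runif_int(1L, spec$variants_per_gene)
    # master chain first; extra variants skip distinct subsets of internal exons
    internal <- if (k > 2L) 2:(k - 1L) else integer(0)
    skip_sets <- list(integer(0))
    if (n_var > 1L && length(internal)) {
      pool <- unlist(lapply(seq_along(internal), function(m)
        utils::combn(internal, m, simplify = FALSE)), recursive = FALSE)
      pool <- pool[sample.int(length(pool))]
      skip_sets <- c(skip_sets, pool[seq_len(min(n_var - 1L, length(pool)))])
    }
    for (v in seq_along(skip_sets)) {
      tid <- sprintf("%sT%d", gid, v)
      keep <- setdiff(seq_len(k), skip_sets[[v]])
      tx_seq <- paste(substring(genome[[chrom]], ex_start[keep], ex_end[keep]),
                      collapse = "")
      transcripts[[tid]] <- data.frame(transcript_id = tid, gene_id = gid,
                                       stringsAsFactors = FALSE)
      seqs[[tid]] <- tx_seq
      exons[[tid]] <- data.frame(gene_id = gid, transcript_id = tid,
                                 exon = seq_along(keep),
                                 start = ex_start[keep], end = ex_end[keep],
                                 stringsAsFactors = FALSE)
      if (v == 1L) targets <- c(targets, tid)
    }
  }

  # decoy paralogs: mutated copies of master transcripts, own chromosomes
  decoy_map <- data.frame(decoy_transcript_id = character(0),
                          source_transcript_id = character(0),
                          identity = numeric(0), stringsAsFactors = FALSE)
  for (d in seq_len(spec$n_decoy_paralogs)) {
    src_tid <- targets[((d - 1L) %% length(targets)) + 1L]
    src <- strsplit(seqs[[src_tid]], "", fixed = TRUE)[[1]]
    mut <- stats::runif(length(src)) < (1 - spec$decoy_identity)
    src[mut] <- vapply(src[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    dseq <- paste(src, collapse = "")
    did <- sprintf("DG%02d", d); dtid <- sprintf("%sT1", did)
    chrom <- sprintf("chrD%d", d)
    genome[[chrom]] <- paste0(random_dna(pad, spec$gc_content), dseq,
                              random_dna(pad, spec$gc_content))
    genes[[did]] <- data.frame(gene_id = did, chrom = chrom, strand = "+",
                               start = pad + 1L,
                               end = pad + nchar(dseq),
                               stringsAsFactors = FALSE)
    transcripts[[dtid]] <- data.frame(transcript_id = dtid, gene_id = did,
                                      stringsAsFactors = FALSE)
    seqs[[dtid]] <- dseq
    exons[[dtid]] <- data.frame(gene_id = did, transcript_id = dtid,
                                exon = 1L, start = pad + 1L,
                                end = pad + nchar(dseq),
                                stringsAsFactors = FALSE)
    decoy_map <- rbind(decoy_map, data.frame(
      decoy_transcript_id = dtid, source_transcript_id = src_tid,
      identity = 1 - sum(mut) / length(src), stringsAsFactors = FALSE))
  }

  genes_df <- do.call(rbind, genes); rownames(genes_df) <- NULL
  exons_df <- do.call(rbind, exons); rownames(exons_df) <- NULL
  genome_set <- Biostrings::DNAStringSet(genome)

  # plant SNVs in exonic windows of real genes
  planted <- list()
  if (spec$n_planted_snvs > 0L) {
    master_ex <- exons_df[exons_df$transcript_id %in% targets, , drop = FALSE]
    windows <- if (spec$snv_placement == "primer_window") {
      data.frame(chrom = genes_df$chrom[match(master_ex$gene_id,
                                              genes_df$gene_id)],
                 start = pmax(master_ex$start, master_ex$end - 29L),
                 end = master_ex$end, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = genes_df$chrom[match(master_ex$gene_id,
                                              genes_df$gene_id)],
                 start = master_ex$start, end = master_ex$end,
                 stringsAsFactors = FALSE)
    }
    seen <- character(0)
    i <- 0L; tries <- 0L
    while (i < spec$n_planted_snvs && tries < 50L * spec$n_planted_snvs) {
      tries <- tries + 1L
      w <- windows[runif_int(1L, c(1L, nrow(windows))), ]
      v <- plant_snv_in_window(genome_set, w$chrom, w$start, w$end,
                               variant_id = sprintf("snv%03d", i + 1L),
                               af = round(stats::runif(1, 0.01, 0.5), 3))
      key <- sprintf("%s:%d", v$chrom, v$pos)
      if (key %in% seen) next
      seen <- c(seen, key)
      i <- i + 1L
      planted[[i]] <- v
    }
  }
  variants <- if (length(planted)) do.call(rbind, planted) else NULL

  bundle <- reference_bundle(genome = genome_set, genes = genes_df,
                             transcripts = do.call(rbind, transcripts),
                             transcript_seqs = Biostrings::DNAStringSet(seqs),
                             variants = variants, exons = exons_df)
  planted_df <- if (!is.null(variants))
    variants[, c("variant_id", "chrom", "pos")] else
    data.frame(variant_id = character(0), chrom = character(0),
               pos = integer(0), stringsAsFactors = FALSE)
  structure(list(bundle = bundle, planted_snvs = planted_df,
                 decoy_map = decoy_map, variant_structure = exons_df,
                 targets = targets),
            class = "FixtureTruth")
}
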