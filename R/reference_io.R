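#' Assemble a cross-indexed reference bundle
#'
#' A `ReferenceBundle` ties together the four reference inputs of an assay
#' design run: the genome, the gene annotation, the transcriptome and the
#' variant catalogue. All cross-references are validated on construction:
#' transcripts announced by the annotation but missing from the transcriptome
#' (and vice versa) are dropped with a warning, duplicated identifiers are an
#' error, and every retained transcript resolves to a gene.
#'
#' Coordinates are 1-based inclusive throughout (the Biostrings/IRanges
#' convention); serialised outputs convert back to each format's own
#' convention.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character vector,
#'   one element per chromosome.
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param transcript_seqs named [Biostrings::DNAStringSet] or named character
#'   vector, names matching `transcript_id`.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `af` (`NA` where unannotated); zero rows allowed.
#' @param exons optional data.frame (`gene_id`, `transcript_id`, `exon`,
#'   `start`, `end`) carried along for serialisation; not used by screening.
#' @return object of class `ReferenceBundle`.
#' @export
reference_bundle <- function(genome, genes, transcripts, transcript_seqs,
                             variants = NULL, exons = NULL) {
  if (!is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  if (!is(transcript_seqs, "DNAStringSet"))
    transcript_seqs <- Biostrings::DNAStringSet(toupper(unlist(transcript_seqs)))
  if (is.null(names(genome)) || is.null(names(transcript_seqs)))
    stop("genome and transcript_seqs must be named", call. = FALSE)
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome ids in genome", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in annotation", call. = FALSE)
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript ids in annotation", call. = FALSE)

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  if (!all(genes$chrom %in% names(genome)))
    stop("annotation references chromosomes absent from the genome",
         call. = FALSE)
  if (any(genes$start > genes$end))
    stop("gene span with start > end", call. = FALSE)

  # annotation transcripts without a sequence record: drop, warn
  missing_seq <- setdiff(transcripts$transcript_id, names(transcript_seqs))
  if (length(missing_seq)) {
    warning(sprintf(
      "dropping %d annotated transcript(s) missing from the transcriptome: %s",
      length(missing_seq), paste(utils::head(missing_seq, 5), collapse = ", ")),
      call. = FALSE)
    transcripts <- transcripts[!transcripts$transcript_id %in% missing_seq, ,
                               drop = FALSE]
  }
  # sequence records without an annotation entry: drop, warn
  orphan <- setdiff(names(transcript_seqs), transcripts$transcript_id)
  if (length(orphan)) {
    warning(sprintf(
      "dropping %d transcriptome record(s) absent from the annotation: %s",
      length(orphan), paste(utils::head(orphan, 5), collapse = ", ")),
      call. = FALSE)
    transcript_seqs <- transcript_seqs[!names(transcript_seqs) %in% orphan]
  }
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stop("transcript references gene id absent from the annotation",
         call. = FALSE)
  transcript_seqs <- transcript_seqs[transcripts$transcript_id]
  transcripts$length <- Biostrings::width(transcript_seqs)
  if (any(transcripts$length < 1L))
    stop("empty transcript sequence", call. = FALSE)

  if (is.null(variants) || nrow(as.data.frame(variants)) == 0L) {
    variants <- data.frame(variant_id = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0), af = numeric(0),
                           stringsAsFactors = FALSE)
  } else {
    variants <- as.data.frame(variants, stringsAsFactors = FALSE)
    variants$pos <- as.integer(variants$pos)
    if (anyDuplicated(variants$variant_id))
      stop("duplicate variant ids", call. = FALSE)
    if (any(nchar(variants$ref) < 1L))
      stop("variant with empty REF allele", call. = FALSE)
  }

  structure(list(genome = genome, genes = genes, transcripts = transcripts,
                 transcript_seqs = transcript_seqs, variants = variants,
                 exons = exons),
            class = "ReferenceBundle")
}

#' @export
print.ReferenceBundle <- function(x, ...) {
  cat(sprintf(
    "ReferenceBundle: %d chromosome(s) (%s bp), %d gene(s), %d transcript(s), %d variant(s)\n",
    length(x$genome), format(sum(Biostrings::width(x$genome)), big.mark = ","),
    nrow(x$genes), nrow(x$transcripts), nrow(x$variants)))
  invisible(x)
}

#' Load and cross-index the four reference inputs
#'
#' Reads a genome FASTA, a GFF3 gene annotation (only `gene` and
#' `mRNA`/`transcript` features are interpreted; all other feature types are
#' ignored), a transcriptome FASTA (one record per transcript, ids matching
#' the annotation) and a VCF of variants, and assembles them into a validated
#' [reference_bundle()]. Soft-masked bases are uppercased; multi-allelic VCF
#' rows are split into one record per ALT allele.
#'
#' @param genome_path,gff_path,transcriptome_path,vcf_path input file paths.
#' @param info_key INFO key holding the alternative-allele frequency
#'   (default `"AF"`, one value per ALT; `"CAF"`-style lists whose first
#'   entry is the reference-allele frequency are also understood).
#' @return a `ReferenceBundle`.
#' @export
load_references <- function(genome_path, gff_path, transcriptome_path,
                            vcf_path, info_key = "AF") {
  genome <- read_fasta_upper(genome_path)
  ann <- read_gff_genes(gff_path)
  tx_seqs <- read_fasta_upper(transcriptome_path)
  variants <- read_vcf_variants(vcf_path, info_key = info_key)
  reference_bundle(genome = genome, genes = ann$genes,
                   transcripts = ann$transcripts, transcript_seqs = tx_seqs,
                   variants = variants)
}

read_fasta_upper <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop(sprintf(
                  "cannot parse FASTA '%s': %s", path, conditionMessage(e)),
                  call. = FALSE))
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}

read_gff_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop(sprintf(
                   "cannot parse GFF3 '%s': %s", path, conditionMessage(e)),
                   call. = FALSE))
  type <- as.character(gr$type)
  g <- gr[type == "gene"]
  genes <- data.frame(
    gene_id = as.character(g$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  tx <- gr[type %in% c("mRNA", "transcript")]
  parent <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  transcripts <- data.frame(
    transcript_id = as.character(tx$ID),
    gene_id = parent,
    stringsAsFactors = FALSE)
  transcripts <- transcripts[!is.na(transcripts$gene_id), , drop = FALSE]
  list(genes = genes, transcripts = transcripts)
}

read_vcf_variants <- function(path, info_key = "AF") {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop(sprintf(
                    "cannot parse VCF '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-row VCFs drop to a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0),
                      stringsAsFactors = FALSE))
  af_raw <- tryCatch(vcfR::extract.info(vcf, element = info_key),
                     error = function(e) rep(NA_character_, nrow(fix)))
  if (is.null(af_raw)) af_raw <- rep(NA_character_, nrow(fix))

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i] %||% "", ",", fixed = TRUE)[[1]]
    alts <- alts[nzchar(alts) & alts != "."]
    if (!length(alts)) return(NULL)
    afs <- suppressWarnings(as.numeric(
      strsplit(af_raw[i] %||% NA_character_, ",", fixed = TRUE)[[1]]))
    if (identical(toupper(info_key), "CAF") && length(afs) > 1L)
      afs <- afs[-1L]  # first entry is the REF-allele frequency
    af_per_alt <- rep(NA_real_, length(alts))
    if (length(afs))
      af_per_alt[seq_len(min(length(alts), length(afs)))] <-
        afs[seq_len(min(length(alts), length(afs)))]
    id <- fix$ID[i]
    if (is.na(id) || id == ".")
      id <- sprintf("%s:%s", fix$CHROM[i], fix$POS[i])
    ids <- if (length(alts) > 1L) paste0(id, "_", seq_along(alts)) else id
    data.frame(variant_id = ids, chrom = fix$CHROM[i],
               pos = as.integer(fix$POS[i]), ref = toupper(fix$REF[i]),
               alt = toupper(alts), af = af_per_alt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check that variant REF alleles match the genome
#'
#' Compares every variant's REF allele with the genome substring at its
#' locus. A variant whose locus extends beyond the chromosome end, or whose
#' chromosome is unknown, is reported as an inconsistency rather than raising
#' an error.
#'
#' @param bundle a `ReferenceBundle`.
#' @return data.frame with one row per inconsistent variant
#'   (`variant_id`, `chrom`, `pos`, `ref`, `genome_allele`, `reason`);
#'   zero rows iff the bundle is fully consistent.
#' @export
check_variant_consistency <- function(bundle) {
  v <- bundle$variants
  out <- data.frame(variant_id = character(0), chrom = character(0),
                    pos = integer(0), ref = character(0),
                    genome_allele = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(v) == 0L) return(out)
  chrom_len <- setNames(Biostrings::width(bundle$genome), names(bundle$genome))
  reports <- lapply(seq_len(nrow(v)), function(i) {
    chrom <- v$chrom[i]; pos <- v$pos[i]; ref <- v$ref[i]
    if (!chrom %in% names(chrom_len))
      return(data.frame(variant_id = v$variant_id[i], chrom = chrom, pos = pos,
                        ref = ref, genome_allele = NA_character_,
                        reason = "unknown chromosome",
                        stringsAsFactors = FALSE))
    if (pos < 1L || pos + nchar(ref) - 1L > chrom_len[[chrom]])
      return(data.frame(variant_id = v$variant_id[i], chrom = chrom, pos = pos,
                        ref = ref, genome_allele = NA_character_,
                        reason = "locus beyond chromosome end",
                        stringsAsFactors = FALSE))
    g <- as.character(Biostrings::subseq(bundle$genome[[chrom]], pos,
                                         pos + nchar(ref) - 1L))
    if (identical(g, ref)) return(NULL)
    data.frame(variant_id = v$variant_id[i], chrom = chrom, pos = pos,
               ref = ref, genome_allele = g, reason = "REF allele mismatch",
               stringsAsFactors = FALSE)
  })
  reports <- Filter(Negate(is.null), reports)
  if (length(reports)) out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}

#' Filter the variant catalogue by alternative-allele frequency
#'
#' Retains variants whose alternative-allele frequency is at least
#' `min_freq` (the cut is inclusive). Variants with no frequency annotation
#' are retained by default; `keep_missing = FALSE` drops them (strict mode).
#'
#' @param bundle a `ReferenceBundle`.
#' @param min_freq minimum frequency in `[0, 1]`; default `0.01`.
#' @param keep_missing keep variants without a frequency annotation?
#' @return the bundle with a filtered variant table.
#' @export
filter_variants_by_frequency <- function(bundle, min_freq = 0.01,
                                         keep_missing = TRUE) {
  stopifnot(min_freq >= 0, min_freq <= 1)
  v <- bundle$variants
  keep <- ifelse(is.na(v$af), keep_missing, v$af >= min_freq)
  bundle$variants <- v[keep, , drop = FALSE]
  rownames(bundle$variants) <- NULL
  bundle
}

#' Serialise a reference bundle to standard formats
#'
#' Writes `genome.fa`, `genes.gff3`, `transcripts.fa` and `snps.vcf` into
#' `dir`. Reloading the four files with [load_references()] reproduces the
#' bundle (round trip). Exon features are emitted when the bundle carries
#' them; they are informational only.
#'
#' @param bundle a `ReferenceBundle`.
#' @param dir output directory, created if needed.
#' @return invisibly, the four file paths.
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                gff = file.path(dir, "genes.gff3"),
                transcriptome = file.path(dir, "transcripts.fa"),
                vcf = file.path(dir, "snps.vcf"))
  Biostrings::writeXStringSet(bundle$genome, paths$genome, width = 70L)
  Biostrings::writeXStringSet(bundle$transcript_seqs, paths$transcriptome,
                              width = 70L)
  write_gff3(bundle, paths$gff)
  write_vcf(bundle$variants, paths$vcf,
            contigs = setNames(Biostrings::width(bundle$genome),
                               names(bundle$genome)))
  invisible(paths)
}

write_gff3 <- function(bundle, path) {
  esc <- function(x) gsub("([;=,&\t])", "", x)
  lines <- c("##gff-version 3")
  g <- bundle$genes
  tx <- bundle$transcripts
  ex <- bundle$exons
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom[i], "qpcrdesign", g$start[i], g$end[i],
                              g$strand[i], esc(g$gene_id[i])))
    gtx <- tx[tx$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(gtx))) {
      tid <- gtx$transcript_id[j]
      tex <- if (!is.null(ex)) ex[ex$transcript_id == tid, , drop = FALSE] else NULL
      tspan <- if (!is.null(tex) && nrow(tex))
        c(min(tex$start), max(tex$end)) else c(g$start[i], g$end[i])
      lines <- c(lines, sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                g$chrom[i], "qpcrdesign", tspan[1], tspan[2],
                                g$strand[i], esc(tid), esc(g$gene_id[i])))
      if (!is.null(tex) && nrow(tex)) {
        ord <- order(tex$start)
        for (k in seq_len(nrow(tex))) {
          e <- tex[ord[k], ]
          lines <- c(lines, sprintf(
            "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
            g$chrom[i], "qpcrdesign", e$start, e$end, g$strand[i],
            esc(tid), k, esc(tid)))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_vcf <- function(variants, path, contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=qpcrdesign",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternative allele frequency\">")
  if (!is.null(contigs))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contigs), as.integer(contigs)))
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(variants)) {
    info <- ifelse(is.na(variants$af), ".",
                   sprintf("AF=%s", formatC(variants$af, format = "g",
                                            digits = 6)))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                    variants$chrom, variants$pos, variants$variant_id,
                    variants$ref, variants$alt, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Extract one transcript as a target record
#'
#' @param bundle a `ReferenceBundle`.
#' @param transcript_id transcript identifier present in the bundle.
#' @return list with `transcript_id`, `gene_id` and `sequence` (character).
#' @export
transcript_record <- function(bundle, transcript_id) {
  idx <- match(transcript_id, bundle$transcripts$transcript_id)
  if (is.na(idx))
    stop(sprintf("unknown transcript '%s'", transcript_id), call. = FALSE)
  list(transcript_id = transcript_id,
       gene_id = bundle$transcripts$gene_id[idx],
       sequence = as.character(bundle$transcript_seqs[[transcript_id]]))
}
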