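#' Cross-hybridisation screen configuration
#'
#' @param seed_length exact word size used by the optional external blastn
#'   backend (`-word_size`); the internal scanner is complete and does not
#'   use a seed heuristic.
#' @param evalue_cutoff e-value cutoff for the external backend only.
#' @param min_similarity matches are reported when
#'   identities / primer length is strictly greater than this fraction.
#' @param max_product_factor off-target amplicons are retained only when
#'   strictly smaller than this multiple of the intended product size.
#' @return list of class `CrossHybConfig`.
#' @export
crosshyb_config <- function(seed_length = 6L, evalue_cutoff = 10,
                            min_similarity = 0.7, max_product_factor = 20) {
  stopifnot(seed_length >= 4L, min_similarity > 0, min_similarity <= 1,
            max_product_factor > 0)
  structure(list(seed_length = as.integer(seed_length),
                 evalue_cutoff = evalue_cutoff,
                 min_similarity = min_similarity,
                 max_product_factor = max_product_factor),
            class = "CrossHybConfig")
}

match_frame <- function(n = 0L) {
  data.frame(transcript_id = character(n), strand = character(n),
             start = integer(n), end = integer(n), identities = integer(n),
             similarity = numeric(n), stringsAsFactors = FALSE)
}

#' Build a reusable scan index over a transcriptome
#'
#' Encodes the transcript sequences into one integer vector (transcripts
#' separated by non-matching sentinels) so that repeated primer scans avoid
#' re-encoding. [find_matches()] builds the index on the fly when not
#' supplied; callers screening many primers should build it once.
#'
#' @param transcriptome named [Biostrings::DNAStringSet] or named character
#'   vector of transcript sequences.
#' @param gap sentinel run length between transcripts; must be at least the
#'   longest primer scanned.
#' @return list of class `TxScanIndex`.
#' @export
build_tx_index <- function(transcriptome, gap = 40L) {
  if (is(transcriptome, "DNAStringSet"))
    transcriptome <- as.character(transcriptome)
  ids <- names(transcriptome)
  lens <- nchar(transcriptome)
  n <- length(transcriptome)
  # base codes 1..4, sentinel/N -> 0 (matches nothing)
  chunks <- vector("list", 2L * n)
  starts <- integer(n)
  off <- 0L
  sep <- integer(gap)
  for (i in seq_len(n)) {
    code <- match(strsplit(transcriptome[[i]], "", fixed = TRUE)[[1]],
                  c("A", "C", "G", "T"))
    code[is.na(code)] <- 0L
    starts[i] <- off + 1L
    chunks[[2L * i - 1L]] <- code
    chunks[[2L * i]] <- sep
    off <- off + lens[i] + gap
  }
  structure(list(code = unlist(chunks, use.names = FALSE), ids = ids,
                 starts = starts, lens = lens, gap = gap),
            class = "TxScanIndex")
}

#' Find primer binding sites across a transcriptome
#'
#' Ungapped matching of a primer (and its reverse complement) against every
#' offset of every transcript, reporting each full-length placement whose
#' base identity exceeds `min_similarity` (strictly; the primer length is
#' the reference). The scan is complete: it scores every offset on both
#' strands, so the result equals an exhaustive sliding-window alignment.
#'
#' @param primer primer sequence (character, `{A,C,G,T}`).
#' @param transcriptome named [Biostrings::DNAStringSet] (or named character
#'   vector) of transcript sequences.
#' @param cfg a [crosshyb_config()].
#' @param index optional pre-built [build_tx_index()] for `transcriptome`.
#' @return data.frame with columns `transcript_id`, `strand` (`"+"` when the
#'   primer sequence itself matches the transcript, `"-"` when its reverse
#'   complement does), `start`, `end` (1-based inclusive on the transcript),
#'   `identities`, `similarity`.
#' @export
find_matches <- function(primer, transcriptome, cfg = crosshyb_config(),
                         index = NULL) {
  assert_dna(primer, "primer")
  if (is.null(index)) {
    if (!length(transcriptome)) return(match_frame())
    index <- build_tx_index(transcriptome,
                            gap = max(40L, nchar(primer) + 1L))
  }
  if (!length(index$ids)) return(match_frame())
  L <- nchar(primer)
  if (L > index$gap)
    stop("primer longer than the index gap; rebuild the index", call. = FALSE)
  id_min <- floor(cfg$min_similarity * L + 1e-9) + 1L
  if (id_min > L) return(match_frame())
  x <- index$code
  n_win <- length(x) - L + 1L
  if (n_win < 1L) return(match_frame())
  tx_ends <- index$starts + index$lens - 1L

  scan_strand <- function(pat, strand) {
    p <- match(strsplit(pat, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    p[is.na(p)] <- -1L
    hit <- .scan_identities(x, p, id_min)
    s <- hit$start
    if (!length(s)) return(NULL)
    # drop windows that are not fully inside a single transcript
    k <- findInterval(s, index$starts)
    keep <- k >= 1L & (s + L - 1L) <= tx_ends[k]
    s <- s[keep]; k <- k[keep]
    idn <- hit$identities[keep]
    if (!length(s)) return(NULL)
    st <- s - index$starts[k] + 1L
    data.frame(transcript_id = index$ids[k], strand = strand, start = st,
               end = st + L - 1L, identities = idn,
               similarity = idn / L, stringsAsFactors = FALSE)
  }
  out <- rbind(scan_strand(primer, "+"), scan_strand(revcomp(primer), "-"))
  if (is.null(out)) return(match_frame())
  out <- out[order(out$transcript_id, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hit_frame <- function(n = 0L) {
  data.frame(transcript_id = character(n), gene_id = character(n),
             same_gene = logical(n), fwd_strand = character(n),
             fwd_start = integer(n), fwd_end = integer(n),
             fwd_similarity = numeric(n), rev_strand = character(n),
             rev_start = integer(n), rev_end = integer(n),
             rev_similarity = numeric(n), implied_product_size = integer(n),
             stringsAsFactors = FALSE)
}

#' Combine forward and reverse matches into candidate amplification events
#'
#' A hit is one (transcript, forward match, reverse match) combination in
#' which the two matches lie on opposite strands, the plus-strand match lies
#' 5' of the minus-strand match, and the implied amplicon is physically
#' plausible: at least as long as the two primers combined and strictly
#' shorter than `max_product_factor` times the intended product size. The
#' implied product spans from the 5'-most base of the upstream match to the
#' 3'-most base of the downstream match, inclusive.
#'
#' @param pair one row of the candidate table from [generate_candidates()].
#' @param fwd_matches,rev_matches match tables from [find_matches()] for the
#'   pair's forward and reverse primer.
#' @param bundle a `ReferenceBundle` (gene membership lookup). Transcripts
#'   absent from the annotation are conservatively treated as other-gene.
#' @param cfg a [crosshyb_config()].
#' @return data.frame of hits (see `hit` columns in the source).
#' @export
pair_matches_to_hits <- function(pair, fwd_matches, rev_matches, bundle,
                                 cfg = crosshyb_config()) {
  if (!nrow(fwd_matches) || !nrow(rev_matches)) return(hit_frame())
  min_len <- nchar(pair$fwd_seq) + nchar(pair$rev_seq)
  max_len <- cfg$max_product_factor * pair$product_size
  common <- intersect(fwd_matches$transcript_id, rev_matches$transcript_id)
  rows <- lapply(common, function(tx) {
    f <- fwd_matches[fwd_matches$transcript_id == tx, , drop = FALSE]
    r <- rev_matches[rev_matches$transcript_id == tx, , drop = FALSE]
    combo <- expand.grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
    keep <- f$strand[combo$fi] != r$strand[combo$ri]
    combo <- combo[keep, , drop = FALSE]
    if (!nrow(combo)) return(NULL)
    plus_start <- ifelse(f$strand[combo$fi] == "+", f$start[combo$fi],
                         r$start[combo$ri])
    minus_end <- ifelse(f$strand[combo$fi] == "+", r$end[combo$ri],
                        f$end[combo$fi])
    product <- minus_end - plus_start + 1L
    ok <- product >= min_len & product < max_len
    if (!any(ok)) return(NULL)
    combo <- combo[ok, , drop = FALSE]
    product <- product[ok]
    gene <- bundle$transcripts$gene_id[match(tx, bundle$transcripts$transcript_id)]
    data.frame(transcript_id = tx,
               gene_id = ifelse(is.na(gene), "<unknown>", gene),
               same_gene = !is.na(gene) & gene == pair$gene_id,
               fwd_strand = f$strand[combo$fi], fwd_start = f$start[combo$fi],
               fwd_end = f$end[combo$fi],
               fwd_similarity = f$similarity[combo$fi],
               rev_strand = r$strand[combo$ri], rev_start = r$start[combo$ri],
               rev_end = r$end[combo$ri],
               rev_similarity = r$similarity[combo$ri],
               implied_product_size = as.integer(product),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(hit_frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a primer pair's off-target profile
#'
#' Three situations are distinguished. Hits confined to the intended
#' transcript itself leave the pair `clean`. Hits to sibling splice variants
#' of the intended gene make the pair `variants_only` (a strict subset of
#' the gene's variants is amplified) or `all_variants` (every variant is).
#' Any hit to a different gene makes the pair `other_gene`, or `mixed` when
#' sibling-variant hits are present as well; both set the `crosshyb_fail`
#' flag, rendering the pair unspecific.
#'
#' @param pair one candidate-table row.
#' @param hits hit table from [pair_matches_to_hits()].
#' @param bundle a `ReferenceBundle`.
#' @return list with `pair_id`, `status`, `amplified` (sorted character
#'   vector of transcript ids, always containing the intended target) and
#'   `crosshyb_fail`.
#' @export
classify_crosshyb <- function(pair, hits, bundle) {
  gene_variants <- bundle$transcripts$transcript_id[
    bundle$transcripts$gene_id == pair$gene_id]
  same_tx <- unique(hits$transcript_id[hits$same_gene])
  amplified <- sort_c(union(pair$target_id, same_tx))
  off <- hits[!hits$same_gene, , drop = FALSE]
  extra_variants <- length(setdiff(amplified, pair$target_id)) > 0L
  status <- if (nrow(off)) {
    if (extra_variants) "mixed" else "other_gene"
  } else if (!extra_variants) {
    "clean"
  } else if (setequal(amplified, gene_variants)) {
    "all_variants"
  } else "variants_only"
  list(pair_id = pair$pair_id, status = status, amplified = amplified,
       crosshyb_fail = status %in% c("other_gene", "mixed"))
}

#' Screen a candidate table for cross-hybridisation
#'
#' Runs [find_matches()] for every distinct primer sequence of the table
#' against the bundle's transcriptome, assembles per-pair hits and verdicts,
#' and sets the `crosshyb_fail` flag on unspecific pairs.
#'
#' @param pairs candidate table from [generate_candidates()].
#' @param bundle a `ReferenceBundle`.
#' @param cfg a [crosshyb_config()].
#' @param transcriptome optional [Biostrings::DNAStringSet] to screen
#'   against instead of the bundle's transcriptome (e.g. with a decoy
#'   removed).
#' @param index optional pre-built [build_tx_index()] for `transcriptome`;
#'   built on the fly when absent.
#' @return list with `pairs` (flags updated), `verdicts` (data.frame:
#'   `pair_id`, `status`, `amplified` comma-joined, `n_amplified`) and
#'   `hits` (all retained off-target candidate events with `pair_id`).
#' @export
screen_crosshyb <- function(pairs, bundle, cfg = crosshyb_config(),
                            transcriptome = NULL, index = NULL) {
  if (is.null(transcriptome)) transcriptome <- bundle$transcript_seqs
  verdicts <- data.frame(pair_id = character(0), status = character(0),
                         amplified = character(0), n_amplified = integer(0),
                         stringsAsFactors = FALSE)
  all_hits <- NULL
  if (!nrow(pairs)) return(list(pairs = pairs, verdicts = verdicts,
                                hits = hit_frame()))
  if (is.null(index))
    index <- build_tx_index(transcriptome,
                            gap = max(40L, max(nchar(c(pairs$fwd_seq,
                                                       pairs$rev_seq))) + 1L))
  cache <- new.env(parent = emptyenv())
  matches_for <- function(p) {
    if (!exists(p, envir = cache))
      assign(p, find_matches(p, transcriptome, cfg, index = index),
             envir = cache)
    get(p, envir = cache)
  }
  vrows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    hits <- pair_matches_to_hits(pr, matches_for(pr$fwd_seq),
                                 matches_for(pr$rev_seq), bundle, cfg)
    v <- classify_crosshyb(pr, hits, bundle)
    pairs$crosshyb_fail[i] <- v$crosshyb_fail
    vrows[[i]] <- data.frame(pair_id = v$pair_id, status = v$status,
                             amplified = paste(v$amplified, collapse = ","),
                             n_amplified = length(v$amplified),
                             stringsAsFactors = FALSE)
    if (nrow(hits)) {
      hits <- cbind(pair_id = pr$pair_id, hits, stringsAsFactors = FALSE)
      all_hits <- rbind(all_hits, hits)
    }
  }
  verdicts <- do.call(rbind, vrows)
  rownames(verdicts) <- NULL
  list(pairs = pairs, verdicts = verdicts,
       hits = all_hits %||% hit_frame())
}

#' Find primer matches with the external blastn backend
#'
#' Optional alternative to the internal scanner: runs `blastn -task
#' blastn-short` with `-word_size cfg$seed_length` and `-evalue
#' cfg$evalue_cutoff` against a database built from the transcriptome, then
#' applies the same strict similarity rule (identities / primer length
#' greater than `min_similarity`). Requires the BLAST+ executables on the
#' path. Being seed-based, blastn can in principle miss low-identity
#' placements that lack an exact word; on high-identity sites it agrees
#' with [find_matches()].
#'
#' @inheritParams find_matches
#' @return match data.frame in the [find_matches()] layout.
#' @export
find_matches_blast <- function(primer, transcriptome,
                               cfg = crosshyb_config()) {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop("BLAST+ executables not found on PATH", call. = FALSE)
  if (!is(transcriptome, "DNAStringSet"))
    transcriptome <- Biostrings::DNAStringSet(unlist(transcriptome))
  td <- tempfile("blastdb")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  db <- file.path(td, "tx.fa")
  Biostrings::writeXStringSet(transcriptome, db)
  system2("makeblastdb", c("-in", db, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  qf <- file.path(td, "q.fa")
  writeLines(c(">q", primer), qf)
  out <- system2("blastn",
                 c("-task", "blastn-short", "-word_size", cfg$seed_length,
                   "-evalue", format(cfg$evalue_cutoff), "-query", qf,
                   "-db", db, "-dust", "no", "-outfmt",
                   shQuote("6 sseqid nident sstart send sstrand qstart qend")),
                 stdout = TRUE)
  if (!length(out)) return(match_frame())
  f <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("sseqid", "nident", "sstart", "send",
                                       "sstrand", "qstart", "qend"))
  L <- nchar(primer)
  id_min <- floor(cfg$min_similarity * L + 1e-9) + 1L
  f <- f[f$nident >= id_min, , drop = FALSE]
  if (!nrow(f)) return(match_frame())
  plus <- f$sstrand == "plus"
  # extend the local alignment to the full primer footprint on the subject
  start <- ifelse(plus, f$sstart - (f$qstart - 1L), f$send - (L - f$qend))
  end <- ifelse(plus, f$send + (L - f$qend), f$sstart + (f$qstart - 1L))
  out <- data.frame(transcript_id = f$sseqid,
                    strand = ifelse(plus, "+", "-"),
                    start = as.integer(start), end = as.integer(end),
                    identities = as.integer(f$nident),
                    similarity = f$nident / L, stringsAsFactors = FALSE)
  lens <- setNames(Biostrings::width(transcriptome), names(transcriptome))
  out <- out[out$start >= 1L & out$end <= lens[out$transcript_id], ,
             drop = FALSE]
  out <- out[order(out$transcript_id, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
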