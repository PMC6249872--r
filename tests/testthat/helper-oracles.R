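# Independent oracles, implemented without the package's scan kernel.

# Exhaustive sliding-window alignment over every offset and both strands,
# vectorised per alignment column (no shared code with the C scanner).
oracle_find_matches <- function(primer, transcriptome, min_similarity = 0.7) {
  L <- nchar(primer)
  rows <- list()
  for (nm in names(transcriptome)) {
    tb <- strsplit(as.character(transcriptome[[nm]]), "", fixed = TRUE)[[1]]
    n <- length(tb)
    if (n < L) next
    n_win <- n - L + 1L
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") primer else revcomp(primer)
      pb <- strsplit(pat, "", fixed = TRUE)[[1]]
      idn <- integer(n_win)
      for (j in seq_len(L))
        idn <- idn + (tb[j:(n_win + j - 1L)] == pb[j])
      s <- which(idn / L > min_similarity)
      if (length(s))
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = nm, strand = strand, start = s, end = s + L - 1L,
          identities = idn[s], similarity = idn[s] / L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(transcript_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      identities = integer(0), similarity = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force REF-allele check by direct substring lookup
oracle_inconsistent_variants <- function(bundle) {
  v <- bundle$variants
  bad <- character(0)
  for (i in seq_len(nrow(v))) {
    g <- as.character(bundle$genome[[v$chrom[i]]])
    sub <- substr(g, v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L)
    if (!identical(sub, v$ref[i])) bad <- c(bad, v$variant_id[i])
  }
  bad
}

# global alignment identity via Biostrings (independent of the fixture
# generator's mutation bookkeeping)
oracle_global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::pid(aln) / 100
}
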