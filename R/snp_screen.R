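#' Corona (variant-flank) configuration
#'
#' @param flank bases extracted on each side of a variant locus when
#'   building its corona sequence; 26 accommodates any full primer up to
#'   27 nt placed over the locus.
#' @return list of class `CoronaConfig`.
#' @export
corona_config <- function(flank = 26L) {
  stopifnot(flank >= 1L)
  structure(list(flank = as.integer(flank)), class = "CoronaConfig")
}

corona_frame <- function(n = 0L) {
  data.frame(variant_id = character(n), chrom = character(n),
             start = integer(n), end = integer(n), seq = character(n),
             var_start = integer(n), var_len = integer(n),
             clipped = logical(n), usable = logical(n),
             stringsAsFactors = FALSE)
}

#' Build corona sequences around every variant inside a gene's span
#'
#' For each variant whose locus lies within the gene's genomic span, the
#' reference-genome window `[pos - flank, pos + flank + len(REF) - 1]`
#' (clipped at chromosome ends) is extracted. A corona around an SNV is
#' `2*flank + 1` bases long unless clipped. Coronas are built from the
#' reference allele only; a corona containing N is emitted but marked
#' unusable so no primer can match it.
#'
#' @param gene_id gene identifier in the bundle.
#' @param bundle a `ReferenceBundle` (variants already frequency-filtered
#'   upstream as desired).
#' @param cfg a [corona_config()].
#' @return data.frame with one corona per variant: `variant_id`, `chrom`,
#'   `start`, `end` (1-based inclusive genomic interval), `seq`,
#'   `var_start` (1-based position of the variant's first base within the
#'   corona), `var_len` (REF length), `clipped`, `usable`.
#' @export
build_coronas <- function(gene_id, bundle, cfg = corona_config()) {
  gi <- match(gene_id, bundle$genes$gene_id)
  if (is.na(gi)) stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
  g <- bundle$genes[gi, ]
  v <- bundle$variants
  v <- v[v$chrom == g$chrom & v$pos >= g$start & v$pos <= g$end, ,
         drop = FALSE]
  if (!nrow(v)) return(corona_frame())
  chrom_len <- Biostrings::width(bundle$genome[g$chrom])
  rows <- lapply(seq_len(nrow(v)), function(i) {
    ref_len <- nchar(v$ref[i])
    lo <- v$pos[i] - cfg$flank
    hi <- v$pos[i] + ref_len - 1L + cfg$flank
    clipped <- lo < 1L || hi > chrom_len
    lo2 <- max(1L, lo); hi2 <- min(chrom_len, hi)
    s <- as.character(Biostrings::subseq(bundle$genome[[g$chrom]], lo2, hi2))
    data.frame(variant_id = v$variant_id[i], chrom = g$chrom,
               start = lo2, end = hi2, seq = s,
               var_start = v$pos[i] - lo2 + 1L, var_len = ref_len,
               clipped = clipped, usable = !grepl("N", s, fixed = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

snp_hit_frame <- function(n = 0L) {
  data.frame(variant_id = character(n), match_start = integer(n),
             match_end = integer(n), strand = character(n),
             stringsAsFactors = FALSE)
}

#' Match a primer against corona sequences
#'
#' A hit is emitted if and only if the full primer sequence, or its reverse
#' complement, occurs exactly (no mismatches) within a usable corona and the
#' occurrence covers the whole variant locus. Partial-length matches are
#' ignored: a shorter match cannot place the full binding site over the
#' variant.
#'
#' @param primer primer sequence (character, `{A,C,G,T}`).
#' @param coronas corona table from [build_coronas()].
#' @return data.frame of hits: `variant_id`, `match_start`, `match_end`
#'   (1-based inclusive within the corona), `strand` (`"+"` primer as given,
#'   `"-"` reverse complement).
#' @export
match_primer_to_coronas <- function(primer, coronas) {
  assert_dna(primer, "primer")
  if (!nrow(coronas)) return(snp_hit_frame())
  pats <- c("+" = primer, "-" = revcomp(primer))
  L <- nchar(primer)
  rows <- list()
  for (i in seq_len(nrow(coronas))) {
    if (!coronas$usable[i]) next
    var_lo <- coronas$var_start[i]
    var_hi <- var_lo + coronas$var_len[i] - 1L
    nc <- nchar(coronas$seq[i])
    if (nc < L) next
    offs <- seq_len(nc - L + 1L)
    for (strand in names(pats)) {
      # all offsets, overlapping occurrences included
      st <- offs[substring(coronas$seq[i], offs, offs + L - 1L) ==
                   pats[[strand]]]
      if (!length(st)) next
      en <- st + L - 1L
      cover <- st <= var_lo & en >= var_hi
      if (!any(cover)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = coronas$variant_id[i], match_start = st[cover],
        match_end = en[cover], strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(snp_hit_frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen a candidate table for SNP contamination
#'
#' Matches each pair's forward and reverse primer against the coronas and
#' sets `snp_fail` on every pair with at least one hit in either primer.
#'
#' @param pairs candidate table from [generate_candidates()].
#' @param coronas corona table for the pairs' gene from [build_coronas()].
#' @return list with `pairs` (flags updated) and `hits` (data.frame:
#'   `pair_id`, `primer_role`, `variant_id`, `match_start`, `match_end`,
#'   `strand`).
#' @export
screen_snps <- function(pairs, coronas) {
  hits <- NULL
  if (nrow(pairs) && nrow(coronas)) {
    cache <- new.env(parent = emptyenv())
    match_cached <- function(p) {
      if (!exists(p, envir = cache))
        assign(p, match_primer_to_coronas(p, coronas), envir = cache)
      get(p, envir = cache)
    }
    for (i in seq_len(nrow(pairs))) {
      for (role in c("fwd", "rev")) {
        h <- match_cached(pairs[[paste0(role, "_seq")]][i])
        if (nrow(h)) {
          pairs$snp_fail[i] <- TRUE
          hits <- rbind(hits, cbind(pair_id = pairs$pair_id[i],
                                    primer_role = role, h,
                                    stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(hits))
    hits <- cbind(data.frame(pair_id = character(0),
                             primer_role = character(0),
                             stringsAsFactors = FALSE), snp_hit_frame())
  rownames(hits) <- NULL
  list(pairs = pairs, hits = hits)
}
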