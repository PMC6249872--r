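#' Primer-generation configuration
#'
#' Parameters governing candidate primer-pair enumeration. Defaults follow
#' standard qPCR assay practice: products of 80-150 bp (optimum 115 bp) in
#' standard mode, 50-70 bp (optimum 60 bp) for short targets, targets below
#' 50 bp excluded outright, primers restricted to the 3'-most 1500 bases of
#' the target, melting temperatures computed at 200 mM monovalent salt, and
#' an annealing temperature of 60 degrees Celsius.
#'
#' @param n_pairs_requested maximum number of candidate pairs per target.
#' @param product_range_standard,product_opt_standard standard-mode product
#'   size window (bp) and optimum.
#' @param product_range_short,product_opt_short short-mode window and optimum.
#' @param min_target_length targets shorter than this are excluded.
#' @param three_prime_window primers must lie within this many bases of the
#'   target's 3' end.
#' @param monovalent_salt monovalent cation concentration in mM.
#' @param annealing_temp assay annealing temperature in degrees Celsius.
#' @param primer_length primer length range enumerated by the internal
#'   generator.
#' @param gc_range admissible primer GC-content window (fractions).
#' @param tm_range admissible primer melting-temperature window (Celsius).
#' @return list of class `GenerationConfig`.
#' @export
generation_config <- function(n_pairs_requested = 200L,
                              product_range_standard = c(80L, 150L),
                              product_opt_standard = 115L,
                              product_range_short = c(50L, 70L),
                              product_opt_short = 60L,
                              min_target_length = 50L,
                              three_prime_window = 1500L,
                              monovalent_salt = 200,
                              annealing_temp = 60,
                              primer_length = c(18L, 27L),
                              gc_range = c(0.40, 0.60),
                              tm_range = c(58, 62)) {
  stopifnot(product_range_standard[1] <= product_range_standard[2],
            product_range_short[1] <= product_range_short[2],
            n_pairs_requested >= 1L, three_prime_window >= 1L,
            monovalent_salt > 0)
  structure(list(n_pairs_requested = as.integer(n_pairs_requested),
                 product_range_standard = as.integer(product_range_standard),
                 product_opt_standard = as.integer(product_opt_standard),
                 product_range_short = as.integer(product_range_short),
                 product_opt_short = as.integer(product_opt_short),
                 min_target_length = as.integer(min_target_length),
                 three_prime_window = as.integer(three_prime_window),
                 monovalent_salt = monovalent_salt,
                 annealing_temp = annealing_temp,
                 primer_length = as.integer(primer_length),
                 gc_range = gc_range, tm_range = tm_range),
            class = "GenerationConfig")
}

target_too_short <- function(target_id, length) {
  structure(class = c("target_too_short", "error", "condition"),
            list(message = sprintf(
              "target '%s' is %d bp, below the %s", target_id, length,
              "minimum target length"),
              call = NULL, target_id = target_id, length = length))
}

#' Generate candidate primer pairs for one target transcript
#'
#' Enumerates every primer window of the configured length range within the
#' 3'-most `three_prime_window` bases of the target, keeps windows passing
#' the GC and melting-temperature filters, forms all forward/reverse
#' combinations whose product size falls in the active window, scores each
#' pair by mean |Tm - annealing_temp| plus |product - optimum|, and returns
#' the best `n_pairs_requested` pairs. Standard product sizing is used
#' whenever the effective target admits a standard-size product; shorter
#' targets switch to the short window; targets below `min_target_length`
#' raise a `target_too_short` condition.
#'
#' @param target a target record as returned by [transcript_record()]
#'   (list with `transcript_id`, `gene_id`, `sequence`).
#' @param cfg a [generation_config()].
#' @return data.frame of candidate pairs, one row per pair, with columns
#'   `pair_id`, `target_id`, `gene_id`, `fwd_seq`, `rev_seq`, `fwd_start`,
#'   `fwd_end`, `rev_start`, `rev_end` (1-based inclusive positions of the
#'   binding sites on the target), `product_size`, `tm_fwd`, `tm_rev`,
#'   `penalty_rank` (0 = best) and the screen flags `crosshyb_fail`,
#'   `snp_fail`, `generation_fail` (all `FALSE` on emission). The attribute
#'   `mode` records `"standard"` or `"short"`.
#' @export
generate_candidates <- function(target, cfg = generation_config()) {
  seq <- toupper(target$sequence)
  assert_dna(seq, "target", allow_n = TRUE)
  n_full <- nchar(seq)
  if (n_full < cfg$min_target_length)
    stop(target_too_short(target$transcript_id, n_full))

  offset <- max(0L, n_full - cfg$three_prime_window)  # bases trimmed from 5'
  eff <- substr(seq, offset + 1L, n_full)
  n <- nchar(eff)

  standard <- n >= cfg$product_range_standard[1]
  prange <- if (standard) cfg$product_range_standard else cfg$product_range_short
  popt <- if (standard) cfg$product_opt_standard else cfg$product_opt_short

  widths <- seq(cfg$primer_length[1], cfg$primer_length[2])
  wins <- lapply(widths, function(w) {
    d <- tm_windows(eff, w, cfg$monovalent_salt)
    d$width <- w
    d[!d$has_n &
        d$gc >= cfg$gc_range[1] & d$gc <= cfg$gc_range[2] &
        d$tm >= cfg$tm_range[1] & d$tm <= cfg$tm_range[2], , drop = FALSE]
  })
  wins <- do.call(rbind, wins)
  empty <- candidate_frame(0L)
  attr(empty, "mode") <- if (standard) "standard" else "short"
  if (is.null(wins) || nrow(wins) == 0L) return(empty)
  wins$end <- wins$start + wins$width - 1L

  # pair forward windows with reverse windows per product size, keeping a
  # running top-K so memory stays bounded on primer-dense targets
  keep_k <- 5L * cfg$n_pairs_requested
  by_end <- split(seq_len(nrow(wins)), wins$end)
  best <- NULL
  for (p in seq(prange[1], prange[2])) {
    rev_idx_list <- by_end[as.character(wins$start + p - 1L)]
    counts <- vapply(rev_idx_list, function(x) if (is.null(x)) 0L else length(x),
                     integer(1))
    f_rows <- rep(seq_len(nrow(wins)), counts)
    if (!length(f_rows)) next
    r_rows <- unlist(rev_idx_list[counts > 0L], use.names = FALSE)
    cand <- data.frame(f = f_rows, r = r_rows, product = p)
    # reverse site must not start before the forward site ends
    ok <- wins$start[cand$r] > wins$end[cand$f]
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    cand$score <- (abs(wins$tm[cand$f] - cfg$annealing_temp) +
                     abs(wins$tm[cand$r] - cfg$annealing_temp)) / 2 +
      abs(p - popt)
    best <- rbind(best, cand)
    if (nrow(best) > keep_k)
      best <- best[order(best$score)[seq_len(keep_k)], , drop = FALSE]
  }
  if (is.null(best) || nrow(best) == 0L) return(empty)

  ord <- order(best$score, wins$start[best$f], best$product,
               wins$width[best$f], wins$width[best$r])
  best <- best[ord[seq_len(min(nrow(best), cfg$n_pairs_requested))], ,
               drop = FALSE]

  fwd_start <- wins$start[best$f] + offset
  fwd_end <- wins$end[best$f] + offset
  rev_start <- wins$start[best$r] + offset
  rev_end <- wins$end[best$r] + offset
  pairs <- data.frame(
    pair_id = sprintf("%s:P%04d", target$transcript_id,
                      seq_len(nrow(best))),
    target_id = target$transcript_id,
    gene_id = target$gene_id %||% NA_character_,
    fwd_seq = substring(seq, fwd_start, fwd_end),
    rev_seq = revcomp(substring(seq, rev_start, rev_end)),
    fwd_start = fwd_start, fwd_end = fwd_end,
    rev_start = rev_start, rev_end = rev_end,
    product_size = best$product,
    tm_fwd = wins$tm[best$f], tm_rev = wins$tm[best$r],
    penalty_rank = seq_len(nrow(best)) - 1L,
    crosshyb_fail = FALSE, snp_fail = FALSE, generation_fail = FALSE,
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  attr(pairs, "mode") <- if (standard) "standard" else "short"
  pairs
}

candidate_frame <- function(n) {
  data.frame(pair_id = character(n), target_id = character(n),
             gene_id = character(n), fwd_seq = character(n),
             rev_seq = character(n), fwd_start = integer(n),
             fwd_end = integer(n), rev_start = integer(n),
             rev_end = integer(n), product_size = integer(n),
             tm_fwd = numeric(n), tm_rev = numeric(n),
             penalty_rank = integer(n), crosshyb_fail = logical(n),
             snp_fail = logical(n), generation_fail = logical(n),
             stringsAsFactors = FALSE)
}

#' Export candidate pairs as TSV
#'
#' Positions are converted to 0-based half-open intervals on the target.
#'
#' @param pairs candidate table from [generate_candidates()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_candidates_tsv <- function(pairs, path) {
  out <- pairs
  out$fwd_start <- out$fwd_start - 1L
  out$rev_start <- out$rev_start - 1L
  write_tsv(out, path)
}
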