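#' Apply the three primer-pair quality criteria
#'
#' A pair survives only if neither primer cross-hybridises to another gene,
#' neither primer overlaps a known variant, and the pair passed the
#' generation-step criteria. Survivors are returned unchanged.
#'
#' @param pairs candidate table with screen flags set.
#' @return the surviving subset of `pairs`.
#' @export
apply_quality_criteria <- function(pairs) {
  out <- pairs[!pairs$crosshyb_fail & !pairs$snp_fail &
                 !pairs$generation_fail, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group surviving pairs into splice-variant categories
#'
#' Pairs are partitioned by the exact subset of the gene's splice variants
#' they can amplify (from the cross-hybridisation verdicts); each distinct
#' subset becomes one category and ultimately one assay.
#'
#' @param pairs surviving candidate table (see [apply_quality_criteria()]).
#' @param verdicts verdict table from [screen_crosshyb()].
#' @return data.frame with one row per category: `gene_id`, `category_key`
#'   (comma-joined sorted transcript ids), `n_variants`, `n_members`, and a
#'   list-column `members` of pair ids.
#' @export
categorise_pairs <- function(pairs, verdicts) {
  if (!nrow(pairs))
    return(data.frame(gene_id = character(0), category_key = character(0),
                      n_variants = integer(0), n_members = integer(0),
                      members = I(list()), stringsAsFactors = FALSE))
  amp <- verdicts$amplified[match(pairs$pair_id, verdicts$pair_id)]
  if (anyNA(amp))
    stop("pair without a cross-hybridisation verdict", call. = FALSE)
  keys <- sort_c(unique(amp))
  out <- data.frame(
    gene_id = pairs$gene_id[match(keys, amp)],
    category_key = keys,
    n_variants = lengths(strsplit(keys, ",", fixed = TRUE)),
    n_members = as.integer(table(amp)[keys]),
    stringsAsFactors = FALSE)
  out$members <- I(lapply(keys, function(k) pairs$pair_id[amp == k]))
  rownames(out) <- NULL
  out
}

#' Select the assay pair of one category
#'
#' Within a category the pair with the maximum dimer MFE (least negative,
#' least dimer-prone) wins; ties are broken by lower generator penalty
#' rank, then lexicographic pair id, giving a deterministic total order.
#'
#' @param category one row of the table from [categorise_pairs()].
#' @param pairs scored candidate table (must carry `dimer_mfe`).
#' @param target target record of the intended transcript (for the amplicon
#'   sequence).
#' @param assay_id identifier for the resulting assay.
#' @param protocol static reagent/cycler protocol template attached
#'   verbatim to the assay.
#' @return list of class `AssayRecord`.
#' @export
select_best <- function(category, pairs, target, assay_id = NULL,
                        protocol = default_protocol()) {
  members <- pairs[pairs$pair_id %in% category$members[[1]], , drop = FALSE]
  stopifnot(nrow(members) >= 1L, !is.null(members$dimer_mfe))
  ord <- order(-members$dimer_mfe, members$penalty_rank, members$pair_id)
  best <- members[ord[1L], ]
  amplicon <- substr(target$sequence, best$fwd_start, best$rev_end)
  structure(list(
    assay_id = assay_id %||% sprintf("%s|%s", best$gene_id,
                                     category$category_key),
    gene_id = best$gene_id, target_id = best$target_id,
    pair_id = best$pair_id,
    fwd_seq = best$fwd_seq, rev_seq = best$rev_seq,
    fwd_start = best$fwd_start, fwd_end = best$fwd_end,
    rev_start = best$rev_start, rev_end = best$rev_end,
    amplicon_seq = amplicon, product_size = best$product_size,
    amplified_variants = strsplit(category$category_key, ",",
                                  fixed = TRUE)[[1]],
    tm_fwd = best$tm_fwd, tm_rev = best$tm_rev,
    dimer_mfe = best$dimer_mfe,
    hairpin_fwd_mfe = best$hairpin_fwd_mfe %||% NA_real_,
    hairpin_rev_mfe = best$hairpin_rev_mfe %||% NA_real_,
    quality_label = "supported", protocol = protocol,
    created = format(Sys.Date())), class = "AssayRecord")
}

#' Default reagent and cycler protocol template
#'
#' A static template attached verbatim to every assay; the chemistry is a
#' placeholder for a lab-specific universal protocol.
#'
#' @return named list describing reagents and the thermal program.
#' @export
default_protocol <- function() {
  list(reagents = "universal qPCR master mix, 200 nM each primer",
       cycler = list(initial_denaturation = "95C 120s",
                     cycles = 40L,
                     denaturation = "95C 15s",
                     annealing_extension = "60C 60s"))
}

#' Summarise the outcome of one gene
#'
#' @param gene_id gene identifier.
#' @param categories category table for the gene (possibly 0 rows).
#' @param too_short was the target excluded for being shorter than the
#'   minimum target length?
#' @return data.frame row: `gene_id`, `status` (`assays_generated`,
#'   `no_valid_pair` or `too_short`), `n_categories`.
#' @export
summarise_gene <- function(gene_id, categories, too_short = FALSE) {
  status <- if (too_short) "too_short"
  else if (nrow(categories) >= 1L) "assays_generated"
  else "no_valid_pair"
  data.frame(gene_id = gene_id, status = status,
             n_categories = if (too_short) 0L else nrow(categories),
             stringsAsFactors = FALSE)
}
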