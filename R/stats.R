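#' Accumulate run statistics from per-target results
#'
#' Gathers the tallies and distributions reported for an assay-generation
#' run: number of targets and assays, exclusion counts, total candidate
#' pairs `n_p`, pairs flagged for cross-hybridisation `n_X` and for SNP
#' contamination `n_SNP` (independent tallies: a pair failing both counts
#' in each), the forward-minus-reverse melting-temperature differences of
#' all candidates, dimer-MFE values before filtering and after selection,
#' category histograms, and per-gene target length with outcome.
#'
#' @param results list of per-target result records as produced by
#'   [run_pipeline()] (each with `target_id`, `gene_id`, `length`,
#'   `status`, `pairs`, `categories`, `assays`).
#' @return list of class `RunStats`.
#' @export
accumulate_stats <- function(results) {
  pairs_list <- Filter(Negate(is.null), lapply(results, `[[`, "pairs"))
  pairs_all <- if (length(pairs_list)) do.call(rbind, pairs_list)
  else candidate_frame(0L)
  status <- vapply(results, `[[`, character(1), "status")
  assays <- unlist(lapply(results, `[[`, "assays"), recursive = FALSE)
  n_categories <- vapply(results, function(r)
    if (is.null(r$categories)) 0L else nrow(r$categories), integer(1))
  variants_per_category <- unlist(lapply(results, function(r)
    if (is.null(r$categories) || !nrow(r$categories)) integer(0)
    else r$categories$n_variants))
  stats <- list(
    n_targets = length(results),
    n_assays = length(assays),
    n_excluded_quality = sum(status == "no_valid_pair"),
    n_excluded_short = sum(status == "too_short"),
    n_p = nrow(pairs_all),
    n_X = sum(pairs_all$crosshyb_fail),
    n_SNP = sum(pairs_all$snp_fail),
    n_survivors = sum(!pairs_all$crosshyb_fail & !pairs_all$snp_fail &
                        !pairs_all$generation_fail),
    dtm_values = pairs_all$tm_fwd - pairs_all$tm_rev,
    mfe_before = if (!is.null(pairs_all$dimer_mfe))
      pairs_all$dimer_mfe[!is.na(pairs_all$dimer_mfe)] else numeric(0),
    mfe_after = vapply(assays, `[[`, numeric(1), "dimer_mfe"),
    categories_per_gene = data.frame(
      gene_id = vapply(results, `[[`, character(1), "gene_id"),
      n_categories = n_categories, stringsAsFactors = FALSE),
    variants_per_category = as.integer(variants_per_category),
    length_by_outcome = data.frame(
      gene_id = vapply(results, `[[`, character(1), "gene_id"),
      length = vapply(results, `[[`, integer(1), "length"),
      status = status, stringsAsFactors = FALSE))
  stopifnot(stats$n_X <= stats$n_p, stats$n_SNP <= stats$n_p,
            stats$n_excluded_quality + stats$n_excluded_short +
              sum(status == "assays_generated") == stats$n_targets)
  structure(stats, class = "RunStats")
}

#' Empirical CDFs of target length for failed vs successful assays
#'
#' Targets longer than `max_length` (outside the 3'-window restriction) are
#' excluded from this analysis. Each group's curve is a monotone
#' non-decreasing step function reaching 1 at its largest length; a group
#' with no members is omitted with a warning.
#'
#' @param length_by_outcome data.frame with `length` and `status` columns
#'   (from [accumulate_stats()]).
#' @param max_length upper length bound of the analysis (default 1500).
#' @return data.frame with columns `group` (`"failed"`/`"successful"`),
#'   `length` and `p` (cumulative probability at that length).
#' @export
length_cdf <- function(length_by_outcome, max_length = 1500L) {
  d <- length_by_outcome[length_by_outcome$length <= max_length, ,
                         drop = FALSE]
  groups <- list(failed = d$length[d$status == "no_valid_pair"],
                 successful = d$length[d$status == "assays_generated"])
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (!length(x)) {
      warning(sprintf("no targets in group '%s'; CDF omitted", g),
              call. = FALSE)
      return(NULL)
    }
    x <- sort(x)
    ux <- unique(x)
    data.frame(group = g, length = ux,
               p = cumsum(as.integer(table(x))) / length(x),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(group = character(0), length = integer(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

hist_counts <- function(x, binwidth) {
  if (!length(x))
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  lo <- floor(min(x) / binwidth) * binwidth
  hi <- ceiling(max(x) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  data.frame(bin_lo = utils::head(h$breaks, -1),
             bin_hi = utils::tail(h$breaks, -1), count = h$counts)
}

#' Export the run-statistics report
#'
#' Writes `stats.json` plus the per-figure TSVs: discard tallies, the
#' melting-temperature-difference histogram (0.25 degree bins), the
#' failed/successful target-length CDFs, the dimer-MFE distributions before
#' filtering and after selection (0.5 kcal/mol bins), and the category
#' histograms.
#'
#' @param stats a `RunStats` object.
#' @param out_dir output directory, created if needed.
#' @param dtm_binwidth,mfe_binwidth histogram bin widths.
#' @return invisibly, the vector of written paths.
#' @export
export_report <- function(stats, out_dir, dtm_binwidth = 0.25,
                          mfe_binwidth = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, "stats.json")
  jsonlite::write_json(unclass(stats), p, dataframe = "columns",
                       digits = NA, pretty = TRUE, auto_unbox = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "fig2_discards.tsv")
  write_tsv(data.frame(metric = c("n_p", "n_X", "n_SNP", "n_survivors"),
                       count = c(stats$n_p, stats$n_X, stats$n_SNP,
                                 stats$n_survivors)), p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "fig2_dtm.tsv")
  write_tsv(hist_counts(stats$dtm_values, dtm_binwidth), p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "fig3_cdf.tsv")
  cdf <- withCallingHandlers(length_cdf(stats$length_by_outcome),
                             warning = function(w) invokeRestart("muffleWarning"))
  write_tsv(cdf, p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "fig4_mfe.tsv")
  mfe <- rbind(cbind(set = "before", hist_counts(stats$mfe_before, mfe_binwidth)),
               cbind(set = "after", hist_counts(stats$mfe_after, mfe_binwidth)))
  write_tsv(mfe, p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "fig5_categories.tsv")
  cat_hist <- as.data.frame(table(stats$categories_per_gene$n_categories),
                            stringsAsFactors = FALSE)
  names(cat_hist) <- c("n_categories", "n_genes")
  var_hist <- as.data.frame(table(stats$variants_per_category),
                            stringsAsFactors = FALSE)
  names(var_hist) <- c("n_variants", "n_categories")
  both <- rbind(
    data.frame(histogram = "assays_per_gene", value = cat_hist$n_categories,
               count = cat_hist$n_genes, stringsAsFactors = FALSE),
    data.frame(histogram = "variants_per_category", value = var_hist$n_variants,
               count = var_hist$n_categories, stringsAsFactors = FALSE))
  write_tsv(both, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Reload an exported `stats.json`
#'
#' @param path path to a `stats.json` written by [export_report()].
#' @return a `RunStats` object.
#' @export
read_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$dtm_values <- as.numeric(x$dtm_values)
  x$mfe_before <- as.numeric(x$mfe_before)
  x$mfe_after <- as.numeric(x$mfe_after)
  x$variants_per_category <- as.integer(x$variants_per_category)
  for (f in c("n_targets", "n_assays", "n_excluded_quality",
              "n_excluded_short", "n_p", "n_X", "n_SNP", "n_survivors"))
    x[[f]] <- as.integer(x[[f]])
  x$categories_per_gene <- as.data.frame(x$categories_per_gene,
                                         stringsAsFactors = FALSE)
  x$length_by_outcome <- as.data.frame(x$length_by_outcome,
                                       stringsAsFactors = FALSE)
  structure(x, class = "RunStats")
}
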