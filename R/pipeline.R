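#' Run configuration for the assay-design pipeline
#'
#' Bundles reference paths, the target list and all stage configurations.
#' The configuration validates eagerly and is serialised verbatim into the
#' output directory for provenance.
#'
#' @param genome_path,gff_path,transcriptome_path,vcf_path reference files
#'   (may be `NULL` when an in-memory bundle is passed to
#'   [run_pipeline()]).
#' @param targets character vector of target transcript ids, or `"all"`.
#' @param generation a [generation_config()].
#' @param crosshyb a [crosshyb_config()].
#' @param corona a [corona_config()].
#' @param structure_backend `"vienna"` or `"stub"` (see
#'   [structure_backend_vienna()]).
#' @param min_freq variant-frequency cut passed to
#'   [filter_variants_by_frequency()].
#' @param keep_missing_freq retain variants without frequency annotation?
#' @param workers per-target worker processes; the outputs are independent
#'   of this value.
#' @param seed integer seed for all randomness in the run.
#' @param out_dir optional output directory.
#' @param allow_inconsistent proceed despite REF-allele inconsistencies?
#' @return list of class `RunConfig`.
#' @export
run_config <- function(genome_path = NULL, gff_path = NULL,
                       transcriptome_path = NULL, vcf_path = NULL,
                       targets = "all", generation = generation_config(),
                       crosshyb = crosshyb_config(), corona = corona_config(),
                       structure_backend = c("vienna", "stub"),
                       min_freq = 0.01, keep_missing_freq = TRUE,
                       workers = 1L, seed = 1L, out_dir = NULL,
                       allow_inconsistent = FALSE) {
  structure_backend <- match.arg(structure_backend)
  stopifnot(workers >= 1L, min_freq >= 0, min_freq <= 1)
  structure(list(genome_path = genome_path, gff_path = gff_path,
                 transcriptome_path = transcriptome_path,
                 vcf_path = vcf_path, targets = targets,
                 generation = generation, crosshyb = crosshyb,
                 corona = corona, structure_backend = structure_backend,
                 min_freq = min_freq, keep_missing_freq = keep_missing_freq,
                 workers = as.integer(workers), seed = as.integer(seed),
                 out_dir = out_dir, allow_inconsistent = allow_inconsistent),
            class = "RunConfig")
}

#' Run the full assay-design pipeline
#'
#' For every target transcript: candidate primer pairs are generated,
#' screened for cross-hybridisation across the transcriptome and for SNPs
#' inside the gene's genomic span, scored for hairpin and dimer MFE,
#' reduced to the surviving pairs, grouped into splice-variant categories,
#' and one assay per category is selected by maximum dimer MFE. Per-target
#' work is independent and deterministic given the seed, so the worker
#' count never changes any output; results are merged in sorted target
#' order.
#'
#' @param config a [run_config()].
#' @param bundle optional pre-loaded `ReferenceBundle`; when `NULL` the
#'   references are loaded from the config paths.
#' @return list with `assays` (list of `AssayRecord`), `results`
#'   (per-target records), `outcomes` (per-gene outcome table), `stats`
#'   (a `RunStats`), and `config`. Output files are written when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config = run_config(), bundle = NULL) {
  if (is.null(bundle))
    bundle <- load_references(config$genome_path, config$gff_path,
                              config$transcriptome_path, config$vcf_path)
  inco <- check_variant_consistency(bundle)
  if (nrow(inco) && !config$allow_inconsistent)
    stop(sprintf(
      "reference bundle inconsistent: %d variant(s) disagree with the genome (first: %s); use allow_inconsistent to proceed",
      nrow(inco), inco$variant_id[1]), call. = FALSE)
  bundle <- filter_variants_by_frequency(bundle, config$min_freq,
                                         config$keep_missing_freq)

  ids <- if (identical(config$targets, "all"))
    sort_c(bundle$transcripts$transcript_id) else sort_c(config$targets)
  missing <- setdiff(ids, bundle$transcripts$transcript_id)
  if (length(missing))
    stop(sprintf("unknown target transcript(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  backend <- switch(config$structure_backend,
                    vienna = structure_backend_vienna(
                      temp = config$generation$annealing_temp),
                    stub = structure_backend_stub(
                      temp = config$generation$annealing_temp))

  tx_index <- build_tx_index(bundle$transcript_seqs)
  worker <- function(i) {
    with_seed(config$seed + i,
              process_target(ids[i], bundle, config, backend, tx_index))
  }
  results <- if (config$workers > 1L)
    parallel::mclapply(seq_along(ids), worker, mc.cores = config$workers)
  else lapply(seq_along(ids), worker)
  failed <- vapply(results, function(r) inherits(r, "try-error") ||
                     is.null(r$status), logical(1))
  if (any(failed))
    stop("internal: unprocessed target", call. = FALSE)

  outcomes <- do.call(rbind, lapply(results, `[[`, "outcome"))
  rownames(outcomes) <- NULL
  assays <- unlist(lapply(results, `[[`, "assays"), recursive = FALSE)
  stats <- accumulate_stats(results)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(serialisable_config(config),
                     file.path(config$out_dir, "run_config.yaml"))
    write_assay_outputs(assays, config$out_dir)
    pairs_list <- Filter(Negate(is.null), lapply(results, `[[`, "pairs"))
    if (length(pairs_list))
      export_candidates_tsv(do.call(rbind, pairs_list),
                            file.path(config$out_dir, "pairs.tsv"))
    write_tsv(outcomes, file.path(config$out_dir, "outcomes.tsv"))
    export_report(stats, config$out_dir)
  }
  list(assays = assays, results = results, outcomes = outcomes,
       stats = stats, config = config)
}

serialisable_config <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace")
}

process_target <- function(target_id, bundle, config, backend,
                           tx_index = NULL) {
  rec <- transcript_record(bundle, target_id)
  len <- nchar(rec$sequence)
  base <- list(target_id = target_id, gene_id = rec$gene_id, length = len)

  pairs <- tryCatch(generate_candidates(rec, config$generation),
                    target_too_short = function(e) e)
  if (inherits(pairs, "target_too_short")) {
    out <- c(base, list(status = "too_short", pairs = NULL, verdicts = NULL,
                        categories = NULL, assays = list(),
                        outcome = summarise_gene(rec$gene_id,
                                                 categorise_pairs(
                                                   candidate_frame(0L),
                                                   NULL),
                                                 too_short = TRUE)))
    return(out)
  }

  err <- NULL
  res <- tryCatch({
    ch <- screen_crosshyb(pairs, bundle, config$crosshyb, index = tx_index)
    coronas <- build_coronas(rec$gene_id, bundle, config$corona)
    sn <- screen_snps(ch$pairs, coronas)
    scored <- score_structures(sn$pairs, backend)
    survivors <- apply_quality_criteria(scored)
    categories <- categorise_pairs(survivors, ch$verdicts)
    assays <- list()
    if (nrow(categories)) {
      for (k in seq_len(nrow(categories))) {
        a <- select_best(categories[k, , drop = FALSE], scored, rec,
                         assay_id = sprintf("%s|%s.A%d", rec$gene_id,
                                            target_id, k))
        assays[[length(assays) + 1L]] <- a
      }
    }
    list(pairs = scored, verdicts = ch$verdicts, hits = ch$hits,
         snp_hits = sn$hits, categories = categories, assays = assays)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    # quarantine the target: record the failure, keep the run going
    return(c(base, list(status = "no_valid_pair", pairs = pairs,
                        verdicts = NULL, categories = NULL, assays = list(),
                        error = conditionMessage(res),
                        outcome = summarise_gene(rec$gene_id,
                                                 categorise_pairs(
                                                   candidate_frame(0L), NULL)))))
  }
  status <- if (length(res$assays)) "assays_generated" else "no_valid_pair"
  c(base, list(status = status), res,
    list(outcome = summarise_gene(rec$gene_id, res$categories)))
}

#' Write assay output files
#'
#' Emits `assays.json` (full records), `assays.tsv` (flat table),
#' `primers.fa` (forward/reverse primer per assay), `amplicons.fa`, and
#' `primers.bed` with 0-based half-open binding intervals on the target
#' transcript.
#'
#' @param assays list of `AssayRecord`s.
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
write_assay_outputs <- function(assays, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ord <- order(vapply(assays, `[[`, character(1), "assay_id"))
  assays <- assays[ord]
  paths <- file.path(out_dir, c("assays.json", "assays.tsv", "primers.fa",
                                "amplicons.fa", "primers.bed"))
  jsonlite::write_json(lapply(assays, unclass), paths[1], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  flat <- do.call(rbind, lapply(assays, function(a) data.frame(
    assay_id = a$assay_id, gene_id = a$gene_id, target_id = a$target_id,
    fwd_seq = a$fwd_seq, rev_seq = a$rev_seq,
    product_size = a$product_size,
    n_amplified = length(a$amplified_variants),
    amplified_variants = paste(a$amplified_variants, collapse = ","),
    tm_fwd = a$tm_fwd, tm_rev = a$tm_rev, dimer_mfe = a$dimer_mfe,
    quality_label = a$quality_label, created = a$created,
    stringsAsFactors = FALSE)))
  if (is.null(flat)) flat <- data.frame(assay_id = character(0))
  write_tsv(flat, paths[2])
  fa <- unlist(lapply(assays, function(a)
    c(sprintf(">%s|fwd", a$assay_id), a$fwd_seq,
      sprintf(">%s|rev", a$assay_id), a$rev_seq)))
  writeLines(fa %||% character(0), paths[3])
  amp <- unlist(lapply(assays, function(a)
    c(sprintf(">%s", a$assay_id), a$amplicon_seq)))
  writeLines(amp %||% character(0), paths[4])
  bed <- unlist(lapply(assays, function(a) c(
    sprintf("%s\t%d\t%d\t%s|fwd\t0\t+", a$target_id, a$fwd_start - 1L,
            a$fwd_end, a$assay_id),
    sprintf("%s\t%d\t%d\t%s|rev\t0\t-", a$target_id, a$rev_start - 1L,
            a$rev_end, a$assay_id))))
  writeLines(bed %||% character(0), paths[5])
  invisible(paths)
}
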