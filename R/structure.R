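#' Secondary-structure backends
#'
#' Hairpin and primer-dimer minimum free energies (MFE, kcal/mol) are
#' computed by a pluggable backend. The default backend drives the
#' ViennaRNA command-line programs (`RNAfold` for single-strand folds,
#' `RNAcofold` for bimolecular structures) with a DNA parameter set at the
#' assay annealing temperature. A deterministic rule-based stub backend is
#' provided so that ranking and selection logic can be exercised without
#' the thermodynamics engine.
#'
#' "No stable structure" is encoded as an MFE of exactly `0.0` with an
#' empty structure string; under max-MFE selection this naturally sorts as
#' the least dimer-prone value.
#'
#' @param temp folding temperature in degrees Celsius.
#' @param param_file path to a ViennaRNA energy-parameter file; defaults to
#'   the DNA (mathews2004) set shipped with the installed ViennaRNA.
#' @return list of class `StructureBackend`.
#' @export
structure_backend_vienna <- function(temp = 60, param_file = NULL) {
  structure(list(type = "vienna", temp = temp,
                 param_file = param_file %||% vienna_dna_params()),
            class = "StructureBackend")
}

#' @rdname structure_backend_vienna
#' @param mfe_table optional named numeric vector overriding the stub's
#'   rule; names are primer sequences (hairpins) or `"SEQ1&SEQ2"` keys with
#'   the two sequences in sorted order (dimers).
#' @export
structure_backend_stub <- function(temp = 60, mfe_table = NULL) {
  structure(list(type = "stub", temp = temp, mfe_table = mfe_table),
            class = "StructureBackend")
}

vienna_dna_params <- function() {
  rnafold <- Sys.which("RNAfold")
  if (rnafold == "") return(NA_character_)
  cand <- file.path(dirname(dirname(rnafold)), "share", "ViennaRNA",
                    "dna_mathews2004.par")
  if (file.exists(cand)) cand else NA_character_
}

backend_missing <- function(what) {
  structure(class = c("backend_missing", "error", "condition"),
            list(message = sprintf(
              "structure backend unavailable: %s", what), call = NULL))
}

run_vienna <- function(prog, seqs, backend) {
  if (Sys.which(prog) == "") stop(backend_missing(sprintf(
    "'%s' not found on PATH", prog)))
  if (is.na(backend$param_file) || !file.exists(backend$param_file))
    stop(backend_missing("DNA parameter file not found"))
  input <- as.vector(rbind(sprintf(">q%d", seq_along(seqs)), seqs))
  out <- suppressWarnings(system2(
    prog, c("--noPS", "-P", backend$param_file, "-T", format(backend$temp)),
    input = input, stdout = TRUE, stderr = FALSE))
  parse_vienna(out, length(seqs))
}

parse_vienna <- function(lines, n) {
  mfe <- rep(NA_real_, n)
  struct <- rep(NA_character_, n)
  cur <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur <- as.integer(sub("^>q", "", ln))
      next
    }
    m <- regmatches(ln, regexec("^([.()&]+)\\s+\\(\\s*(-?[0-9]+\\.?[0-9]*)\\)\\s*$", ln))[[1]]
    if (length(m) == 3L && cur >= 1L && cur <= n && is.na(mfe[cur])) {
      mfe[cur] <- as.numeric(m[3])
      struct[cur] <- m[2]
    }
  }
  if (anyNA(mfe)) stop("failed to parse ViennaRNA output", call. = FALSE)
  # clamp: a fold no more stable than the open chain counts as no structure
  none <- mfe >= 0
  mfe[none] <- 0
  struct[none] <- ""
  data.frame(mfe = mfe, structure = struct, stringsAsFactors = FALSE)
}

# longest Watson-Crick complementary run between a and b (LCS of a and
# revcomp(b)); used by the stub backend as a structure-propensity proxy
longest_comp_run <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(revcomp(b), "", fixed = TRUE)[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    curr <- integer(length(y))
    match_i <- x[i] == y
    curr[match_i] <- 1L
    if (i > 1L) {
      idx <- which(match_i & seq_along(y) > 1L)
      curr[idx] <- prev[idx - 1L] + 1L
    }
    best <- max(best, curr)
    prev <- curr
  }
  best
}

stub_hairpin <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  best <- 0L
  for (i in seq_len(n)) {
    if (i + 4L > n) break
    for (j in n:(i + 4L)) {
      k <- 0L
      while (i + k < j - k - 3L && comp[[b[i + k]]] == b[j - k]) k <- k + 1L
      best <- max(best, k)
    }
  }
  if (best >= 4L) -1.2 * (best - 3L) else 0
}

#' Hairpin minimum free energy per primer
#'
#' @param primers character vector of primer sequences (N-free, >= 8 nt).
#' @param backend a `StructureBackend`.
#' @return data.frame with one row per primer: `mfe` (kcal/mol, `0.0` when
#'   no structure folds below zero) and `structure` (dot-bracket, empty for
#'   no structure).
#' @export
hairpin_mfe <- function(primers, backend = structure_backend_vienna()) {
  if (!length(primers))
    return(data.frame(mfe = numeric(0), structure = character(0)))
  assert_dna(primers, "primer")
  if (any(nchar(primers) < 8L)) stop("primer shorter than 8 nt", call. = FALSE)
  if (backend$type == "vienna") return(run_vienna("RNAfold", primers, backend))
  mfe <- vapply(primers, function(s) {
    tab <- backend$mfe_table
    if (!is.null(tab) && s %in% names(tab)) tab[[s]] else stub_hairpin(s)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(mfe = pmin(mfe, 0),
             structure = ifelse(mfe < 0, "<stub>", ""),
             stringsAsFactors = FALSE)
}

#' Primer-dimer minimum free energy per pair
#'
#' Symmetric in argument order: the two sequences are canonically ordered
#' before the bimolecular fold is computed.
#'
#' @param fwd,rev character vectors of equal length (N-free primers).
#' @param backend a `StructureBackend`.
#' @return data.frame with `mfe` and `structure` per pair, as in
#'   [hairpin_mfe()].
#' @export
dimer_mfe <- function(fwd, rev, backend = structure_backend_vienna()) {
  stopifnot(length(fwd) == length(rev))
  if (!length(fwd))
    return(data.frame(mfe = numeric(0), structure = character(0)))
  assert_dna(c(fwd, rev), "primer")
  a <- pmin(fwd, rev); b <- pmax(fwd, rev)  # canonical order => symmetry
  if (backend$type == "vienna")
    return(run_vienna("RNAcofold", paste0(a, "&", b), backend))
  mfe <- vapply(seq_along(a), function(i) {
    tab <- backend$mfe_table
    key <- paste0(a[i], "&", b[i])
    if (!is.null(tab) && key %in% names(tab)) return(tab[[key]])
    run <- longest_comp_run(a[i], b[i])
    if (run >= 4L) -1.5 * (run - 3L) else 0
  }, numeric(1))
  data.frame(mfe = pmin(mfe, 0),
             structure = ifelse(mfe < 0, "<stub>", ""),
             stringsAsFactors = FALSE)
}

#' Score a candidate table with hairpin and dimer MFEs
#'
#' Adds `hairpin_fwd_mfe`, `hairpin_rev_mfe` and `dimer_mfe` columns.
#' Hairpins are computed once per distinct primer sequence; dimers once per
#' distinct pair.
#'
#' @param pairs candidate table from [generate_candidates()].
#' @param backend a `StructureBackend`.
#' @return the table with score columns appended.
#' @export
score_structures <- function(pairs, backend = structure_backend_vienna()) {
  if (!nrow(pairs)) {
    pairs$hairpin_fwd_mfe <- numeric(0)
    pairs$hairpin_rev_mfe <- numeric(0)
    pairs$dimer_mfe <- numeric(0)
    return(pairs)
  }
  uniq <- unique(c(pairs$fwd_seq, pairs$rev_seq))
  hp <- hairpin_mfe(uniq, backend)
  hmap <- setNames(hp$mfe, uniq)
  pairs$hairpin_fwd_mfe <- unname(hmap[pairs$fwd_seq])
  pairs$hairpin_rev_mfe <- unname(hmap[pairs$rev_seq])
  key <- paste0(pmin(pairs$fwd_seq, pairs$rev_seq), "&",
                pmax(pairs$fwd_seq, pairs$rev_seq))
  uk <- !duplicated(key)
  dm <- dimer_mfe(pairs$fwd_seq[uk], pairs$rev_seq[uk], backend)
  dmap <- setNames(dm$mfe, key[uk])
  pairs$dimer_mfe <- unname(dmap[key])
  pairs
}
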