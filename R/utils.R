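#' @importFrom methods is
#' @importFrom stats setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA character vectors
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x), function(s)
    intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# GC fraction of each sequence; N counts neither way (denominator is full length)
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- vapply(gregexpr("[GC]", x), function(m) sum(m > 0L), integer(1))
  ifelse(n == 0L, NA_real_, gc / n)
}

has_n <- function(x) grepl("N", x, fixed = TRUE)

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: %s",
                 what, if (allow_n) ",N" else "",
                 substr(x[bad][1], 1, 40)), call. = FALSE)
  }
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable, locale-independent string sort
sort_c <- function(x) sort(x, method = "radix")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
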