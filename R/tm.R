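# Nearest-neighbour duplex parameters (SantaLucia unified set):
# dH in kcal/mol, dS in cal/(mol K), keyed by the top-strand dinucleotide.
.nn_dinucs <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
                "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
.nn_dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
            CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
            GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
            TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
.nn_ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
            CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
            GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
            TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
# duplex initiation per terminal base
.init_dh <- c(A = 2.3, C = 0.1, G = 0.1, T = 2.3)
.init_ds <- c(A = 4.1, C = -2.8, G = -2.8, T = 4.1)
.gas_const <- 1.987  # cal/(mol K)

# Owczarzy monovalent-salt correction applied to the reciprocal melting
# temperature: 1/Tm(mon) = 1/Tm(1M) + (4.29 fGC - 3.95)e-5 ln[mon]
#                          + 9.40e-6 ln^2[mon], temperatures in kelvin.
owczarzy_correct <- function(tm_celsius, fgc, monovalent_mM) {
  mon <- monovalent_mM / 1000
  recip <- 1 / (tm_celsius + 273.15) +
    (4.29 * fgc - 3.95) * 1e-5 * log(mon) + 9.40e-6 * log(mon)^2
  1 / recip - 273.15
}

#' Primer melting temperature
#'
#' Nearest-neighbour duplex melting temperature (SantaLucia unified
#' parameters, 25 nM primer against 25 nM template) with the Owczarzy
#' monovalent-salt correction applied at the configured salt concentration.
#'
#' @param seq character vector of primer sequences over `{A,C,G,T}`,
#'   each at least 8 nt.
#' @param cfg a [generation_config()]; `cfg$monovalent_salt` (mM) is used.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temperature <- function(seq, cfg = generation_config()) {
  if (!length(seq)) return(numeric(0))
  assert_dna(seq, "primer")
  if (any(nchar(seq) < 8L))
    stop("primer shorter than 8 nt", call. = FALSE)
  vapply(seq, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    di <- paste0(b[-length(b)], b[-1])
    dh <- sum(.nn_dh[di]) + .init_dh[[b[1]]] + .init_dh[[b[length(b)]]]
    ds <- sum(.nn_ds[di]) + .init_ds[[b[1]]] + .init_ds[[b[length(b)]]]
    k <- 12.5e-9  # effective strand concentration, mol/L
    tm1m <- dh * 1000 / (ds + .gas_const * log(k)) - 273.15
    owczarzy_correct(tm1m, mean(b %in% c("G", "C")), cfg$monovalent_salt)
  }, numeric(1), USE.NAMES = FALSE)
}

# Melting temperatures of every window of width w over a target sequence,
# computed with cumulative sums so that candidate enumeration stays O(n).
# Returns a data.frame with start (1-based), tm, gc, has_n.
tm_windows <- function(target, width, monovalent_mM) {
  b <- strsplit(target, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < width)
    return(data.frame(start = integer(0), tm = numeric(0), gc = numeric(0),
                      has_n = logical(0)))
  code <- match(b, c("A", "C", "G", "T"))  # NA for N
  di <- paste0(b[-n], b[-1])
  dh_i <- unname(.nn_dh[di]); ds_i <- unname(.nn_ds[di])
  dh_i[is.na(dh_i)] <- 0; ds_i[is.na(ds_i)] <- 0
  cs_dh <- c(0, cumsum(dh_i)); cs_ds <- c(0, cumsum(ds_i))
  is_gc <- as.numeric(code %in% c(2L, 3L))
  cs_gc <- c(0, cumsum(is_gc))
  is_n <- as.numeric(is.na(code))
  cs_n <- c(0, cumsum(is_n))

  starts <- seq_len(n - width + 1L)
  ends <- starts + width - 1L
  dh <- cs_dh[ends] - cs_dh[starts] +
    .init_dh[b[starts]] + .init_dh[b[ends]]
  ds <- cs_ds[ends] - cs_ds[starts] +
    .init_ds[b[starts]] + .init_ds[b[ends]]
  gc <- (cs_gc[ends + 1L] - cs_gc[starts]) / width
  has_n <- (cs_n[ends + 1L] - cs_n[starts]) > 0
  tm1m <- dh * 1000 / (ds + .gas_const * log(12.5e-9)) - 273.15
  tm <- owczarzy_correct(tm1m, gc, monovalent_mM)
  tm[has_n] <- NA_real_
  data.frame(start = starts, tm = unname(tm), gc = unname(gc),
             has_n = unname(has_n))
}
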