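# Oligo melting temperature by nearest-neighbor thermodynamics
# (unified duplex parameter set of SantaLucia 1998), with entropic salt
# correction and a fixed primer concentration, as PCR primer software
# computes it.

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation at a terminal G.C / A.T pair
INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Primer melting temperature (nearest-neighbor)
#'
#' Tm of a DNA oligo against its perfect complement, from nearest-neighbor
#' enthalpies and entropies with duplex-initiation terms, an entropic salt
#' correction of `0.368 (L-1) ln[Na+]`, and
#' `Tm = dH / (dS + R ln(C/4)) - 273.15`.
#'
#' @param seqs Character vector of primer sequences (A/C/G/T only).
#' @param monovalent_mM Monovalent cation concentration (default 50 mM).
#' @param primer_nM Primer concentration (default 50 nM).
#' @return Tm in degrees Celsius; `NA` for sequences with non-ACGT bases
#'   or fewer than 2 bases.
#' @export
#' @examples
#' primer_tm("AGCGTACGTTAGCCTAGGCA")
primer_tm <- function(seqs, monovalent_mM = 50, primer_nM = 50) {
  seqs <- toupper(seqs)
  n <- length(seqs)
  lens <- nchar(seqs)
  ok <- lens >= 2 & !stringr::str_detect(seqs, "[^ACGT]")
  dh <- numeric(n)
  ds <- numeric(n)
  maxl <- max(lens, 0)
  if (maxl >= 2) {
    for (j in seq_len(maxl - 1)) {
      live <- ok & j <= lens - 1
      if (!any(live)) next
      d <- substr(seqs[live], j, j + 1)
      dh[live] <- dh[live] + NN_DH[d]
      ds[live] <- ds[live] + NN_DS[d]
    }
  }
  first <- substr(seqs, 1, 1)
  last <- substr(seqs, lens, lens)
  dh <- dh + INIT_DH[first] + INIT_DH[last]
  ds <- ds + INIT_DS[first] + INIT_DS[last]
  ds_salt <- ds + 0.368 * (lens - 1) * log(monovalent_mM / 1000)
  r_gas <- 1.987  # cal / (mol K)
  tm <- dh * 1000 / (ds_salt + r_gas * log(primer_nM * 1e-9 / 4)) - 273.15
  tm[!ok] <- NA_real_
  unname(tm)
}

primer_gc_percent <- function(seqs) {
  100 * stringr::str_count(toupper(seqs), "[GC]") / nchar(seqs)
}

has_long_homopolymer <- function(seqs, max_poly_x) {
  pat <- paste0("A{", max_poly_x + 1, ",}|C{", max_poly_x + 1,
                ",}|G{", max_poly_x + 1, ",}|T{", max_poly_x + 1, ",}")
  stringr::str_detect(toupper(seqs), pat)
}
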