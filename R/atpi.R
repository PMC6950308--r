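#' Reference sequences of the A. tenebrosa Kunitz inhibitors
#'
#' Full-length chains of the two Kunitz-type inhibitors characterized from
#' \emph{Actinia tenebrosa}: the 60-residue ATPI-I chain and the 58-residue
#' ATPI-II chain recovered from overlapping tryptic peptides (its first two
#' residues were not resolved by MS, so numbering of the published peptides
#' starts at position 3).
#'
#' @return Named character vector with elements \code{ATPI_I} and
#'   \code{ATPI_II}.
#' @examples
#' nchar(atpiSequences())
#' @export
atpiSequences <- function() {
    c(ATPI_I = paste0("DANSFCQLPAVVGK", "CRGYFPRYYYNTEAGK",
                      "CQQFIYGGCGGNR", "NNFETVEDCRATCHSHA"),
      ATPI_II = paste0("NSFCNLPAVVGR", "CKGYFPR", "YFYNTEAGKCQR",
                       "FIYGGCGGNRNNFETVDDCRATCHPRE"))
}

#' Published tryptic-peptide table for ATPI-I and ATPI-II
#'
#' The observed tryptic peptides of both inhibitors with their published
#' precursor charges and observed/calculated m/z values (all cysteines
#' carbamidomethylated). Positions are 1-based inclusive on the respective
#' chain; ATPI-II positions follow the published numbering, which starts the
#' resolved chain at position 3. One ATPI-II row was published with a
#' subscript range inconsistent with its residue count; positions here come
#' from residue counting.
#'
#' The row \code{CRGYFPRYYYNTEAGK 509.97 (+4)} is about 2 m/z units below
#' the value obtained by the standard carbamidomethyl monoisotopic
#' computation that reproduces every other row; it is flagged by
#' \code{reproducible = FALSE} and excluded from mass-verification checks.
#'
#' @return data.frame with columns \code{inhibitor, sequence, start, end,
#'   charge, observedMz, calculatedMz, reproducible}.
#' @examples
#' subset(atpiPeptideTable(), inhibitor == "ATPI_I")
#' @export
atpiPeptideTable <- function() {
    out <- read.table(text = "
inhibitor sequence start end charge observedMz calculatedMz reproducible
ATPI_I DANSFCQLPAVVGK 1 14 2 753.47 753.37 TRUE
ATPI_I CRGYFPRYYYNTEAGK 15 30 4 510.32 509.97 FALSE
ATPI_I YYYNTEAGK 22 30 2 554.97 554.75 TRUE
ATPI_I CQQFIYGGCGGNR 31 43 2 758.89 758.82 TRUE
ATPI_I CQQFIYGGCGGNRNNFETVEDCR 31 53 3 928.00 927.72 TRUE
ATPI_I NNFETVEDCR 44 53 2 642.39 642.27 TRUE
ATPI_I NNFETVEDCRATCHSHA 44 60 4 513.00 512.71 TRUE
ATPI_II NSFCNLPAVVGRCKGYFPR 3 21 4 561.60 561.28 TRUE
ATPI_II NSFCNLPAVVGR 3 14 2 667.53 667.34 TRUE
ATPI_II CKGYFPR 15 21 2 464.63 464.23 TRUE
ATPI_II YFYNTEAGKCQR 22 33 3 513.23 512.90 TRUE
ATPI_II FIYGGCGGNRNNFETVDDCRATCHPRE 34 60 5 641.54 641.28 TRUE
", header = TRUE, stringsAsFactors = FALSE)
    out
}

#' Published average masses of the intact inhibitors
#'
#' Calculated average masses of the full-length reduced chains (unmodified
#' cysteines): 6719.43 Da for ATPI-I and 6604.39 Da for the resolved
#' ATPI-II chain.
#'
#' @return Named numeric vector.
#' @export
atpiChainMasses <- function() {
    c(ATPI_I = 6719.43, ATPI_II = 6604.39)
}
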