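#' The standard genetic code and its degeneracy structure
#'
#' Builds the standard (NCBI transl_table=1) genetic code as the set of
#' lookup tables used by every codon-level statistic in the package: the
#' codon-to-amino-acid map, the synonymous family of each amino acid, family
#' degeneracies, and the 59-codon set eligible for RSCU analysis (the 61
#' sense codons minus ATG and TGG, whose amino acids admit no synonymous
#' choice).
#'
#' @return A list with components:
#'   \item{codon_to_aa}{named character vector over all 64 codons; values are
#'     one-letter amino-acid codes, `"*"` for stop.}
#'   \item{sense_codons}{the 61 non-stop codons.}
#'   \item{stop_codons}{TAA, TAG, TGA.}
#'   \item{rscu_codons}{the 59 codons with a synonymous alternative.}
#'   \item{families}{list mapping each amino acid to its synonymous codon set.}
#'   \item{degeneracy}{named integer vector: family size per amino acid
#'     (1, 2, 3, 4 or 6).}
#'   \item{amino_acids}{the 20 one-letter amino-acid codes.}
#'   \item{fourfold_aa}{Ala, Gly, Pro, Thr, Val -- the strictly fourfold
#'     degenerate amino acids used for PR2 analysis.}
#' @examples
#' code <- genetic_code()
#' length(code$rscu_codons)   # 59
#' code$degeneracy[c("L", "I", "M")]
#' @export
genetic_code <- function() {
  if (!is.null(.code_cache$code)) return(.code_cache$code)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  stops <- codons[gc == "*"]
  sense <- codons[gc != "*"]
  aas <- sort(unique(gc[gc != "*"]))
  families <- split(sense, gc[sense])
  degeneracy <- vapply(families, length, integer(1L))
  code <- list(
    codon_to_aa = gc,
    sense_codons = sense,
    stop_codons = stops,
    rscu_codons = setdiff(sense, c("ATG", "TGG")),
    families = families,
    degeneracy = degeneracy,
    amino_acids = aas,
    fourfold_aa = c("A", "G", "P", "T", "V")
  )
  # sanity of the standard-code structure this package depends on
  stopifnot(
    length(code$sense_codons) == 61L,
    setequal(code$stop_codons, c("TAA", "TAG", "TGA")),
    length(code$rscu_codons) == 59L,
    setequal(names(degeneracy)[degeneracy == 1L], c("M", "W")),
    sum(degeneracy == 2L) == 9L,
    identical(names(degeneracy)[degeneracy == 3L], "I"),
    sum(degeneracy == 4L) == 5L,
    setequal(names(degeneracy)[degeneracy == 6L], c("L", "S", "R"))
  )
  .code_cache$code <- code
  code
}

.code_cache <- new.env(parent = emptyenv())
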