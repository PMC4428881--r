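# Genetic-code helpers shared by all modules.  Codons are uppercase DNA
# triplets throughout; RNA (U) appears only inside folding-energy calls and in
# anticodon identifiers.

.codon_env <- new.env(parent = emptyenv())

#' The standard genetic code as a codon -> amino-acid map
#'
#' @return Named character vector of length 64 (single-letter amino acids,
#'   `"*"` for stop), names are DNA codons.
#' @keywords internal
genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

#' The 61 sense codons, lexicographically ordered
#' @keywords internal
sense_codons <- function() {
  if (is.null(.codon_env$sense)) {
    gc <- genetic_code()
    .codon_env$sense <- sort(names(gc)[gc != "*"])
  }
  .codon_env$sense
}

stop_codons <- function() c("TAA", "TAG", "TGA")

#' Split an in-frame DNA string into codons
#' @keywords internal
split_codons <- function(dna) {
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(dna, starts, starts + 2L)
}

#' Translate an in-frame DNA string with the standard genetic code
#'
#' @param dna DNA string, length a multiple of 3.
#' @return Amino-acid string (`*` for stop codons).
#' @export
#' @examples
#' translate_dna("ATGAAACCCCGCACGGTGCCG")  # "MKPRTVP"
translate_dna <- function(dna) {
  paste(genetic_code()[split_codons(toupper(dna))], collapse = "")
}

#' Synonymous codons of a codon (including the codon itself)
#' @keywords internal
synonymous_codons <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  if (is.null(aa) || aa == "*") stop("not a sense codon: ", codon)
  sort(names(gc)[gc == aa])
}

# Fastest/slowest synonymous codon under a rate table; ties broken
# lexicographically (synonymous_codons() returns sorted names, which.max/min
# take the first).
fastest_synonym <- function(codon, rates) {
  syn <- synonymous_codons(codon)
  syn[which.max(rates[syn])]
}

slowest_synonym <- function(codon, rates) {
  syn <- synonymous_codons(codon)
  syn[which.min(rates[syn])]
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

assert_dna_alphabet <- function(dna, what = "sequence") {
  if (grepl("[^ACGT]", dna)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", dna), "")[[1]])
    stop(what, " contains non-DNA characters: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
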