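# Codon kinetics: host tRNA abundances + a codon->anticodon decoding (wobble)
# map give a relative translation rate per sense codon.  The rate model is
# summed cognate-tRNA concentration, normalized over the 61 sense codons --
# the minimal model in which per-codon speed is driven by the concentration
# of the tRNAs able to decode the codon.

#' Read a tRNA abundance table
#'
#' Parses a tab-separated table with columns `anticodon<TAB>concentration`
#' (an optional third `note` column and `#` comment lines are allowed).
#' Anticodons are 5'->3' triplets; `T` is normalized to `U` so DNA-alphabet
#' input is accepted.
#'
#' @param path Path to the TSV file.
#' @param source_label Free-text label stored with the table; defaults to the
#'   file name.
#' @return A `trna_table`: named numeric vector of concentrations (names are
#'   RNA anticodons) with attributes `source_label` and `note`.
#' @export
#' @examples
#' trna <- ecoli_trna_table()
#' head(sort(trna))
load_trna_table <- function(path, source_label = basename(path)) {
  tab <- read_tsv_table(path, min_cols = 2L)
  anticodon <- dna_to_rna(toupper(tab[[1L]]))
  conc <- suppressWarnings(as.numeric(tab[[2L]]))
  note <- if (ncol(tab) >= 3L) as.character(tab[[3L]]) else rep("", nrow(tab))
  if (anyNA(conc)) stop("non-numeric concentration in ", path)
  trna_table(stats::setNames(conc, anticodon), source_label = source_label,
             note = note)
}

#' Construct and validate a tRNA abundance table
#'
#' @param concentrations Named numeric vector, names are anticodons (RNA,
#'   length 3), values are relative abundances (> 0, arbitrary units).
#' @param source_label Free-text provenance label.
#' @param note Optional per-entry annotation.
#' @return A `trna_table` object.
#' @export
trna_table <- function(concentrations, source_label = "user", note = NULL) {
  anticodon <- names(concentrations)
  if (is.null(anticodon) || any(!nzchar(anticodon)))
    stop("concentrations must be named by anticodon")
  if (any(nchar(anticodon) != 3L) || any(grepl("[^ACGU]", anticodon)))
    stop("anticodons must be RNA triplets over {A,C,G,U}")
  dup <- anticodon[duplicated(anticodon)]
  if (length(dup))
    stop("duplicate anticodon(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("all tRNA concentrations must be positive and finite")
  structure(as.numeric(concentrations),
            names = anticodon,
            source_label = source_label,
            note = note,
            class = "trna_table")
}

#' @export
print.trna_table <- function(x, ...) {
  cat("tRNA abundance table (", attr(x, "source_label"), "): ",
      length(x), " anticodons\n", sep = "")
  cat("  concentration range: ", format(min(x)), " - ", format(max(x)), "\n",
      sep = "")
  invisible(x)
}

#' Built-in E. coli tRNA abundance table
#'
#' Relative tRNA concentrations for *Escherichia coli* (molecules per cell at
#' a growth rate of 0.4 doublings/h, transcribed approximately from the
#' classic Northern-blot measurements).  The CUA-decoding Leu isoacceptor
#' (anticodon UAG) is the rarest leucine tRNA, which is what makes CTA the
#' pause codon of choice.
#'
#' @return A `trna_table`.
#' @export
ecoli_trna_table <- function() {
  load_trna_table(ribotune_extdata("ecoli_trna_dong1996.tsv"),
                  source_label = "E. coli (built-in)")
}

#' Read a codon -> anticodon decoding (wobble) map
#'
#' One `codon<TAB>anticodon` pair per line; a codon decoded by several
#' isoacceptors appears on several lines.  Codons are DNA, anticodons RNA
#' (T/U normalized on both sides as needed).
#'
#' @param path Path to the TSV file.
#' @return A `wobble_map`: named list mapping each sense codon to a character
#'   vector of anticodons.
#' @export
load_wobble_map <- function(path) {
  tab <- read_tsv_table(path, min_cols = 2L)
  codon <- rna_to_dna(toupper(tab[[1L]]))
  anticodon <- dna_to_rna(toupper(tab[[2L]]))
  wobble_map(split(anticodon, factor(codon, levels = unique(codon))))
}

#' Construct and validate a wobble map
#'
#' @param pairs Named list: sense codon -> character vector of anticodons.
#' @return A `wobble_map` object.
#' @export
wobble_map <- function(pairs) {
  codons <- names(pairs)
  if (any(codons %in% stop_codons()))
    stop("stop codons cannot appear in a wobble map: ",
         paste(intersect(codons, stop_codons()), collapse = ", "))
  unknown <- setdiff(codons, sense_codons())
  if (length(unknown))
    stop("not sense codons: ", paste(unknown, collapse = ", "))
  if (any(lengths(pairs) == 0L))
    stop("every codon must map to at least one anticodon")
  pairs <- lapply(pairs, function(a) sort(unique(as.character(a))))
  structure(pairs, class = "wobble_map")
}

#' @export
print.wobble_map <- function(x, ...) {
  cat("wobble map: ", length(x), " codons, ",
      length(unique(unlist(x))), " anticodons\n", sep = "")
  invisible(x)
}

#' Built-in E. coli wobble map
#'
#' Curated decoding table for the E. coli isoacceptor set: Watson-Crick
#' pairing plus the standard wobble-position rules (cmo5U34 reading A/G/U,
#' mnm5(s2)U34 reading A/G, inosine 34 reading U/C/A, G34 reading C/U).
#' All 61 sense codons are covered.  Shipped as editable package data.
#'
#' @return A `wobble_map`.
#' @export
ecoli_wobble_map <- function() {
  load_wobble_map(ribotune_extdata("ecoli_wobble.tsv"))
}

#' Per-codon relative translation rates from tRNA abundances
#'
#' The rate of a sense codon is the summed concentration of all tRNAs able to
#' decode it (per the wobble map), normalized either by the maximum over the
#' 61 sense codons (default; fastest codon gets rate 1) or by the sum.
#' Rates are scale-invariant in the tRNA concentrations.
#'
#' @param trna A [trna_table()].
#' @param wobble A [wobble_map()]; must cover all 61 sense codons with
#'   anticodons present in `trna`.
#' @param normalization_mode `"max"` (default) or `"sum"`.
#' @return A `codon_rate_table`: named numeric vector of 61 rates in (0, 1]
#'   with attribute `normalization_mode`.
#' @export
#' @examples
#' rates <- codon_rates(ecoli_trna_table(), ecoli_wobble_map())
#' rates["CTA"] < rates["CTG"]  # CTA is the slow Leu codon
codon_rates <- function(trna, wobble, normalization_mode = c("max", "sum")) {
  normalization_mode <- match.arg(normalization_mode)
  missing_codons <- setdiff(sense_codons(), names(wobble))
  if (length(missing_codons))
    stop("wobble map has no decoding anticodon for codon(s): ",
         paste(missing_codons, collapse = ", "))
  raw <- vapply(sense_codons(), function(codon) {
    ac <- wobble[[codon]]
    absent <- setdiff(ac, names(trna))
    if (length(absent) == length(ac))
      stop("no decoding anticodon present in the tRNA table for codon ", codon)
    sum(unclass(trna)[intersect(ac, names(trna))])
  }, numeric(1))
  denom <- switch(normalization_mode, max = max(raw), sum = sum(raw))
  structure(raw / denom,
            normalization_mode = normalization_mode,
            class = "codon_rate_table")
}

#' @export
print.codon_rate_table <- function(x, ...) {
  cat("codon rate table (normalization: ", attr(x, "normalization_mode"),
      ")\n", sep = "")
  v <- unclass(x)
  cat("  fastest: ", names(v)[which.max(v)], " (", format(max(v)), ")",
      "   slowest: ", names(v)[which.min(v)], " (", format(min(v)), ")\n",
      sep = "")
  invisible(x)
}

#' Read a codon usage table
#'
#' TSV with columns `codon<TAB>frequency` (per-mille or fraction; any
#' non-negative unit).  All 61 sense codons must be present.
#'
#' @param path Path to the TSV file.
#' @param species_label Free-text label; defaults to the file name.
#' @return A `codon_usage_table`: named numeric vector of 61 frequencies.
#' @export
load_codon_usage <- function(path, species_label = basename(path)) {
  tab <- read_tsv_table(path, min_cols = 2L)
  codon <- rna_to_dna(toupper(tab[[1L]]))
  freq <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(freq)) stop("non-numeric frequency in ", path)
  codon_usage_table(stats::setNames(freq, codon), species_label = species_label)
}

#' Construct and validate a codon usage table
#' @param freqs Named numeric vector: sense codon -> frequency (>= 0).
#' @param species_label Free-text label.
#' @return A `codon_usage_table` object.
#' @export
codon_usage_table <- function(freqs, species_label = "user") {
  missing_codons <- setdiff(sense_codons(), names(freqs))
  if (length(missing_codons))
    stop("usage table missing codon(s): ",
         paste(missing_codons, collapse = ", "))
  extra <- setdiff(names(freqs), sense_codons())
  if (length(extra))
    stop("usage table has non-sense-codon entries: ",
         paste(extra, collapse = ", "))
  if (any(!is.finite(freqs)) || any(freqs < 0))
    stop("all usage frequencies must be non-negative and finite")
  structure(as.numeric(freqs)[match(sense_codons(), names(freqs))],
            names = sense_codons(),
            species_label = species_label,
            class = "codon_usage_table")
}

#' Built-in approximate E. coli K-12 codon usage table
#' @return A `codon_usage_table` (per-mille units).
#' @export
ecoli_codon_usage <- function() {
  load_codon_usage(ribotune_extdata("ecoli_codon_usage.tsv"),
                   species_label = "E. coli K-12 (built-in, approximate)")
}

#' The k least-used codons of a species
#'
#' Rare codons are defined as the `k` least used codons of the species
#' (default 10), the codon-usage fallback for hosts whose tRNA concentrations
#' are unknown.  Frequency ties are broken lexicographically.
#'
#' @param usage A [codon_usage_table()].
#' @param k Number of codons to return (1..61).
#' @return Character vector of `k` codons, ordered by increasing frequency.
#' @export
rare_codons <- function(usage, k = 10) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k != round(k))
    stop("k must be a positive integer")
  if (k > 61L) stop("k must be <= 61")
  v <- stats::setNames(as.numeric(usage), names(usage))
  ord <- order(v, names(v))  # lexicographic tie-break
  names(v)[ord][seq_len(k)]
}

ribotune_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ribotune")
  if (!nzchar(path)) stop("built-in data file not found: ", file)
  path
}

# Shared TSV reader: tab-separated, '#' comments, no header.
read_tsv_table <- function(path, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty table: ", path)
  if (ncol(tab) < min_cols)
    stop(path, " must have at least ", min_cols, " tab-separated columns")
  tab
}
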