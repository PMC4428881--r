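# File I/O: FASTA in/out (via Biostrings), domain-boundary annotations,
# profile/site/plan exports and the JSON design report.

#' Read ORFs from a DNA FASTA file
#'
#' Each record is validated as an in-frame ORF (see [orf()]).  Ambiguity
#' characters such as `N` are rejected with the offending record named.
#'
#' @param path FASTA file.
#' @return List of [orf()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  mapply(function(id, s) orf(id, s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write ORFs (or named sequences) to a FASTA file
#'
#' @param orfs List of [orf()] objects, or a named character vector of DNA
#'   sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(orfs, path) {
  if (is.character(orfs)) {
    seqs <- orfs
  } else {
    seqs <- stats::setNames(vapply(orfs, function(o) o$dna, character(1)),
                            vapply(orfs, function(o) o$id, character(1)))
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read domain-boundary annotations
#'
#' TSV with columns `seq_id<TAB>domain_start_aa<TAB>domain_end_aa` (1-based,
#' inclusive); `#` comments allowed.
#'
#' @param path TSV file.
#' @return Data frame with columns `seq_id`, `start_aa`, `end_aa`.
#' @export
read_domains <- function(path) {
  tab <- read_tsv_table(path, min_cols = 3L)
  out <- suppressWarnings(
    data.frame(seq_id = tab[[1L]],
               start_aa = as.integer(tab[[2L]]),
               end_aa = as.integer(tab[[3L]])))
  if (anyNA(out$start_aa) || anyNA(out$end_aa))
    stop("non-integer domain coordinates in ", path)
  out
}

#' Export a translation profile as TSV
#' @param profile A [raw_profile()] (smoothed or not).
#' @param path Output path, or `""` for stdout.
#' @export
write_profile_tsv <- function(profile, path = "") {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export attenuation sites as TSV
#' @param sites A [detect_minima()] (optionally [site_domain_offsets()])
#'   result.
#' @param path Output path, or `""` for stdout.
#' @export
write_sites_tsv <- function(sites, path = "") {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a substitution plan as TSV
#' @param plan A [substitution_plan()].
#' @param path Output path, or `""` for stdout.
#' @export
write_plan_tsv <- function(plan, path = "") {
  utils::write.table(plan$edits, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle a per-ORF design run into a serializable report
#'
#' @param orf The source [orf()].
#' @param profile Smoothed [raw_profile()].
#' @param threshold [genome_threshold()] used for site calls.
#' @param sites [detect_minima()] / [site_domain_offsets()] result.
#' @param plans List of [substitution_plan()]s.
#' @param dg_before,dg_after Optional [dg_profile()]s.
#' @return A `design_report` list ready for [write_report_json()].
#' @export
design_report <- function(orf, profile, threshold, sites, plans = list(),
                          dg_before = NULL, dg_after = NULL) {
  for (p in plans)
    if (!isTRUE(verify_synonymy(list(dna = p$source_dna), p)))
      stop("plan for '", p$orf_id, "' is not synonymous")
  rep <- list(
    orf_id = orf$id,
    n_codons = n_codons(orf),
    profile_summary = list(
      window = profile$window,
      raw_mean = mean(profile$raw),
      smoothed_min = min(profile$smoothed, na.rm = TRUE),
      smoothed_max = max(profile$smoothed, na.rm = TRUE)),
    threshold = unclass(threshold),
    sites = as.data.frame(sites),
    plans = lapply(plans, function(p)
      list(orf_id = p$orf_id, edits = p$edits, result_dna = p$result_dna)),
    dg_before = if (!is.null(dg_before)) as.data.frame(dg_before),
    dg_after = if (!is.null(dg_after)) as.data.frame(dg_after))
  structure(rep, class = "design_report")
}

#' Write a design report as JSON
#' @param report A [design_report()].
#' @param path Output path.
#' @param timestamp Include a timestamp field (default `FALSE`, so identical
#'   inputs give identical bytes).
#' @export
write_report_json <- function(report, path, timestamp = FALSE) {
  out <- unclass(report)
  if (timestamp) out$generated_at <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a design report
#' @param path JSON file written by [write_report_json()].
#' @return The report as a list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
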