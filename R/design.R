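# Synonymous redesign: insert ribosome-pausing codons downstream of domain
# boundaries (slow-down mode), or erase detected pauses by swapping to the
# fastest synonyms (speed-up mode).  Every plan preserves the encoded
# protein; local folding-energy changes are annotated and guarded.

#' Design parameters for pause insertion/removal
#'
#' @param offset_range_aa Window downstream of a domain boundary, in amino
#'   acids, in which a pause may be placed (default 20-70 aa — the span of
#'   nascent chain that can be buried in the ribosome exit tunnel).
#' @param preferred_offset_aa Preferred pause position downstream of the
#'   boundary (default 30 aa, the typical tunnel-protected stretch).
#' @param preferred_slow_codon The pause codon of choice (default `"CTA"`,
#'   read by the rarest Leu isoacceptor in E. coli).
#' @param max_codons_per_site Cap on edits per site when no Leu is available
#'   and the greedy slowest-synonym fallback runs (default 3).
#' @param ddg_guard_kcal Warn when an edit shifts the local 39-nt folding
#'   energy by more than this many kcal/mol (default 2.0).
#' @param fast_mode_scope Whether speed-up edits touch only detected sites
#'   (`"site"`, default) or every below-threshold codon in the ORF
#'   (`"whole_orf"`).
#' @return A `design_config` list.
#' @export
design_config <- function(offset_range_aa = c(20L, 70L),
                          preferred_offset_aa = 30L,
                          preferred_slow_codon = "CTA",
                          max_codons_per_site = 3L,
                          ddg_guard_kcal = 2.0,
                          fast_mode_scope = c("site", "whole_orf")) {
  fast_mode_scope <- match.arg(fast_mode_scope)
  if (length(offset_range_aa) != 2L || offset_range_aa[1] > offset_range_aa[2])
    stop("offset_range_aa must be c(low, high) with low <= high")
  if (preferred_offset_aa < offset_range_aa[1] ||
      preferred_offset_aa > offset_range_aa[2])
    stop("preferred_offset_aa must lie within offset_range_aa")
  if (ddg_guard_kcal < 0) stop("ddg_guard_kcal must be >= 0")
  if (!preferred_slow_codon %in% sense_codons())
    stop("preferred_slow_codon must be a sense codon")
  if (max_codons_per_site < 1L) stop("max_codons_per_site must be >= 1")
  structure(list(offset_range_aa = as.integer(offset_range_aa),
                 preferred_offset_aa = as.integer(preferred_offset_aa),
                 preferred_slow_codon = preferred_slow_codon,
                 max_codons_per_site = as.integer(max_codons_per_site),
                 ddg_guard_kcal = ddg_guard_kcal,
                 fast_mode_scope = fast_mode_scope),
            class = "design_config")
}

empty_edits <- function() {
  data.frame(codon_pos = integer(0), old_codon = character(0),
             new_codon = character(0), reason = character(0),
             local_ddG = numeric(0), ddg_warning = logical(0))
}

edit_row <- function(pos, old, new, reason) {
  data.frame(codon_pos = as.integer(pos), old_codon = old, new_codon = new,
             reason = reason, local_ddG = NA_real_, ddg_warning = FALSE)
}

apply_edits <- function(dna, edits) {
  for (i in seq_len(nrow(edits))) {
    pos <- edits$codon_pos[i]
    nt <- (pos - 1L) * 3L + 1L
    if (substr(dna, nt, nt + 2L) != edits$old_codon[i])
      stop("edit at codon ", pos, " expects ", edits$old_codon[i],
           " but sequence has ", substr(dna, nt, nt + 2L))
    substr(dna, nt, nt + 2L) <- edits$new_codon[i]
  }
  dna
}

#' Construct a substitution plan
#'
#' Bundles an ordered set of codon-level synonymous edits with the redesigned
#' sequence.  Construction enforces the core guarantees: edits are at
#' distinct positions, each edit is synonymous, and the result translates to
#' the same protein as the source.
#'
#' @param orf Source [orf()].
#' @param edits Data frame with columns `codon_pos`, `old_codon`,
#'   `new_codon`, `reason` (and optionally `local_ddG`, `ddg_warning`).
#' @return A `substitution_plan`: list with `orf_id`, `edits`, `source_dna`,
#'   `result_dna`.
#' @export
substitution_plan <- function(orf, edits) {
  if (nrow(edits)) {
    if (anyDuplicated(edits$codon_pos))
      stop("edits must be at distinct codon positions")
    gc <- genetic_code()
    nonsyn <- gc[edits$old_codon] != gc[edits$new_codon]
    if (any(nonsyn))
      stop("non-synonymous edit at codon position ",
           edits$codon_pos[which(nonsyn)[1L]])
    edits <- edits[order(edits$codon_pos), , drop = FALSE]
    rownames(edits) <- NULL
  }
  if (!"local_ddG" %in% names(edits)) edits$local_ddG <- NA_real_
  if (!"ddg_warning" %in% names(edits)) edits$ddg_warning <- FALSE
  result <- apply_edits(orf$dna, edits)
  plan <- structure(list(orf_id = orf$id, edits = edits,
                         source_dna = orf$dna, result_dna = result),
                    class = "substitution_plan")
  if (!isTRUE(verify_synonymy(orf, plan)))
    stop("internal error: plan changes the encoded protein")
  plan
}

#' @export
print.substitution_plan <- function(x, ...) {
  cat("substitution plan for '", x$orf_id, "': ", nrow(x$edits),
      " synonymous edit(s)\n", sep = "")
  if (nrow(x$edits)) print.data.frame(x$edits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.substitution_plan <- function(object, ...) {
  e <- object$edits
  cat("plan '", object$orf_id, "': ", nrow(e), " edit(s); reasons: ",
      if (nrow(e)) paste(names(table(e$reason)), table(e$reason),
                         sep = "=", collapse = ", ") else "none",
      "\n", sep = "")
  if (any(e$ddg_warning))
    cat("  ", sum(e$ddg_warning),
        " edit(s) exceed the local folding-energy guard\n", sep = "")
  invisible(object)
}

#' Check that a plan preserves the encoded protein
#'
#' @param source Source [orf()].
#' @param plan A [substitution_plan()] (or any list with `result_dna`).
#' @return `TRUE` iff the standard-genetic-code translations of source and
#'   result are identical.
#' @export
#' @examples
#' verify_synonymy(orf("m9", "ATGAAACCCCGCACGGTGCCG"),
#'                 list(result_dna = "ATGAAACCACGAACAGTACCA"))
verify_synonymy <- function(source, plan) {
  if (nchar(plan$result_dna) != nchar(source$dna))
    stop("result length (", nchar(plan$result_dna),
         ") differs from source length (", nchar(source$dna), ")")
  identical(translate_dna(source$dna), translate_dna(plan$result_dna))
}

# Annotate each edit with the local folding-energy change: dG of the
# window_nt window centered on the edited codon's middle nucleotide, after
# minus before (clipped at sequence ends; upstream context included when the
# ORF carries one).  Raises a warning per edit beyond the guard.
annotate_ddg <- function(orf, edits, engine, window_nt = 39L,
                         guard = 2.0) {
  if (is.null(engine) || nrow(edits) == 0L) return(edits)
  up <- if (is.null(orf$upstream)) "" else orf$upstream
  before <- paste0(up, orf$dna)
  after <- paste0(up, apply_edits(orf$dna, edits))
  half <- (window_nt - 1L) %/% 2L
  for (i in seq_len(nrow(edits))) {
    center <- nchar(up) + (edits$codon_pos[i] - 1L) * 3L + 2L
    lo <- max(1L, center - half)
    hi <- min(nchar(before), center + half)
    ddg <- engine(dna_to_rna(substr(after, lo, hi))) -
           engine(dna_to_rna(substr(before, lo, hi)))
    edits$local_ddG[i] <- ddg
    if (is.finite(ddg) && abs(ddg) > guard) {
      edits$ddg_warning[i] <- TRUE
      warning("edit at codon ", edits$codon_pos[i],
              " changes local folding energy by ", format(round(ddg, 2)),
              " kcal/mol (guard ", guard, ")")
    }
  }
  edits
}

#' Insert a translational pause downstream of a domain boundary
#'
#' Places a slow-translating site in the window
#' `domain_end + offset_range_aa` (default 20-70 aa downstream, so that the
#' folded domain plus the tunnel-buried stretch has fully emerged).  If the
#' window contains a codon for the preferred pause amino acid (Leu by
#' default) that is not already the preferred slow codon, a single edit to
#' that codon (default CTA) nearest the preferred offset is made — one codon
#' read by a very rare tRNA suffices for a transient pause.  If every such
#' codon is already slow, the plan is empty.  Windows without Leu fall back
#' to greedy slowest-synonym substitution of at most `max_codons_per_site`
#' codons, largest rate decrease first, stopping early once the window's
#' smoothed minimum drops below `threshold` (when one is supplied).
#'
#' @param orf An [orf()].
#' @param domain_end_aa Domain boundary (1-based amino-acid position).
#' @param rates A [codon_rates()] table.
#' @param cfg A [design_config()].
#' @param threshold Optional [genome_threshold()] or numeric: stop the greedy
#'   fallback once the site is this slow.
#' @param window Smoothing window in codons used to assess the site.
#' @param engine Optional [folding engine][rnafold_engine()] for per-edit
#'   local folding-energy annotation.
#' @return A [substitution_plan()] with reason `"insert_pause"`.
#' @export
insert_pause <- function(orf, domain_end_aa, rates, cfg = design_config(),
                         threshold = NULL, window = 19L, engine = NULL) {
  L <- n_codons(orf)
  win_lo <- domain_end_aa + cfg$offset_range_aa[1L]
  win_hi <- domain_end_aa + cfg$offset_range_aa[2L]
  if (win_lo < 1L || win_hi > L)
    stop("target window [", win_lo, ", ", win_hi,
         "] lies outside the ORF (", L, " codons)")
  codons <- orf_codons(orf)
  win <- win_lo:win_hi
  gc <- genetic_code()
  pause_aa <- gc[[cfg$preferred_slow_codon]]
  is_pause_aa <- gc[codons[win]] == pause_aa

  if (any(is_pause_aa)) {
    editable <- win[is_pause_aa & codons[win] != cfg$preferred_slow_codon]
    if (!length(editable))
      return(substitution_plan(orf, empty_edits()))  # already slow
    target_pos <- domain_end_aa + cfg$preferred_offset_aa
    dist <- abs(editable - target_pos)
    pick <- editable[order(dist, editable)][1L]  # ties: smaller position
    edits <- edit_row(pick, codons[pick], cfg$preferred_slow_codon,
                      "insert_pause")
  } else {
    candidates <- win[vapply(codons[win],
                             function(cc) length(synonymous_codons(cc)) > 1L,
                             logical(1))]
    if (!length(candidates))
      stop("no synonymous slow-down possible: window contains only ",
           "single-codon amino acids")
    cutoff <- if (is.null(threshold)) -Inf else threshold_value(threshold)
    work <- codons
    edits <- empty_edits()
    for (k in seq_len(cfg$max_codons_per_site)) {
      open_pos <- setdiff(candidates, edits$codon_pos)
      if (!length(open_pos)) break
      slow <- vapply(work[open_pos],
                     function(cc) slowest_synonym(cc, rates), character(1))
      decrease <- unclass(rates)[work[open_pos]] - unclass(rates)[slow]
      if (max(decrease) <= 0) break
      best <- which(decrease == max(decrease))[1L]  # ties: smaller position
      pos <- open_pos[best]
      edits <- rbind(edits, edit_row(pos, work[pos], slow[best],
                                     "insert_pause"))
      work[pos] <- slow[best]
      prof <- structure(list(orf_id = orf$id, codons = work,
                             raw = as.numeric(unclass(rates)[work]),
                             smoothed = NA_real_, window = NA_integer_),
                        class = "translation_profile")
      prof <- smooth_profile(prof, window = min(window, L - (1 - L %% 2)))
      site_min <- min(prof$smoothed[win], na.rm = TRUE)
      if (site_min < cutoff) break
    }
  }
  edits <- annotate_ddg(orf, edits, engine, guard = cfg$ddg_guard_kcal)
  substitution_plan(orf, edits)
}

#' Erase a translational pause
#'
#' Replaces every codon inside the site whose rate is below the site-call
#' threshold with its fastest synonymous codon (ties broken
#' lexicographically), producing a locally fast, smooth profile.
#'
#' @param orf An [orf()].
#' @param site One row of a [detect_minima()] result (or any list with
#'   `start_codon` and `end_codon`).
#' @param rates A [codon_rates()] table.
#' @param threshold The threshold the site was called at
#'   ([genome_threshold()] or numeric).
#' @param cfg A [design_config()].
#' @param engine Optional folding engine for local ddG annotation.
#' @return A [substitution_plan()] with reason `"remove_pause"`.
#' @export
remove_pause <- function(orf, site, rates, threshold, cfg = design_config(),
                         engine = NULL) {
  L <- n_codons(orf)
  span <- site$start_codon[1L]:site$end_codon[1L]
  if (min(span) < 1L || max(span) > L)
    stop("site [", min(span), ", ", max(span), "] lies outside the ORF")
  cutoff <- threshold_value(threshold)
  codons <- orf_codons(orf)
  edits <- empty_edits()
  for (pos in span) {
    if (unclass(rates)[[codons[pos]]] < cutoff) {
      fast <- fastest_synonym(codons[pos], rates)
      if (fast != codons[pos])
        edits <- rbind(edits, edit_row(pos, codons[pos], fast, "remove_pause"))
    }
  }
  edits <- annotate_ddg(orf, edits, engine, guard = cfg$ddg_guard_kcal)
  substitution_plan(orf, edits)
}

#' Erase every detected pause in an ORF
#'
#' Runs [detect_minima()] and applies [remove_pause()] to every site,
#' returning one merged plan — the "uniformly fast" redesign.
#'
#' @inheritParams remove_pause
#' @param window Smoothing window in codons.
#' @param min_gap Site-merging gap passed to [detect_minima()].
#' @return A [substitution_plan()].
#' @export
remove_all_pauses <- function(orf, threshold, rates, cfg = design_config(),
                              window = 19L, min_gap = 5L, engine = NULL) {
  prof <- smooth_profile(raw_profile(orf, rates), window = window)
  sites <- detect_minima(prof, threshold, min_gap = min_gap)
  edits <- empty_edits()
  for (i in seq_len(nrow(sites)))
    edits <- rbind(edits,
                   remove_pause(orf, sites[i, ], rates, threshold, cfg)$edits)
  edits <- edits[!duplicated(edits$codon_pos), , drop = FALSE]
  edits$local_ddG <- rep(NA_real_, nrow(edits))
  edits$ddg_warning <- rep(FALSE, nrow(edits))
  edits <- annotate_ddg(orf, edits, engine, guard = cfg$ddg_guard_kcal)
  substitution_plan(orf, edits)
}
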