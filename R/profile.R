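# Translation profiles: per-codon raw rates along an ORF, a centered sliding
# mean (default window 19 codons), a genome-wide slow-translation threshold,
# and detection of attenuation sites (below-threshold minima).

#' Construct an open reading frame
#'
#' Validates an in-frame protein-coding DNA sequence.  A single trailing stop
#' codon is accepted and stripped (profiles are defined over sense codons);
#' internal stop codons are an error.  An optional `upstream` sequence holds
#' 5' context (vector/UTR) used only by folding-energy windows.
#'
#' @param id Sequence identifier.
#' @param dna Coding sequence (DNA, length a multiple of 3, starting at the
#'   start codon).
#' @param upstream Optional DNA string immediately 5' of `dna`.
#' @return An `orf` object (list with `id`, `dna`, `upstream`).
#' @export
#' @examples
#' o <- orf("toy", "ATGCTGCTGCTA")
#' n_codons(o)
orf <- function(id, dna, upstream = NULL) {
  dna <- toupper(gsub("\\s", "", dna))
  assert_dna_alphabet(dna, paste0("ORF '", id, "'"))
  if (nchar(dna) %% 3L != 0L)
    stop("ORF '", id, "': length ", nchar(dna), " is not a multiple of 3")
  codons <- split_codons(dna)
  if (length(codons) && codons[length(codons)] %in% stop_codons()) {
    codons <- codons[-length(codons)]
    dna <- paste(codons, collapse = "")
  }
  internal_stop <- which(codons %in% stop_codons())
  if (length(internal_stop))
    stop("ORF '", id, "': internal stop codon at codon position ",
         internal_stop[1L])
  if (!length(codons)) stop("ORF '", id, "': empty sequence")
  if (!is.null(upstream)) {
    upstream <- toupper(gsub("\\s", "", upstream))
    assert_dna_alphabet(upstream, paste0("upstream context of '", id, "'"))
  }
  structure(list(id = id, dna = dna, upstream = upstream), class = "orf")
}

#' @export
print.orf <- function(x, ...) {
  cat("ORF '", x$id, "': ", n_codons(x), " codons",
      if (!is.null(x$upstream))
        paste0(" (+", nchar(x$upstream), " nt upstream context)"),
      "\n", sep = "")
  invisible(x)
}

#' Number of codons of an ORF
#' @param x An [orf()].
#' @export
n_codons <- function(x) nchar(x$dna) %/% 3L

orf_codons <- function(x) split_codons(x$dna)

#' Raw per-codon translation profile
#'
#' Looks up the relative translation rate of each codon of the ORF.  Codon
#' positions are 1-based; codon 1 is the start codon.
#'
#' @param orf An [orf()].
#' @param rates A [codon_rates()] table.
#' @return A `translation_profile`: list with `orf_id`, `codons`, `raw`
#'   (numeric, one rate per codon), `smoothed` (NA until [smooth_profile()]
#'   is applied) and `window`.
#' @export
raw_profile <- function(orf, rates) {
  codons <- orf_codons(orf)
  missing_codons <- setdiff(unique(codons), names(rates))
  if (length(missing_codons))
    stop("no rate for codon(s): ", paste(missing_codons, collapse = ", "))
  structure(list(orf_id = orf$id,
                 codons = codons,
                 raw = as.numeric(unclass(rates)[codons]),
                 smoothed = rep(NA_real_, length(codons)),
                 window = NA_integer_),
            class = "translation_profile")
}

#' Smooth a translation profile with a centered sliding mean
#'
#' The smoothed value at codon i is the arithmetic mean of the raw rates over
#' the centered window `i - (w-1)/2 .. i + (w-1)/2`.  Positions where a full
#' window does not fit carry `NA` — no padding and no shrinking windows, so
#' no speed is fabricated near the termini.
#'
#' @param profile A [raw_profile()].
#' @param window Odd window size in codons (default 19).
#' @return The profile with `smoothed` filled for positions
#'   `(w+1)/2 .. L-(w-1)/2`.
#' @export
smooth_profile <- function(profile, window = 19L) {
  w <- as.integer(window)
  if (w < 1L || w %% 2L == 0L) stop("window must be a positive odd integer")
  L <- length(profile$raw)
  if (w > L) stop("window (", w, ") exceeds ORF length (", L, " codons)")
  sm <- stats::filter(profile$raw, rep(1 / w, w), sides = 2)
  profile$smoothed <- as.numeric(sm)
  profile$window <- w
  profile
}

#' @export
print.translation_profile <- function(x, ...) {
  cat("translation profile of '", x$orf_id, "': ", length(x$raw),
      " codons\n", sep = "")
  cat("  raw rate range: ", format(min(x$raw)), " - ", format(max(x$raw)),
      "\n", sep = "")
  if (!all(is.na(x$smoothed)))
    cat("  smoothed (window ", x$window, "): ",
        format(min(x$smoothed, na.rm = TRUE)), " - ",
        format(max(x$smoothed, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.translation_profile <- function(x, ...) {
  data.frame(codon_pos = seq_along(x$raw),
             codon = x$codons,
             raw_rate = x$raw,
             smoothed_rate = x$smoothed)
}

#' Plot a translation profile
#'
#' Raw per-codon rates as vertical gray bars with the sliding-window mean
#' overlaid as a red line; an optional horizontal threshold line marks the
#' slow-translation cutoff.
#'
#' @param x A `translation_profile`.
#' @param threshold Optional [genome_threshold()] object or numeric value.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.translation_profile <- function(x, threshold = NULL, ...) {
  pos <- seq_along(x$raw)
  graphics::plot(pos, x$raw, type = "h", col = "gray70",
                 xlab = "codon position", ylab = "relative translation rate",
                 main = x$orf_id, ylim = c(0, max(x$raw)), ...)
  if (!all(is.na(x$smoothed)))
    graphics::lines(pos, x$smoothed, col = "red", lwd = 2)
  if (!is.null(threshold)) {
    v <- if (inherits(threshold, "translation_threshold")) threshold$value
         else threshold
    graphics::abline(h = v, col = "blue", lty = 2)
  }
  invisible(x)
}

#' Genome-wide slow-translation threshold
#'
#' Pools smoothed rates across a reference ORF set and reduces them to a
#' single cutoff below which smoothed translation is called "slow".  Methods:
#' `"percentile"` (default; `parameter` is the percentile, default 10, linear
#' interpolation), `"mean_minus_sd"` (`parameter` is the number of standard
#' deviations) and `"fixed"` (`parameter` is the threshold itself).
#'
#' @param reference_orfs List of [orf()] objects (may be empty for
#'   `method = "fixed"`).
#' @param rates A [codon_rates()] table (unused for `"fixed"`).
#' @param method One of `"percentile"`, `"mean_minus_sd"`, `"fixed"`.
#' @param parameter Method parameter (see above).
#' @param window Smoothing window in codons.
#' @param reference_set_label Free-text label for reports.
#' @return A `translation_threshold`: list with `value`, `method`,
#'   `parameter`, `reference_set_label`.
#' @export
genome_threshold <- function(reference_orfs, rates = NULL,
                             method = c("percentile", "mean_minus_sd", "fixed"),
                             parameter = 10, window = 19L,
                             reference_set_label = "reference set") {
  method <- match.arg(method)
  if (method == "fixed") {
    value <- as.numeric(parameter)
  } else {
    if (length(reference_orfs) == 0L)
      stop("empty reference ORF set (only method = \"fixed\" allows this)")
    pooled <- unlist(lapply(reference_orfs, function(o) {
      p <- smooth_profile(raw_profile(o, rates), window = window)
      p$smoothed[!is.na(p$smoothed)]
    }))
    value <- switch(method,
      percentile = as.numeric(stats::quantile(pooled, parameter / 100,
                                              type = 7, names = FALSE)),
      mean_minus_sd = mean(pooled) - parameter * stats::sd(pooled))
  }
  structure(list(value = value, method = method, parameter = parameter,
                 reference_set_label = reference_set_label),
            class = "translation_threshold")
}

#' @export
print.translation_threshold <- function(x, ...) {
  cat("slow-translation threshold: ", format(x$value),
      " (", x$method, ", parameter ", x$parameter, "; ",
      x$reference_set_label, ")\n", sep = "")
  invisible(x)
}

threshold_value <- function(threshold) {
  if (inherits(threshold, "translation_threshold")) threshold$value
  else as.numeric(threshold)
}

#' Detect translational attenuation sites
#'
#' Attenuation sites are maximal runs of consecutive codon positions whose
#' smoothed rate lies strictly below the threshold.  Runs separated by fewer
#' than `min_gap` codons are merged (one biological pause should not fragment
#' into several calls).  Each site reports the position of its smoothed
#' minimum (ties: smallest position) and the value there.
#'
#' @param profile A smoothed [raw_profile()] (see [smooth_profile()]).
#' @param threshold A [genome_threshold()] object or a numeric cutoff.
#' @param min_gap Runs closer than this many codons are merged (default 5).
#' @return A data frame (class `attenuation_sites`) with columns
#'   `start_codon`, `end_codon`, `argmin_codon`, `depth`; zero rows when
#'   nothing lies below the threshold.
#' @export
detect_minima <- function(profile, threshold, min_gap = 5L) {
  if (all(is.na(profile$smoothed)))
    stop("profile has no smoothed values; call smooth_profile() first")
  cutoff <- threshold_value(threshold)
  below <- !is.na(profile$smoothed) & profile$smoothed < cutoff
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]; ends <- ends[keep]
  sites <- empty_sites()
  if (length(starts)) {
    # merge runs separated by < min_gap codons
    m_start <- starts[1L]; m_end <- ends[1L]
    merged <- list()
    if (length(starts) > 1L) for (i in 2L:length(starts)) {
      if (starts[i] - m_end - 1L < min_gap) {
        m_end <- ends[i]
      } else {
        merged[[length(merged) + 1L]] <- c(m_start, m_end)
        m_start <- starts[i]; m_end <- ends[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(m_start, m_end)
    sites <- do.call(rbind, lapply(merged, function(se) {
      span <- se[1L]:se[2L]
      vals <- profile$smoothed[span]
      am <- span[which.min(vals)]  # which.min: first = smallest position
      data.frame(start_codon = se[1L], end_codon = se[2L],
                 argmin_codon = am, depth = profile$smoothed[am])
    }))
  }
  structure(sites, threshold = cutoff, orf_id = profile$orf_id,
            class = c("attenuation_sites", "data.frame"))
}

empty_sites <- function() {
  data.frame(start_codon = integer(0), end_codon = integer(0),
             argmin_codon = integer(0), depth = numeric(0))
}

#' @export
print.attenuation_sites <- function(x, ...) {
  cat(nrow(x), " attenuation site(s)",
      if (!is.null(attr(x, "orf_id"))) paste0(" in '", attr(x, "orf_id"), "'"),
      " (threshold ", format(attr(x, "threshold")), ")\n", sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Offsets of attenuation sites from upstream domain boundaries
#'
#' For each site, finds the closest domain whose end lies at or upstream of
#' the site's smoothed minimum and reports the offset (in amino acids, equal
#' to codon-index difference) from that domain end.  Sites upstream of every
#' domain end get `NA`.
#'
#' @param sites A [detect_minima()] result.
#' @param domains Data frame with columns `start_aa`, `end_aa` (1-based,
#'   inclusive), sorted and non-overlapping.
#' @return `sites` with columns `domain_end_aa` and `offset_aa` appended.
#' @export
site_domain_offsets <- function(sites, domains) {
  if (!all(c("start_aa", "end_aa") %in% names(domains)))
    stop("domains must have columns start_aa and end_aa")
  if (nrow(domains)) {
    if (is.unsorted(domains$start_aa, strictly = TRUE))
      stop("domains must be sorted by start_aa")
    if (any(domains$end_aa < domains$start_aa))
      stop("domain end_aa precedes start_aa")
    if (nrow(domains) > 1L &&
        any(domains$start_aa[-1L] <= domains$end_aa[-nrow(domains)]))
      stop("domains overlap")
  }
  out <- as.data.frame(sites)
  out$domain_end_aa <- NA_integer_
  out$offset_aa <- NA_integer_
  for (i in seq_len(nrow(out))) {
    upstream_ends <- domains$end_aa[domains$end_aa <= out$argmin_codon[i]]
    if (length(upstream_ends)) {
      de <- max(upstream_ends)
      out$domain_end_aa[i] <- de
      out$offset_aa[i] <- out$argmin_codon[i] - de
    }
  }
  structure(out, threshold = attr(sites, "threshold"),
            orf_id = attr(sites, "orf_id"),
            class = c("attenuation_sites", "data.frame"))
}
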