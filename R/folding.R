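# mRNA folding energy around the start codon.  A folding engine is any
# function mapping an RNA string to the minimum free energy (kcal/mol) of
# its secondary structure; the default adapter shells out to RNAfold
# (ViennaRNA) at default parameters (37 C).  Profiles assign each window's
# dG to the window-center nucleotide, position 0 being the first nucleotide
# of the start ATG.

#' Folding engine backed by RNAfold (ViennaRNA)
#'
#' Returns a function `RNA string -> MFE (kcal/mol)` that invokes the
#' `RNAfold` executable with default parameters.  Unpairable sequences
#' (e.g. homopolymer A) get 0.
#'
#' @param exe Name or path of the RNAfold executable.
#' @return A folding-engine function.
#' @export
#' @examples
#' \dontrun{
#' engine <- rnafold_engine()
#' engine("GGGAAACCC")  # about -1.2
#' }
rnafold_engine <- function(exe = "RNAfold") {
  if (!nzchar(Sys.which(exe)))
    stop("RNAfold executable not found on PATH: ", exe)
  function(rna) {
    rna <- dna_to_rna(toupper(rna))
    out <- system2(exe, args = c("--noPS"), input = rna, stdout = TRUE)
    # last line: "structure ( -1.20)"
    m <- regmatches(out, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
    m <- m[nzchar(m)]
    if (!length(m)) stop("could not parse RNAfold output")
    as.numeric(gsub("[()\\s]", "", m[length(m)], perl = TRUE))
  }
}

#' Sliding-window folding-energy profile around the start codon
#'
#' Computes the minimum free energy of every `window_nt`-long window whose
#' center lies in `range` (nucleotide positions relative to the first
#' nucleotide of the start codon, which is position 0).  Centers lacking
#' full sequence context on either side are omitted, not extrapolated.
#' Defaults reproduce the standard initiation-region scan: window 39 nt,
#' centers -50..+50, which needs at least 69 nt of upstream context.
#'
#' @param orf An [orf()] carrying an `upstream` context sequence.
#' @param engine A folding engine (see [rnafold_engine()]).
#' @param window_nt Odd window length in nucleotides (default 39).
#' @param range Length-2 integer vector of center positions (default
#'   `c(-50, 50)`).
#' @return A `folding_energy_profile`: data frame with columns `center_pos`
#'   and `dG`, attributes `window_nt` and `orf_id`.
#' @export
dg_profile <- function(orf, engine, window_nt = 39L, range = c(-50L, 50L)) {
  window_nt <- as.integer(window_nt)
  if (window_nt < 1L || window_nt %% 2L == 0L)
    stop("window_nt must be a positive odd integer")
  half <- (window_nt - 1L) %/% 2L
  up <- if (is.null(orf$upstream)) "" else orf$upstream
  need_up <- -(range[1L]) + half
  if (range[1L] < 0L && nchar(up) < need_up)
    stop("insufficient upstream context: centers from ", range[1L],
         " with a ", window_nt, " nt window require ", need_up,
         " nt (have ", nchar(up), ")")
  seq_full <- paste0(up, orf$dna)
  origin <- nchar(up)  # 0-based index of the A of ATG in seq_full
  centers <- seq.int(range[1L], range[2L])
  # keep centers with full context on both sides
  ok <- (origin + centers - half >= 0L) &
        (origin + centers + half <= nchar(seq_full) - 1L)
  centers <- centers[ok]
  if (!length(centers))
    stop("no window center has full sequence context")
  dg <- vapply(centers, function(p) {
    lo <- origin + p - half + 1L  # to 1-based substring coordinates
    engine(dna_to_rna(substr(seq_full, lo, lo + window_nt - 1L)))
  }, numeric(1))
  structure(data.frame(center_pos = centers, dG = dg),
            window_nt = window_nt, orf_id = orf$id,
            class = c("folding_energy_profile", "data.frame"))
}

#' @export
print.folding_energy_profile <- function(x, ...) {
  cat("folding-energy profile of '", attr(x, "orf_id"), "': centers ",
      min(x$center_pos), "..", max(x$center_pos), " (window ",
      attr(x, "window_nt"), " nt)\n", sep = "")
  cat("  dG range: ", format(min(x$dG)), " .. ", format(max(x$dG)),
      " kcal/mol\n", sep = "")
  invisible(x)
}

#' Plot a folding-energy profile
#' @param x A `folding_energy_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.folding_energy_profile <- function(x, ...) {
  graphics::plot(x$center_pos, x$dG, type = "l",
                 xlab = "nucleotide position relative to start ATG",
                 ylab = expression(Delta * G ~ "(kcal/mol)"),
                 main = attr(x, "orf_id"), ...)
  graphics::abline(v = 0, col = "gray60", lty = 3)
  invisible(x)
}

# Synonymous third-base options of a codon (all codons for the same amino
# acid differing from it only at position 3), original included.
third_base_options <- function(codon) {
  syn <- synonymous_codons(codon)
  syn[substr(syn, 1, 2) == substr(codon, 1, 2)]
}

#' Weaken 5'-coding-region mRNA structure by synonymous third-base edits
#'
#' Lowers the secondary-structure propensity of the initial coding region so
#' ribosome loading is not blocked by a stable 5' hairpin.  Two modes:
#'
#' * `"force_preferred"` — for each codon in `codon_range`, set the third
#'   base to `base_preference` (default A) whenever the change is
#'   synonymous; codons where it would change the protein (e.g. ATG, TGG)
#'   are skipped.  No folding engine required.
#' * `"search"` — exhaustively enumerate all synonymous third-base variants
#'   over `codon_range` and return the plan maximizing the minimum dG over
#'   window centers covering the edited codons.  Ties prefer fewer edits,
#'   then more `base_preference` third bases, then the lexicographically
#'   smallest sequence.
#'
#' Codons 1-2 are never edited (the start codon and its immediate neighbour
#' stay untouched).
#'
#' @param orf An [orf()]; `"search"` mode uses its upstream context for
#'   folding windows.
#' @param engine Folding engine (required for `"search"`).
#' @param codon_range Length-2 vector of 1-based codon positions (default
#'   `c(3, 7)`).
#' @param base_preference Preferred third base (default `"A"`).
#' @param mode `"force_preferred"` (default) or `"search"`.
#' @param window_nt Folding window (default 39).
#' @return A [substitution_plan()] with reason `"five_prime"`.
#' @export
#' @examples
#' plan <- optimize_five_prime(orf("m9", "ATGAAACCCCGCACGGTGCCG"))
#' plan$result_dna  # "ATGAAACCACGAACAGTACCA"
optimize_five_prime <- function(orf, engine = NULL, codon_range = c(3L, 7L),
                                base_preference = "A",
                                mode = c("force_preferred", "search"),
                                window_nt = 39L) {
  mode <- match.arg(mode)
  lo <- as.integer(codon_range[1L]); hi <- as.integer(codon_range[2L])
  if (lo < 3L) stop("codons 1-2 are never edited; codon_range must start >= 3")
  if (hi < lo) stop("empty codon_range")
  if (hi > n_codons(orf))
    stop("codon_range extends beyond the ORF (", n_codons(orf), " codons)")
  codons <- orf_codons(orf)
  positions <- lo:hi

  if (mode == "force_preferred") {
    edits <- empty_edits()
    for (pos in positions) {
      new <- paste0(substr(codons[pos], 1, 2), base_preference)
      if (new != codons[pos] && !(new %in% stop_codons()) &&
          genetic_code()[[new]] == genetic_code()[[codons[pos]]])
        edits <- rbind(edits, edit_row(pos, codons[pos], new, "five_prime"))
    }
    return(substitution_plan(orf, edits))
  }

  # search mode
  if (is.null(engine)) stop("search mode requires a folding engine")
  half <- (window_nt - 1L) %/% 2L
  span_lo_nt <- (lo - 1L) * 3L        # 0-based nt, relative to ATG
  span_hi_nt <- hi * 3L - 1L
  center_range <- c(span_lo_nt - half, span_hi_nt + half)
  # clip to centers with full window context
  up_len <- if (is.null(orf$upstream)) 0L else nchar(orf$upstream)
  center_range[1L] <- max(center_range[1L], half - up_len)
  center_range[2L] <- min(center_range[2L], nchar(orf$dna) - 1L - half)
  if (center_range[1L] > center_range[2L])
    stop("insufficient sequence context around codon_range for a ",
         window_nt, " nt folding window")
  options_per_pos <- lapply(positions, function(p) third_base_options(codons[p]))
  grid <- expand.grid(options_per_pos, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  objective <- function(variant_codons) {
    work <- codons
    work[positions] <- variant_codons
    cand <- orf
    cand$dna <- paste(work, collapse = "")
    prof <- dg_profile(cand, engine, window_nt = window_nt,
                       range = center_range)
    min(prof$dG)
  }
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    variant <- as.character(grid[i, ])
    obj <- objective(variant)
    n_edit <- sum(variant != codons[positions])
    n_pref <- sum(substr(variant, 3, 3) == base_preference)
    seq_key <- paste(variant, collapse = "")
    cand <- list(variant = variant, obj = obj, n_edit = n_edit,
                 n_pref = n_pref, seq_key = seq_key)
    if (is.null(best) || obj > best$obj ||
        (obj == best$obj && (n_edit < best$n_edit ||
          (n_edit == best$n_edit && (n_pref > best$n_pref ||
            (n_pref == best$n_pref && seq_key < best$seq_key))))))
      best <- cand
  }
  changed <- which(best$variant != codons[positions])
  edits <- empty_edits()
  for (j in changed)
    edits <- rbind(edits, edit_row(positions[j], codons[positions[j]],
                                   best$variant[j], "five_prime"))
  substitution_plan(orf, edits)
}
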