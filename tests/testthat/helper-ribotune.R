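# Shared fixtures and independent oracles for the test suite.

# Built-in E. coli rate table, computed once per run.
ecoli_rates <- codon_rates(ecoli_trna_table(), ecoli_wobble_map())

# Random in-frame ORF: start codon followed by random sense codons.
random_orf <- function(n_codons, id = "rnd") {
  body <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA")),
                 n_codons - 1L, replace = TRUE)
  orf(id, paste(c("ATG", body), collapse = ""))
}

# Build a translation_profile directly from a numeric vector (codon labels
# are placeholders), for operations that only look at raw/smoothed values.
profile_from_values <- function(raw, smoothed = NULL, window = NA_integer_,
                                id = "synthetic") {
  structure(list(orf_id = id,
                 codons = rep("NNN", length(raw)),
                 raw = as.numeric(raw),
                 smoothed = if (is.null(smoothed)) rep(NA_real_, length(raw))
                            else as.numeric(smoothed),
                 window = window),
            class = "translation_profile")
}

# --- independent oracles -------------------------------------------------

# Naive O(L*w) centered sliding mean; NA where no full window fits.
oracle_smooth <- function(raw, w) {
  L <- length(raw)
  half <- (w - 1L) %/% 2L
  out <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    lo <- i - half; hi <- i + half
    if (lo >= 1L && hi <= L) {
      s <- 0
      for (j in lo:hi) s <- s + raw[j]
      out[i] <- s / w
    }
  }
  out
}

# Linear-interpolation percentile (independent of stats::quantile): the
# p-th percentile of sorted x interpolates between order statistics at
# rank 1 + (n-1) * p/100.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- 1 + (n - 1) * p / 100
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Position-by-position run finder with gap merging and first-minimum
# argmin; mirrors the attenuation-site contract with plain loops.
oracle_minima <- function(smoothed, cutoff, min_gap) {
  below <- which(!is.na(smoothed) & smoothed < cutoff)
  if (!length(below)) return(NULL)
  groups <- list(c(below[1L], below[1L]))
  for (p in below[-1L]) {
    last <- groups[[length(groups)]]
    if (p - last[2L] - 1L < min_gap) {
      groups[[length(groups)]][2L] <- p
    } else groups[[length(groups) + 1L]] <- c(p, p)
  }
  do.call(rbind, lapply(groups, function(g) {
    span <- g[1L]:g[2L]
    am <- span[1L]
    for (q in span)
      if (!is.na(smoothed[q]) && smoothed[q] < smoothed[am]) am <- q
    data.frame(start_codon = g[1L], end_codon = g[2L], argmin_codon = am,
               depth = smoothed[am])
  }))
}

# All-pairs nearest-upstream-domain search.
oracle_offsets <- function(argmins, domain_ends) {
  vapply(argmins, function(a) {
    ends <- domain_ends[domain_ends <= a]
    if (!length(ends)) NA_integer_ else as.integer(a - max(ends))
  }, integer(1))
}

# Deterministic stub folding engines (no thermodynamics needed).
gc_stub_engine <- function(rna) {
  -sum(strsplit(rna, "")[[1]] %in% c("G", "C"))
}
g_stub_engine <- function(rna) {
  -sum(strsplit(rna, "")[[1]] == "G")
}

# Synthetic 5' context (labelled synthetic: the expression-vector upstream
# region is not public) -- 69 nt, deterministic.
synthetic_upstream <- function() {
  paste(rep("TACGATCGATTTGCAGTAACGCT", 3), collapse = "")
}

# Deterministic synthetic downstream extension for short 5' fragments.
# Deliberately A/T-rich and unstructured so folding windows that overlap it
# are dominated by the 5' region under study, not by the flank.
synthetic_downstream <- function(n_codons = 20L) {
  paste(rep("GAAATTACT", ceiling(n_codons / 3)), collapse = "")
}
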