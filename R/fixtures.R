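# Synthetic fixtures: seeded ORF sets with known domain boundaries and
# planted slow-codon runs, so the whole pipeline (profile -> threshold ->
# site detection -> redesign) can be exercised and validated without any
# external sequence.
#
# The generator emulates a well-expressed bacterial coding sequence: the
# background amino-acid alphabet is restricted to residues whose fastest
# synonyms are all decoded by abundant E. coli tRNAs (Leu, Val, Arg, Glu,
# Gly, Ala), so a fully codon-optimized background translates uniformly
# fast, while `slow_fraction` mixes in random synonym choices to mimic
# natural codon-usage heterogeneity.  Planted attenuation sites are
# contiguous runs of the slowest Leu synonym (CTA under the built-in table),
# the same primitive the redesign module uses.

fixture_alphabet <- c("L", "V", "R", "E", "G", "A")

#' Generate a seeded synthetic fixture
#'
#' Produces `n_orfs` ORFs with one generated domain boundary per planted
#' site; each ORF carries every planted site, a run of `depth` slowest-Leu
#' codons centered `offset_aa` amino acids downstream of its domain end.
#' Deterministic for a fixed seed (byte-identical files on re-run).
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_orfs Number of ORFs.
#' @param length_codons ORF length in codons (>= 19).
#' @param slow_fraction Probability that a background codon is drawn
#'   uniformly from all synonyms instead of being the fastest one (0 =
#'   fully fast-codon-optimized background).
#' @param planted_sites List of `c(offset_aa, depth)` pairs (or a data frame
#'   with those columns): pause runs to plant, `depth` = run length in
#'   codons (default 19 when omitted).
#' @param dir Optional directory: writes `orfs.fasta`, `domains.tsv` and the
#'   host tRNA table `trna.tsv` there.
#' @param rates Rate table used to pick fastest/slowest synonyms (default:
#'   built-in E. coli).
#' @return List with `orfs` (list of [orf()]), `domains` (data frame
#'   `seq_id`, `start_aa`, `end_aa`), `truth` (planted-site coordinates per
#'   ORF) and, when `dir` is given, `paths`.
#' @export
generate_fixture <- function(seed, n_orfs = 6L, length_codons = 300L,
                             slow_fraction = 0.5, planted_sites = list(),
                             dir = NULL, rates = NULL) {
  if (length_codons < 19L) stop("length_codons must be >= 19")
  if (slow_fraction < 0 || slow_fraction > 1)
    stop("slow_fraction must be in [0, 1]")
  if (is.null(rates))
    rates <- codon_rates(ecoli_trna_table(), ecoli_wobble_map())
  plant <- normalize_planted(planted_sites)
  L <- as.integer(length_codons)

  # domain layout and planted-run coordinates (deterministic, shared by all
  # ORFs of the fixture)
  k <- nrow(plant)
  n_dom <- max(k, 1L)
  dom_ends <- round(seq_len(n_dom) * L / (n_dom + 2))
  truth0 <- NULL
  if (k) {
    centers <- dom_ends[seq_len(k)] + plant$offset_aa
    half_run <- (plant$depth - 1L) %/% 2L
    run_start <- centers - half_run
    run_end <- run_start + plant$depth - 1L
    if (any(run_start < 2L) || any(run_end > L))
      stop("planted site outside ORF: run [", run_start[1L], ", ",
           run_end[1L], "] vs ", L, " codons")
    if (k > 1L && any(run_start[-1L] <= run_end[-k]))
      stop("planted sites overlap")
    truth0 <- data.frame(domain_end_aa = dom_ends[seq_len(k)],
                         offset_aa = plant$offset_aa,
                         planted_center = centers,
                         run_start = run_start, run_end = run_end)
  }

  gc <- genetic_code()
  slow_leu <- slowest_synonym("CTG", rates)
  fastest_by_aa <- vapply(fixture_alphabet, function(aa) {
    fastest_synonym(sort(names(gc)[gc == aa])[1L], rates)
  }, character(1))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  orfs <- vector("list", n_orfs)
  truth <- NULL
  for (i in seq_len(n_orfs)) {
    id <- sprintf("fix%02d", i)
    aa_seq <- sample(fixture_alphabet, L, replace = TRUE)
    codons <- character(L)
    use_random <- stats::runif(L) < slow_fraction
    for (j in seq_len(L)) {
      codons[j] <- if (use_random[j]) {
        syn <- synonymous_codons(fastest_by_aa[[aa_seq[j]]])
        syn[sample.int(length(syn), 1L)]
      } else fastest_by_aa[[aa_seq[j]]]
    }
    codons[1L] <- "ATG"
    if (k) for (s in seq_len(k))
      codons[truth0$run_start[s]:truth0$run_end[s]] <- slow_leu
    orfs[[i]] <- orf(id, paste(codons, collapse = ""))
    if (k) truth <- rbind(truth, cbind(orf_id = id, truth0))
  }

  dom_starts <- c(1L, utils::head(dom_ends, -1L) + 1L)
  domains <- do.call(rbind, lapply(orfs, function(o)
    data.frame(seq_id = o$id, start_aa = dom_starts, end_aa = dom_ends)))

  out <- list(orfs = orfs, domains = domains, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(orfs = file.path(dir, "orfs.fasta"),
                  domains = file.path(dir, "domains.tsv"),
                  trna = file.path(dir, "trna.tsv"))
    write_fasta(orfs, paths$orfs)
    utils::write.table(domains, paths$domains, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    file.copy(ribotune_extdata("ecoli_trna_dong1996.tsv"), paths$trna,
              overwrite = TRUE)
    out$paths <- paths
  }
  out
}

normalize_planted <- function(planted_sites) {
  if (is.data.frame(planted_sites)) {
    if (!"depth" %in% names(planted_sites)) planted_sites$depth <- 19L
    return(data.frame(offset_aa = as.integer(planted_sites$offset_aa),
                      depth = as.integer(planted_sites$depth)))
  }
  if (!length(planted_sites))
    return(data.frame(offset_aa = integer(0), depth = integer(0)))
  do.call(rbind, lapply(planted_sites, function(p) {
    offset <- as.integer(p[[1L]])
    depth <- if (length(p) >= 2L) as.integer(p[[2L]]) else 19L
    if (depth < 1L) stop("planted-site depth (run length) must be >= 1")
    data.frame(offset_aa = offset, depth = depth)
  }))
}
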