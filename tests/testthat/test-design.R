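# ORF with a single Leu (CTG) placed at a chosen codon position, on an
# otherwise Leu-free fast background.
leu_at <- function(pos, L = 120, leu = "CTG") {
  codons <- c("ATG", rep("GAA", L - 1))
  codons[pos] <- leu
  orf("leu1", paste(codons, collapse = ""))
}

test_that("insert_pause swaps the Leu nearest the preferred offset to CTA", {
  o <- leu_at(80)  # domain end 50 + preferred offset 30
  plan <- insert_pause(o, 50, ecoli_rates)
  expect_equal(nrow(plan$edits), 1)
  expect_equal(plan$edits$codon_pos, 80)
  expect_equal(plan$edits$old_codon, "CTG")
  expect_equal(plan$edits$new_codon, "CTA")
  expect_equal(plan$edits$reason, "insert_pause")

  # several Leus: nearest to offset 30 wins; equidistant -> smaller position
  codons <- c("ATG", rep("GAA", 119))
  codons[c(75, 85)] <- "CTC"
  o2 <- orf("leu2", paste(codons, collapse = ""))
  plan2 <- insert_pause(o2, 50, ecoli_rates)
  expect_equal(plan2$edits$codon_pos, 75)
  expect_equal(plan2$edits$old_codon, "CTC")
})

test_that("insert_pause is idempotent when the window Leu is already CTA", {
  o <- leu_at(80, leu = "CTA")
  plan <- insert_pause(o, 50, ecoli_rates)
  expect_equal(nrow(plan$edits), 0)
  expect_equal(plan$result_dna, o$dna)
})

test_that("insert_pause validates the target window", {
  o <- leu_at(80, L = 100)
  expect_error(insert_pause(o, 50, ecoli_rates), "outside the ORF")
  # window of only Met/Trp: no synonymous slow-down exists
  codons <- c("ATG", rep("TGG", 119))
  o2 <- orf("trp", paste(codons, collapse = ""))
  expect_error(insert_pause(o2, 50, ecoli_rates),
               "no synonymous slow-down possible")
})

test_that("insert_pause strictly deepens the window minimum unless empty", {
  set.seed(71)
  for (i in 1:10) {
    o <- random_orf(150)
    plan <- insert_pause(o, 40, ecoli_rates)
    if (nrow(plan$edits) == 0) next
    before <- smooth_profile(raw_profile(o, ecoli_rates), 19)
    redesigned <- orf(o$id, plan$result_dna)
    after <- smooth_profile(raw_profile(redesigned, ecoli_rates), 19)
    # minimum over the smoothed positions whose window covers the edit
    covering <- intersect((plan$edits$codon_pos[1] - 9):
                          (plan$edits$codon_pos[1] + 9),
                          which(!is.na(before$smoothed)))
    expect_lt(min(after$smoothed[covering]), min(before$smoothed[covering]))
  }
})

test_that("Leu-free greedy fallback matches exhaustive search on small windows", {
  # 21-codon ORF, design window codons 6..15: every smoothed window (w = 19)
  # covers all candidate codons, so the smoothed minimum is linear in the
  # summed rate decrease and greedy must equal brute force.
  cfg <- design_config(offset_range_aa = c(5L, 14L), preferred_offset_aa = 9L,
                       max_codons_per_site = 2L)
  aa_pool <- c("GGT", "CCG", "ACC", "TCT", "CGT", "GTT", "GCG")  # no Leu
  set.seed(72)
  for (i in 1:10) {
    codons <- c("ATG", sample(aa_pool, 20, replace = TRUE))
    o <- orf("greedy", paste(codons, collapse = ""))
    plan <- insert_pause(o, 1, ecoli_rates, cfg = cfg, window = 19)
    # brute force: all <= 2-subsets of window positions, slowest synonyms
    win <- 6:15
    best_sum <- sum(unclass(ecoli_rates)[codons])
    for (k in 1:2) for (combo in utils::combn(win, k, simplify = FALSE)) {
      work <- codons
      for (p in combo)
        work[p] <- {
          syn <- names(Biostrings::GENETIC_CODE)[
            Biostrings::GENETIC_CODE ==
              Biostrings::GENETIC_CODE[[codons[p]]]]
          syn[which.min(unclass(ecoli_rates)[syn])]
        }
      best_sum <- min(best_sum, sum(unclass(ecoli_rates)[work]))
    }
    got <- orf("got", plan$result_dna)
    got_sum <- sum(unclass(ecoli_rates)[
      substring(got$dna, seq(1, nchar(got$dna), 3),
                seq(3, nchar(got$dna), 3))])
    expect_equal(got_sum, best_sum)
    expect_lte(nrow(plan$edits), 2)
  }
})

test_that("remove_pause swaps below-threshold codons to fastest synonyms", {
  codons <- c("ATG", rep("GAA", 30))
  codons[10:12] <- c("CTA", "CAT", "TCG")
  o <- orf("slowpatch", paste(codons, collapse = ""))
  site <- data.frame(start_codon = 10, end_codon = 12)
  plan <- remove_pause(o, site, ecoli_rates, threshold = 0.35)
  e <- plan$edits
  expect_equal(e$codon_pos[e$old_codon == "CTA"], 10)
  expect_equal(e$new_codon[e$old_codon == "CTA"], "CTG")
  # every edited position now carries the per-amino-acid fastest synonym
  for (i in seq_len(nrow(e))) {
    syn <- names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE == Biostrings::GENETIC_CODE[[e$old_codon[i]]]]
    expect_equal(unname(unclass(ecoli_rates)[e$new_codon[i]]),
                 max(unclass(ecoli_rates)[syn]))
  }

  # already-fastest site: nothing to do
  fast <- orf("fast", paste(c("ATG", rep("CTG", 20)), collapse = ""))
  p2 <- remove_pause(fast, data.frame(start_codon = 5, end_codon = 10),
                     ecoli_rates, threshold = 0.99)
  expect_equal(nrow(p2$edits), 0)
})

test_that("remove_pause never lowers a raw rate and lifts the smoothed site", {
  set.seed(81)
  for (i in 1:20) {
    o <- random_orf(80)
    start <- sample(5:60, 1)
    site <- data.frame(start_codon = start, end_codon = start + 10)
    cutoff <- runif(1, 0.1, 0.6)
    plan <- remove_pause(o, site, ecoli_rates, threshold = cutoff)
    before <- raw_profile(o, ecoli_rates)$raw
    after <- raw_profile(orf(o$id, plan$result_dna), ecoli_rates)$raw
    expect_true(all(after >= before))
    sb <- oracle_smooth(before, 19); sa <- oracle_smooth(after, 19)
    idx <- !is.na(sb)
    expect_true(all(sa[idx] >= sb[idx]))
    # oracle: below-threshold positions end at the per-aa maximum synonym
    codons <- substring(o$dna, seq(1, nchar(o$dna), 3),
                        seq(3, nchar(o$dna), 3))
    for (p in start:(start + 10)) {
      if (unclass(ecoli_rates)[[codons[p]]] < cutoff) {
        syn <- names(Biostrings::GENETIC_CODE)[
          Biostrings::GENETIC_CODE == Biostrings::GENETIC_CODE[[codons[p]]]]
        expect_equal(unname(after[p]), max(unclass(ecoli_rates)[syn]))
      } else {
        expect_equal(after[p], before[p])
      }
    }
  }
})

test_that("remove_all_pauses clears detected sites and merges per-site plans", {
  fx <- generate_fixture(seed = 101, n_orfs = 4, length_codons = 250,
                         slow_fraction = 0, planted_sites = list(c(30, 19)))
  ref <- generate_fixture(seed = 102, n_orfs = 6, length_codons = 250,
                          slow_fraction = 0.5)
  th <- genome_threshold(ref$orfs, ecoli_rates, "percentile", 10)
  for (o in fx$orfs) {
    prof <- smooth_profile(raw_profile(o, ecoli_rates), 19)
    sites <- detect_minima(prof, th)
    expect_gt(nrow(sites), 0)
    plan <- remove_all_pauses(o, th, ecoli_rates)
    # merged plan equals the union of per-site plans
    per_site <- unlist(lapply(seq_len(nrow(sites)), function(i)
      remove_pause(o, sites[i, ], ecoli_rates, th)$edits$codon_pos))
    expect_setequal(plan$edits$codon_pos, unique(per_site))
    # closure: the redesigned ORF has no (or fewer) detected sites
    redesigned <- orf(o$id, plan$result_dna)
    prof2 <- smooth_profile(raw_profile(redesigned, ecoli_rates), 19)
    expect_lte(nrow(detect_minima(prof2, th)), nrow(sites))
  }

  # already-uniform ORF: empty plan
  fast <- orf("fast", paste(c("ATG", rep("CTG", 99)), collapse = ""))
  expect_equal(nrow(remove_all_pauses(fast, 0.3, ecoli_rates)$edits), 0)
})

test_that("insert then remove on the same window restores rate dominance", {
  o <- leu_at(80)
  ins <- insert_pause(o, 50, ecoli_rates)
  mid <- orf(o$id, ins$result_dna)
  rem <- remove_pause(mid, data.frame(start_codon = 70, end_codon = 90),
                      ecoli_rates, threshold = 0.5)
  before <- raw_profile(o, ecoli_rates)$raw
  after <- raw_profile(orf(o$id, rem$result_dna), ecoli_rates)$raw
  expect_true(all(after >= before))
})

test_that("verify_synonymy compares standard-genetic-code translations", {
  src <- orf("m9", "ATGAAACCCCGCACGGTGCCG")
  expect_true(verify_synonymy(src, list(result_dna = "ATGAAACCACGAACAGTACCA")))
  expect_equal(translate_dna(src$dna), "MKPRTVP")
  expect_true(verify_synonymy(src, list(result_dna = src$dna)))
  nonsyn <- "ATGCAACCCCGCACGGTGCCG"  # codon 2 AAA -> CAA
  expect_false(verify_synonymy(src, list(result_dna = nonsyn)))
  expect_error(verify_synonymy(src, list(result_dna = "ATG")), "length")
})

test_that("substitution_plan enforces synonymy and distinct positions", {
  o <- orf("x", "ATGCTGCTC")
  expect_error(substitution_plan(o, data.frame(codon_pos = 2,
                                               old_codon = "CTG",
                                               new_codon = "ATG",
                                               reason = "insert_pause")),
               "non-synonymous")
  dup <- rbind(data.frame(codon_pos = 2, old_codon = "CTG", new_codon = "CTA",
                          reason = "insert_pause"),
               data.frame(codon_pos = 2, old_codon = "CTG", new_codon = "TTA",
                          reason = "insert_pause"))
  expect_error(substitution_plan(o, dup), "distinct")
})

test_that("local folding-energy annotation flags large changes", {
  codons <- c("ATG", rep("GAA", 119))
  codons[80] <- "CTG"
  o <- orf("ddg", paste(codons, collapse = ""))
  # engine that rewards G-richness strongly: CTG -> CTA removes one G
  harsh <- function(rna) -3 * sum(strsplit(rna, "")[[1]] == "G")
  expect_warning(plan <- insert_pause(o, 50, ecoli_rates, engine = harsh),
                 "folding energy")
  expect_equal(plan$edits$local_ddG, 3)
  expect_true(plan$edits$ddg_warning)

  gentle <- function(rna) -0.5 * sum(strsplit(rna, "")[[1]] == "G")
  plan2 <- insert_pause(o, 50, ecoli_rates, engine = gentle)
  expect_equal(plan2$edits$local_ddG, 0.5)
  expect_false(plan2$edits$ddg_warning)
})
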