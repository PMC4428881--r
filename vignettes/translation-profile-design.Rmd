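---
title: "Translation-profile guided synonymous redesign: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translation-profile guided synonymous redesign: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotune)
```

## The problem

mRNA is translated at a non-uniform speed, and that rhythm is functional:
transient ribosome pauses downstream of protein domain boundaries give each
domain time to fold co-translationally before the next one emerges.  When a
multi-domain protein is moved into a new expression host, the host's tRNA
pool reads its codons at different relative speeds, the pauses vanish (or
appear in the wrong places), and the protein partitions into insoluble
inclusion bodies.  Independently, stable mRNA secondary structure around
the start codon can block ribosome loading and suppress expression
altogether.  Both defects can be repaired without touching the protein
sequence, by synonymous codon exchanges — which is what this package
computes.

## The rate model

The relative translation rate of sense codon $c$ in a host is modelled as
the summed concentration of the tRNA species able to decode it:

$$\mathrm{rate}(c) \;=\; \frac{\sum_{a \,\in\, \mathrm{decoders}(c)} [\mathrm{tRNA}_a]}{\max_{c'} \sum_{a \,\in\, \mathrm{decoders}(c')} [\mathrm{tRNA}_a]}$$

`decoders(c)` comes from a codon→anticodon wobble map.  This is the minimal
model in which per-codon speed is driven by cognate tRNA supply; it
deliberately ignores near-cognate competition, amino-acid starvation
effects, and codon-context coupling, none of which can be parameterized
from bulk tRNA abundances alone.  Normalizing by the maximum makes rates
dimensionless, scale-invariant in the concentrations, and capped at 1
(`normalization_mode = "sum"` is available for users who prefer
probabilities).

Two data files ship with the package and are deliberately editable TSVs:

* `ecoli_trna_dong1996.tsv` — *E. coli* tRNA concentrations (molecules per
  cell at 0.4 doublings/h, an approximate transcription of the classic
  Northern-blot measurements).  Analyses in this package depend on
  *orderings* (e.g. the CUA-decoding Leu isoacceptor being the rarest Leu
  tRNA), not on any single absolute value.  One representational quirk: the
  AUA-reading Ile isoacceptor carries a lysidine-modified CAU anticodon,
  which would collide with the elongator-Met anticodon in an
  anticodon-keyed table; it is therefore listed under its *functional*
  anticodon UAU (noted in the file).
* `ecoli_wobble.tsv` — a curated decoding table (Watson–Crick plus the
  standard wobble rules for the known isoacceptor set: cmo⁵U34 reading
  A/G/U, mnm⁵(s²)U34 reading A/G, inosine reading U/C/A, G34 reading C/U).
  It is shipped as data rather than derived algorithmically because base
  modifications make rule-based derivation unreliable; users targeting
  other hosts supply their own table.

When tRNA concentrations are unknown for a species, the codon-usage
fallback `rare_codons()` defines rare codons as the `k = 10` least-used
codons (lexicographic tie-break), which is the standard proxy.

## Profiles, threshold, attenuation sites

`raw_profile()` maps an ORF to per-codon rates (codon 1 = start codon,
1-based).  `smooth_profile()` applies a centered arithmetic-mean window of
**19 codons** — roughly the stretch of mRNA a translating ribosome commits
to around its A site, and the window at which individual slow codons merge
into a site-level signal.  Positions where a full window does not fit carry
`NA`: no padding and no shrinking windows, so no speed is fabricated at the
termini.  The mean (rather than median or a weighted kernel) is the
simplest statistic consistent with interpreting the smoothed value as
average transit time per codon.

The *genome-wide threshold* separating "slow" from ordinary translation is
not analytically defined anywhere; we default to the **10th percentile**
(linear-interpolation quantile) of pooled smoothed rates over a
user-supplied reference ORF set, because a percentile is scale-free,
reproducible, and transparent.  `mean_minus_sd` and `fixed` are offered as
alternatives, and the method and parameter are carried in the returned
threshold object so reports are self-describing.

`detect_minima()` calls maximal runs of smoothed rate strictly below the
threshold; runs separated by fewer than `min_gap = 5` codons are merged so
one biological pause does not fragment into several calls; each site
reports its smoothed minimum (`argmin`, ties resolved to the smallest
position).  `site_domain_offsets()` pairs each site with the nearest
upstream domain end; offsets are in amino acids and equal codon-index
differences.

## Pause design

`insert_pause()` targets the window 20–70 aa downstream of a domain
boundary — the ribosome exit tunnel covers roughly 30 (20–70) C-terminal
residues of the nascent chain, so a pause there lets the upstream domain
emerge fully before translation resumes.  Design logic, in order:

1. If the window contains a codon of the preferred pause amino acid (Leu)
   that is not already the preferred slow codon (**CTA**), exactly one edit
   is made: the Leu nearest the preferred offset (30 aa; distance ties go
   to the smaller position) becomes CTA.  A single codon read by a very
   rare tRNA suffices for a transient pause, and one edit minimizes
   side-effects on mRNA structure.
2. If every window Leu is already CTA, the plan is empty (the site is
   already slow).
3. Leu-free windows fall back to greedy slowest-synonym substitution:
   repeatedly replace the codon whose slow-synonym swap yields the largest
   rate decrease, up to `max_codons_per_site = 3` edits, stopping early
   once the window's smoothed minimum falls below a supplied threshold.
   When no threshold is supplied the greedy loop simply spends its full
   edit budget.  Met/Trp-only windows raise an error: no synonymous
   slow-down exists.

`remove_pause()` is the inverse: every codon in a called site whose rate is
below the site-call threshold is swapped to its fastest synonym
(lexicographic tie-break), which provably never lowers any raw rate and
never deepens the smoothed profile.  `remove_all_pauses()` composes
detection and removal into one merged plan — the "uniformly fast" redesign.

Every plan construction enforces synonymy (`verify_synonymy()` compares
standard-genetic-code translations), distinct edit positions, and
reproducibility of `result_dna` from the edit list.  When a folding engine
is supplied, each edit is annotated with the local folding-energy change
over the 39-nt window centered on the edited codon; edits beyond the
`ddg_guard_kcal = 2.0` kcal/mol guard raise an explicit warning rather than
being dropped silently — single synonymous changes can alter mRNA
stability, and the user should see it, but the guard value itself is a
package choice, surfaced in `design_config()`.

## 5′ folding energy

`dg_profile()` computes minimum free energy in a **39-nt** sliding window
whose centers run over nucleotide positions **−50..+50** relative to the
first nucleotide of the start codon (position 0).  Centers lacking full
context on either side are omitted, never extrapolated; the default range
therefore needs ≥69 nt of upstream context, which must be supplied (the
package refuses to fabricate vector sequence).  Folding is delegated
through an engine contract — any function from RNA string to MFE — with
`rnafold_engine()` binding RNAfold (ViennaRNA) at default parameters
(37 °C).  The tests use deterministic stub engines (e.g. −G-count) so the
suite exercises all the windowing logic without thermodynamics.

`optimize_five_prime()` edits only third codon positions within
`codon_range = c(3, 7)`; codons 1–2 are never touched (the start codon is
fixed, and in practice codon 2 tends to be A-rich already).
`force_preferred` mode sets each third base to A where synonymous — A-rich
sequence pairs poorly and destabilizes local structure.  `search` mode
exhaustively enumerates synonymous third-base combinations and maximizes
the minimum dG over window centers spanning the edited codons (ties: fewest
edits, then most preferred bases, then lexicographically smallest
sequence).  The exhaustive search is affordable because each codon has at
most four third-base synonyms and the range is short (≤4⁵ variants at the
defaults).

## The fixture generator

`generate_fixture()` produces the synthetic study material: seeded ORF sets
with known domain boundaries and planted pause sites, so site recovery can
be scored against ground truth.  Design choices, and what they do and do
not emulate:

* **Background.**  Codons are drawn per position from a reduced amino-acid
  alphabet (Leu, Val, Arg, Glu, Gly, Ala) whose fastest synonyms are all
  decoded by abundant *E. coli* tRNAs.  With `slow_fraction = 0` the
  background is a fully codon-optimized gene translating uniformly fast —
  the negative control; `slow_fraction = 0.5` (the reference default) mixes
  in uniform-random synonym choices, mimicking the codon-usage
  heterogeneity of a natural transcriptome.  The reduced alphabet is
  deliberate: it makes "fast background" an actual property rather than an
  accident of amino-acid composition, at the cost of unrealistic protein
  sequences — these fixtures model translation kinetics, not proteins.
* **Planted sites.**  A planted site is a run of the slowest Leu synonym
  (CTA under the built-in table) of length `depth` codons (default 19,
  matching the smoothing window so the site's smoothed minimum reaches the
  run's own rate), centered `offset_aa` downstream of a generated domain
  end.  Real pause sites are rarely homogeneous runs; the homogeneous run
  is the cleanest recoverable ground truth.
* **Host model.**  The fixture directory receives the shipped *E. coli*
  tRNA table, so "slowest synonym" is well defined and deterministic.
* Same seed ⇒ byte-identical output files.

Passing recovery tests on these fixtures shows the pipeline finds what its
own rate model considers slow, at the offsets where it was planted.  It
does not show that real heterologous genes carry such clean signals, that
the threshold default transfers to any particular reference transcriptome,
or anything about actual protein solubility — those are wet-lab outcomes
outside the scope of computation.

## Numerical and degenerate-input choices

* Percentile = linear interpolation between order statistics
  (`stats::quantile` type 7).
* All argmin/argmax tie-breaks go to the smallest codon position; synonym
  ties go to the lexicographically smallest codon.
* Sequences are DNA internally; T↔U conversion happens only at the
  folding-engine boundary and in anticodon identifiers.
* A single trailing stop codon on an input ORF is stripped (profiles are
  defined over sense codons); an internal stop is an error with its
  position named.
* `smooth_profile()` rejects even windows and windows longer than the ORF
  rather than guessing.
* Site detection uses strict inequality (`smoothed < threshold`), so a
  constant profile at exactly the threshold yields no sites.

## Problem sizes in the shipped tests

The randomized suites use 200 instances per oracle comparison, 1,000
randomized design calls for protein-conservation checks, fixture sets of
8–10 ORFs × 300 codons, and short (≤60-codon) ORFs with 7-nt stub-engine
windows for the exhaustive 5′-search comparisons — sizes chosen so the
whole suite settles in about a minute while still exercising every
branch.  The acceptance script reports, among other quantities, folding
minima computed with the real RNAfold engine on the printed start-region
sequences embedded in deliberately A/T-rich synthetic flanks (the true
expression-vector context is not public), restricted to window centers
inside the edited codons 3–7 so the comparison reflects the region under
study rather than the synthetic flanks.

## Known limitations

* Rates are static per codon: no ribosome-flow/traffic simulation, no
  initiation-limited coupling between 5′ structure and elongation.
* The summed-cognate rate model ignores near-cognate competition and
  modification-state changes; the built-in abundance table is an
  approximate transcription and other growth rates will shift it.
* Domain boundaries are inputs, derived by the user from structural
  homology; the package does not predict structure.
* The ΔΔG guard flags but does not veto; mRNA half-life effects of
  synonymous edits are not modelled.
* `rare_codons()` is a usage-frequency proxy, not a kinetic statement.
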