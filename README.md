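# ribotune

Heterologous multi-domain proteins frequently misfold and aggregate into
inclusion bodies when expressed in *Escherichia coli*.  One reason is that
the host's tRNA pool translates the foreign mRNA at the wrong rhythm:
the transient ribosome pauses that normally give each protein domain time to
fold co-translationally are missing (or, conversely, pauses that should be
there get "optimized" away).  A second, independent bottleneck is stable
mRNA secondary structure around the start codon, which blocks ribosome
loading and suppresses expression outright.

`ribotune` is an R toolkit for diagnosing and engineering both properties by
purely synonymous codon exchanges:

* **Translation-speed profiles.**  The relative translation rate of a sense
  codon *c* is modelled as the summed concentration of the tRNAs able to
  decode it,

  rate(*c*) = Σ<sub>a ∈ decoders(*c*)</sub> [tRNA<sub>a</sub>] / max over the 61 sense codons,

  using a host tRNA abundance table and a codon→anticodon wobble-decoding
  map (an *E. coli* table and curated decoding map ship with the package).
  Profiles are smoothed with a 19-codon centered sliding mean.
* **Attenuation sites.**  Maximal runs of smoothed rate below a genome-wide
  threshold (default: 10th percentile of pooled smoothed rates over a
  reference ORF set) are called as putative ribosome pause sites, and can be
  positioned relative to protein domain boundaries.
* **Pause design.**  `insert_pause()` places a pause 20–70 aa downstream of
  a domain boundary (preferring a single Leu → CTA exchange — CTA is read by
  the rarest Leu isoacceptor in *E. coli*, so one codon suffices);
  `remove_pause()` / `remove_all_pauses()` erase pauses by swapping
  below-threshold codons to their fastest synonyms.  Every plan provably
  preserves the encoded protein (`verify_synonymy()`), and edits are
  annotated with the local 39-nt folding-energy change (warning beyond
  ±2 kcal/mol).
* **5′ structure optimization.**  `dg_profile()` scans minimum free energy
  in a 39-nt sliding window across nucleotide positions −50..+50 around the
  start codon (RNAfold backend, pluggable engine), and
  `optimize_five_prime()` weakens 5′ structure by synonymous third-base
  substitutions in codons 3–7 (preferring A), either forced or by
  exhaustive search.

## Worked example

```r
library(ribotune)
rates <- codon_rates(ecoli_trna_table(), ecoli_wobble_map())
round(rates[c("CTA", "CTC", "CTT", "TTA", "TTG", "CTG")], 3)
#>   CTA   CTC   CTT   TTA   TTG   CTG
#> 0.117 0.165 0.282 0.181 0.516 0.900
```

CTA is the slowest leucine codon (rate 0.117 relative to the fastest codon
in the genome), which is why a single CTG→CTA exchange creates a pause.
Insert one downstream of a domain that ends at residue 71:

```r
o <- orf("target", paste(c("ATG", rep("GAA", 99), "CTG", rep("GAA", 59)),
                         collapse = ""))
insert_pause(o, domain_end_aa = 71, rates)
#> substitution plan for 'target': 1 synonymous edit(s)
#>  codon_pos old_codon new_codon       reason local_ddG ddg_warning
#>        101       CTG       CTA insert_pause        NA       FALSE
```

The Leu at codon 101 — 30 aa downstream of the boundary, the typical length
of nascent chain buried in the ribosome exit tunnel — is swapped to CTA.
Detection works the other way around: on a synthetic ORF with a planted
slow-codon run (package fixture generator), the pipeline recovers it:

```r
ref <- generate_fixture(seed = 42, n_orfs = 8, length_codons = 300,
                        slow_fraction = 0.5)          # genome-like reference
th  <- genome_threshold(ref$orfs, rates, "percentile", 10)
tgt <- generate_fixture(seed = 43, n_orfs = 1, length_codons = 300,
                        slow_fraction = 0,
                        planted_sites = list(c(30, 19)))$orfs[[1]]
prof  <- smooth_profile(raw_profile(tgt, rates), 19)
sites <- detect_minima(prof, th)
site_domain_offsets(sites, data.frame(start_aa = 1, end_aa = 100))
#> 1 attenuation site(s) in 'fix01' (threshold 0.6181812)
#>  start_codon end_codon argmin_codon     depth domain_end_aa offset_aa
#>          117       142          130 0.1167192           100        30
```

The site's smoothed minimum sits exactly 30 aa downstream of the domain
boundary where the generator planted it.  Finally, the 5′ optimizer on a
structure-prone start region:

```r
optimize_five_prime(orf("M9dH11", "ATGAAACCCCGCACGGTGCCG"))
#> substitution plan for 'M9dH11': 5 synonymous edit(s)
#>  codon_pos old_codon new_codon     reason local_ddG ddg_warning
#>          3       CCC       CCA five_prime        NA       FALSE
#>          4       CGC       CGA five_prime        NA       FALSE
#>          5       ACG       ACA five_prime        NA       FALSE
#>          6       GTG       GTA five_prime        NA       FALSE
#>          7       CCG       CCA five_prime        NA       FALSE
```

yielding `ATGAAACCACGAACAGTACCA` — same protein (MKPRTVP), far less 5′
structure.

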