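Package: ribotune
Title: Translation-Profile Guided Synonymous Redesign of Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-codon translation-speed profiles for open reading
    frames from host tRNA abundances and a codon-anticodon decoding map,
    detects slow-translating attenuation sites relative to a genome-wide
    threshold, and produces synonymous redesigns that either insert
    ribosome-pausing codons downstream of protein domain boundaries (to aid
    co-translational folding of heterologous multi-domain proteins) or erase
    existing pauses.  Also profiles mRNA folding energy around the start codon
    with a sliding window and weakens 5' secondary structure by synonymous
    third-base substitutions.  Ships an Escherichia coli tRNA abundance table
    and wobble decoding map; every redesign preserves the encoded protein.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
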