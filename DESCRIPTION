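Package: vgmotif
Title: Variant- and Haplotype-Aware Motif Scanning on Variation Graphs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans transcription-factor motifs (position weight matrices in
    JASPAR or MEME format) over pangenome variation graphs built from a
    reference genome plus phased variants. K-mer windows are enumerated
    along observed haplotype paths (or all recombinant walks), scored with
    an integer-scaled log-odds matrix, assigned exact P-values by dynamic
    programming over the score distribution, and Benjamini-Hochberg
    q-values pooled over all extracted k-mer paths. Occurrences are
    reported with haplotype counts and reference/non-reference flags in
    FIMO-compatible TSV, GFF3 and HTML reports. Includes a deterministic
    toy-data generator with planted motif instances for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    parallel,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
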