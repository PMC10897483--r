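Package: crispaav
Title: Amplicon Sequencing Analysis of CRISPR Editing Outcomes and AAV
    Vector Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies on-target CRISPR editing outcomes from targeted
    amplicon sequencing while retaining reads that carry long insertions
    of AAV vector sequence, which conventional amplicon tools discard.
    Reads are partitioned into amplicon-only, chimeric (amplicon plus
    vector) and vector-only classes; amplicon-only reads are aligned with
    an affine-gap glocal aligner and summarised into a normalized indel
    variant table; chimeric reads are resolved into integration events
    with vector-genome coverage and ITR arm breakpoint statistics;
    deletion junctions are scored for flanking microhomology to profile
    microhomology-mediated end joining. Includes a paired-nickase cut
    geometry calculator, degenerate-PAM off-target identity scoring, and
    a truth-tagged synthetic read simulator so the whole pipeline can be
    validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
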