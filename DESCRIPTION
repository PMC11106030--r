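Package: squigglescope
Title: Comparative Visualization and Testing of Nanopore Current Events at
    Candidate Modification Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Contrasts a native and a negative-control nanopore sequencing
    sample at candidate DNA/RNA base-modification sites. Reads raw current
    signals (ASCII SLOW5) and per-read event indices (f5c resquiggle,
    eventalign, basecaller move tables, Tombo-style TSV), normalizes signals
    per read by median shift and MAD scale with clipping, projects
    basecall-space events onto the reference through the alignment CIGAR,
    computes per-read per-position event features (mean, median, standard
    deviation, dwell time), profiles per-position nucleotide composition and
    mismatch fractions from BAM pileups, and tests per-position group
    separation with a k-mer-window PCA followed by MANOVA (Pillai's trace).
    Includes a synthetic squiggle generator producing internally consistent
    reference, signal, event, and alignment fixtures, figure builders for
    alignment, current-feature, PCA, and significance panels, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    grDevices,
    IRanges,
    Rsamtools,
    ggplot2,
    jsonlite,
    optparse,
    patchwork,
    MASS,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
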