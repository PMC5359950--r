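Package: anchorsim
Title: Anchored Phylogenetic Genome and Short-Read Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates whole-genome short-read datasets from a known
    phylogeny in which one tip is an observed "anchor" genome reproduced
    byte-for-byte. Variable sites are drawn from a general time-reversible
    (GTR) substitution process conditioned on the anchor state, placed
    uniformly or with exponential clustering, insertions and deletions are
    simulated on branches with Lavalette-distributed lengths, and
    Illumina-like paired-end reads are generated at a target fold
    coverage. Outputs per-tip FASTA genomes, a truth VCF, a gapped
    alignment, an indel event log and gzipped FASTQ, so that SNP-calling
    and tree-inference pipelines can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    IRanges,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
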