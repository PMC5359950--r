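# anchorsim

Simulate whole-genome short-read datasets from a known phylogeny, with one
tip — the **anchor genome** — reproduced byte-for-byte from an observed
assembly. Because the true tree, the true variant positions, and the true
per-tip alleles are all known exactly, the output is ground truth for
validating SNP-calling and phylogeny-inference pipelines: map the simulated
reads against the anchor (or a relative of it), call variants, infer a tree,
and compare against what was simulated.

## The science

Empirical benchmarks for variant-calling pipelines never know the real
answer; fully synthetic benchmarks know the answer but drift away from the
properties of real genomes. `anchorsim` splits the difference:

* **Anchored simulation.** One tip of the user's phylogeny is assigned a
  real assembly, emitted unchanged. Every other tip genome is that assembly
  plus simulated mutations, so simulated reads can be mapped against the
  same reference as empirical reads.
* **Fixed SNP count, GTR substitutions.** The user fixes the *total number
  of variable sites* (avoiding ascertainment-bias guesswork), and the
  simulator distributes mutations along branches in proportion to branch
  length under a general time-reversible (GTR) model. Alignment columns are
  simulated natively: the tree is re-rooted at the anchor tip (valid for
  any reversible, stationary model), the root state is fixed to the anchor
  base, states are propagated through matrix-exponential transition
  probabilities, and non-variable columns are rejected until the demanded
  number of variable columns per anchor base is met. The anchor is thus
  *structurally* incapable of mutating.
* **Site placement.** Sites are placed uniformly over all unambiguous
  A/C/G/T positions, or with a configurable fraction *clustered*: each
  clustered site sits at signed offset `±(1 + floor(Exp(mean)))` from a
  previously placed site, mimicking the clustered substitution patterns of
  recombining bacteria without simulating recombination itself.
* **Indels.** Insertion and deletion events occur on branches with
  probability proportional to branch length; event counts are Poisson with
  mean `rate × nSNPs` per kind; lengths follow the bounded heavy-tailed
  Lavalette distribution `P(L) ∝ (L·M/(M−L+1))^(−a)`. Events never touch
  the anchor's coordinates, SNP sites, or each other, so the truth
  alignment is exactly invertible back to the event log.
* **Reads.** Paired-end reads with Normal fragment lengths and a per-cycle
  error model (default: linear ramp from 0.1% to 1% across the read), at a
  user-set fold coverage. Same-seed runs are byte-identical, including the
  gzipped FASTQ files.

Everything the simulator decides is written down: a truth VCF, a per-contig
gapped alignment of all tips, a TSV indel event log, per-tip FASTA genomes,
and a JSON manifest.

## Worked example

```r
library(anchorsim)

# generate a small self-contained example: a 6-tip tree, a 50 kb genome,
# and a configuration file requesting 100 variable sites with indels
cfg <- writeFixture("example", nTips = 6, genomeLength = 50000, seed = 42,
                    nSites = 100, indelRate = 0.1, clustering = TRUE,
                    clusteredFraction = 0.2, exponentialMean = 125,
                    coverage = 20)
manifest <- runSimulation(cfg, seed = 1)
```

```
05:58:01  run starting, seed 1
05:58:01  tree: 6 tips; genome: 50000 bp
05:58:01  placed 100 sites (20 clustered)
05:58:03  simulated 40000 columns, kept 22526 variable
05:58:03  15 indel events (7 insertions, 8 deletions)
05:58:03  wrote 6 genomes, VCF, event log, alignment
05:58:07  read stage complete for 6 tips
```

```r
list.files("example/output")
#> [1] "fasta"                        "fastq"
#> [3] "sim_alignment_contig01.fasta" "sim_events.tsv"
#> [5] "sim_manifest.json"            "sim.log"
#> [7] "sim.vcf"
```

The truth VCF records every simulated site with haploid genotypes per tip
(`t2` is the anchor here, so its genotype is always the REF allele):

```
#CHROM    POS   ID  REF  ALT  QUAL FILTER INFO FORMAT t2 t4 t6 t5 t1 t3
contig01  165   .   T    G    .    .      .    GT     0  1  1  1  1  1
contig01  2923  .   T    A,C  .    .      .    GT     0  1  2  2  2  2
contig01  4075  .   T    G    .    .      .    GT     0  0  1  0  1  1
```

The event log records each indel with its branch, 1-based anchor position,
length, inserted sequence, and carrier tips:

```
kind       branch  contig    pos1   length  seq  tips
insertion  4       contig01  97     1       C    t5
deletion   8       contig01  31575  6       .    t3,t1,t5,t6,t4
```

The anchor comes back untouched, and reads are standard paired FASTQ:

```r
a <- Biostrings::readDNAStringSet("example/fixture.fasta")
b <- Biostrings::readDNAStringSet("example/output/fasta/t2/sim_t2.fasta")
identical(as.character(a[[1]]), as.character(b[[1]]))
#> [1] TRUE
```

```
@t2:contig01:22642:23103:R:1/1
CCCGAACAAGCTTGCCGCTGACTTCAGCTCCATTTAGGAGTCTTCGGGCT...
```

At coverage 20 with 250 bp reads on 50 kb this yields 2,000 pairs per tip
(`8000` FASTQ lines in each `R1` file). Rerunning with the same seed
reproduces every output file byte-for-byte; `genomesOnly()` skips the read
stage, and `readsOnly()` regenerates identical reads from a finished
genome stage.

To drive a run on your own data, write a `key=value` config file (see
`?parseConfig` for the full vocabulary and defaults) pointing at your
Newick tree and anchor FASTA, then `runSimulation("my.config")`. A
command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "anchorsim.R", package = "anchorsim"))') run -c my.config --seed 1
```

## Package layout

* `R/` — S4 classes (`AnchorGenome`, `SimTree`, `GTRModel`, `SitePlan`,
  `MutationSites`, `TipGenome`, `ReadProfile`, `SimulationConfig`) and the
  pipeline stages: config parsing, GTR machinery, site placement, column
  assignment, indel simulation, genome/alignment/VCF construction, read
  simulation, and the orchestrating `runSimulation()`.
* `inst/scripts/anchorsim.R` — CLI with `run`, `genomes-only`, and
  `fixture` subcommands.
* `vignettes/anchored-simulation.Rmd` — methods vignette: model choices,
  the anchor-rooting argument, and design trade-offs.
* `tests/testthat/` — unit, property, and acceptance tests (all oracles
  are independent implementations: `ape::matexpo` enumeration, closed
  forms, brute-force normalisations).
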