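---
title: "Anchored phylogenetic genome and read simulation: methods"
author: "anchorsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored phylogenetic genome and read simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorsim)
```

# Purpose

`anchorsim` produces benchmark datasets for SNP-calling and
phylogeny-inference pipelines. The user supplies a phylogeny with branch
lengths, an observed genome assembly, and a target number of variable
sites; the simulator emits one genome per tip — one of which, the
**anchor**, is the input assembly reproduced byte-for-byte — plus
paired-end reads, a truth VCF, a gapped truth alignment, and an indel
event log. This vignette records the statistical model and the design
decisions; see the README for a worked example.

# Substitution model

Substitutions follow a general time-reversible (GTR) model: six
exchangeabilities $s_{ij}$ (reported relative to $s_{GT} = 1$) and four
stationary frequencies $\pi$ taken, by default, from the anchor genome's
own base composition. The rate matrix $Q_{ij} = s_{ij}\pi_j$ is scaled so
that $-\sum_i \pi_i Q_{ii} = 1$, i.e. branch lengths are expected
substitutions per site. Transition probabilities $P(t) = e^{Qt}$ are
computed by matrix exponential (`Matrix::expm`); the test suite checks
them against the JC69 closed form and against `ape::matexpo` so that the
implementation and its oracle share no code.

```{r gtr}
m <- buildGTR(c(1.207, 5.9306, 1.7425, 0.461, 5.1238, 1),
              c(A = 0.3115, C = 0.1907, G = 0.1891, T = 0.3087))
round(transitionProbs(m, 0.1), 4)
```

# Why rooting at the anchor is valid

The input tree may be rooted anywhere. We re-orient all edges away from
the anchor tip and simulate each alignment column by drawing the root
(anchor) state and propagating it along the oriented edges. For a
reversible, stationary model the joint tip-pattern distribution is
invariant to root placement (the "pulley principle"), so this changes
nothing statistically — but it makes the anchor's invariance
*structural*: the anchor base is an input to the simulation, never an
output, so no code path can mutate it. Fixing the root state to the
observed anchor base is exactly conditioning the column distribution on
that base. A test enumerates all tip patterns under three different
rootings and confirms the distributions agree to $10^{-10}$.

# Fixed SNP count and column rejection

Pipelines are usually evaluated on variable sites only, so the simulator
takes the *total SNP count* as a parameter rather than deriving it from
branch lengths (which would entangle the benchmark with an ascertainment
model). The site-placement stage picks the genomic coordinates; the
column stage reads off the anchor base at each coordinate and demands
that many *variable* columns conditioned on each root state. Columns are
simulated in batches and non-variable ones rejected. A chi-square test
checks the retained columns against the exhaustively enumerated
conditional pattern distribution.

# Site placement

Uniform placement samples without replacement over all unambiguous
A/C/G/T positions across contigs in one concatenated coordinate frame.
Clustered placement puts a fraction of sites at a signed offset
$d = \pm(1 + \lfloor \mathrm{Exp}(\text{mean}) \rfloor)$ from a uniformly
chosen already-placed site, rejecting draws that leave the contig, land
on an ambiguous base, or collide. The $+1$ shift keeps offsets nonzero;
acceptance target `t3` removes it before comparing the sample mean to the
configured exponential mean. Clustering imitates the spatially
correlated substitutions left by homologous recombination without
simulating recombination across lineages, which is out of scope.

# Indels

Indel events are attached to branches with probability proportional to
branch length. Event counts per kind are Poisson with mean
$\text{rate} \times n_\text{SNPs}$, i.e. the configured rate is *per
kind, per substitution site* (`indel_rate = 0.1` with 500 SNPs gives ~50
insertions and ~50 deletions; acceptance target `t6`). Lengths follow
the Lavalette distribution
$P(L) \propto \left( \frac{LM}{M - L + 1} \right)^{-a}$, $L = 1..M$,
sampled by inverse CDF; it is heavy-tailed but bounded, matching
observed indel-length spectra.

Three placement constraints keep the ground truth exactly recoverable:
events never overlap a SNP site (a deleted "variable site" would break
the exact-SNP-count guarantee), anchor-coordinate spans of distinct
events are disjoint with a 1 bp buffer (adjacent gap runs would
otherwise merge in the alignment and become unrecoverable as separate
events), and deletions never span contig boundaries. The test suite and
acceptance target `t8` re-derive all events from the gap structure of
the emitted alignment and require zero discrepancies against the event
log — the analogue of validating the realized gap distribution against
the simulator's intent.

# Genomes, alignment, truth VCF

Each tip genome is the anchor sequence with that tip's substitutions
applied, then its inherited indels (an event is inherited by exactly the
tips subtended by its branch). The truth alignment is reconstructed per
contig in anchor coordinates: deletions become `-` fills, insertions
become columns that are gaps in every non-carrier including the anchor.
The VCF is haploid VCF 4.2 with one record per variable site and ALT
alleles in first-seen tip order; `vcfR` is used in the tests as an
independent reader.

# Reads

Read pairs are simulated per tip: fragment length
$\sim \mathcal{N}(\mu, \sigma)$ truncated to
$[\text{read length}, \text{contig length}]$, uniform start, fair-coin
strand; R1 is the 5' end, R2 the reverse complement of the 3' end. The
pair count is $\text{round}(\text{coverage} \times L / (2 \times
\text{read length}))$, so realized coverage matches the target up to
rounding (acceptance target `t7`). Sequencing errors are substitutions
drawn per cycle from a position-dependent rate vector — by default a
linear ramp from 0.001 at cycle 1 to 0.01 at the last cycle,
alternatively `flat:<rate>` or `profile:<tsv>` — and the emitted Phred
qualities are the rates' own transformation, so downstream callers see
internally consistent qualities. FASTQ is gzip-compressed with a zeroed
timestamp, making same-seed runs byte-identical.

# Seeding and stage isolation

One user seed governs a run. Each stage (site placement, column
simulation, indels, and each tip's read simulation separately) derives
its own child seed through a fixed string hash of the stage name, so
adding or removing the read stage — or regenerating reads for one tip —
never perturbs any other stage. `readsOnly()` on a finished genome stage
reproduces the full run's FASTQ bytes exactly.

# Problem sizes and limitations

The validation suite runs on synthetic fixtures: genomes of 50 kb–10 Mb
of i.i.d. composition-matched sequence and random trees with exponential
branch lengths (`generateFixture`). These exercise every code path at
realistic scale but are not real genomes: they contain no repeats, no
genes, and no compositional heterogeneity, so mapping-difficulty effects
(a large part of why real pipelines miscall) are *not* represented —
users wanting those effects should supply a real assembly as the anchor.
Other limits: substitutions are i.i.d. across sites given placement (no
rate heterogeneity or invariant-sites mixture), indels carry no
within-event substitution structure, recombination/HGT is not simulated
(clustered placement only imitates its spatial signature), and the read
error model is substitution-only with deterministic per-cycle qualities
rather than an empirically trained profile.

# Validation summary

Quantitative claims are recomputed by `scripts/acceptance.R --seed <s>
--out <json>` against the installed package: clustered-offset mean ≈125
bp, Lavalette maximum ≤541 over 100,000 draws, indel events per kind per
SNP ≈0.1 over 200 runs, realized coverage ≈20, and zero event-log versus
alignment discrepancies. The test suite adds exact SNP counts, anchor
byte-identity under indels, agreement with exhaustive pattern
enumeration (256 patterns, chi-square), and recovery of the GTR
exchangeabilities within 10% by maximum likelihood from 50,000 simulated
columns.
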