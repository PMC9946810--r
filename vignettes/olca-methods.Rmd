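---
title: "Methods: rank-based minimizer hashing and likelihood-driven layout in olca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based minimizer hashing and likelihood-driven layout in olca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olca)
```

## Overview

`olca` implements the overlap–layout–consensus (OLC) model for long
sequencing reads (PacBio HiFi-like error profiles: ~0.5% substitutions, ~1%
indels). Its distinctive ingredients are

1. a **k-mer-count-informed minimizer hash** built on a fixed-size 15-mer
   spectrum, which makes single-copy k-mers win minimizer selection and
   deprioritises repeat-derived k-mers without discarding them;
2. an **undirected overlap graph with two vertices per read** (5'-end and
   3'-end), which represents both sequencing strands without committing to an
   orientation;
3. **edge selection as layout**: instead of hard overlap filters, edges are
   ranked by a likelihood computed from feature distributions fitted on
   "safe" (reciprocal-best) edges, and paths are grown greedily under
   matching and acyclicity constraints;
4. **consensus polishing** by pileup majority plus local de Bruijn
   reassembly of indel-active regions; and
5. **haplotype phasing** (ReFHap-style minimum error correction) used to
   remove cross-haplotype edges from the graph before a second layout pass,
   yielding phased diploid assemblies.

This vignette documents the model, the tunable parameters, the numerical
choices, and what the bundled simulations do and do not demonstrate.

## The 15-mer spectrum and the rank-based hash

The spectrum is a fixed array of 4^15 = 2^30 counters of two bytes each
(saturating at 2^15 − 1), so memory is constant (~2 GiB of address space;
resident memory grows only with the pages actually touched) regardless of
input size. Every N-free 15-mer instance of the reads is counted; under the
default `orientation = "both"` policy each instance also increments its
reverse complement, so the count of a genomic locus approximates its total
read depth and the scheme is strand-symmetric. `orientation = "canonical"`
(count min(code, rc-code) once) is available and equivalent for downstream
purposes; the genome-size estimate divides the number of scanned instances
(not array increments) by the mode, so it is policy-invariant.

The count histogram has a characteristic shape: a large error peak at count
1–2 and a coverage peak near the sequencing depth. The **mode** is found by
scanning the dense histogram upward from count 1 to the first rise (the local
minimum separating the error peak) and taking the most populous count beyond
it. A monotonically decreasing histogram (no coverage peak, e.g. a spectrum
built from an assembly rather than reads) falls back to mode 1 with a warning
flag — this is in fact the expected regime for the reference aligner.

Each k-mer (user k from 15 to 31, default 25) is encoded as a 2-bit-per-base
integer `b`. With `x` the spectrum count of the k-mer's 15-mer suffix:

* rank `r(x) = 2 |x − mode|` — modal (single-copy) k-mers rank 0; the rank is
  symmetric below and above the mode;
* hash `h(b) = cumBelow(r(x)) + (b mod primeAbove(x))`, where `cumBelow(r)`
  is the number of distinct observed 15-mers with rank strictly below `r` and
  `primeAbove(x)` is the smallest prime above `x`. The modulus term simulates
  randomness within a rank class.

Two details are interpretation choices: `cumBelow` counts **distinct observed
15-mers** (k-mers never seen in the reads do not contribute; suffixes of read
k-mers always have count ≥ 1), and the sub-mode/super-mode symmetry of the
rank is taken literally. Minimizer selection uses the standard scheme (the
minimum-hash k-mer of every window of `w` consecutive positions, default
`w = 40`, i.e. roughly one minimizer per 20 bp), choosing per position the
orientation with the smaller hash so selection is strand-symmetric. Ties
break on the smaller k-mer code, then position, making the whole module
deterministic.

The **minimizer table** is keyed by the selected k-mer code (hits are exact
k-mer matches; the hash only decides *which* k-mers become minimizers). In
reference-aligner mode, minimizers occurring 1,000+ times in the reference
are purged. Note the hash cannot serve as a table key: on a depth-1 spectrum
almost every k-mer has rank 0 and `primeAbove(1) = 2`, so hashes collapse to
{0, 1}.

## Overlap detection without pairwise alignment

Reads are sorted by decreasing length and each read is queried against the
table of longer reads, so each candidate pair has the longer read as subject.
Every minimizer hit predicts the subject coordinate at which the (oriented)
query would start; hits of a true overlap predict consistent starts. Hits of
one pair and orientation are clustered on this predicted start by 1-D gap
clustering (tolerance `delta = max(100, 1% of query length)`) refined by up
to 10 k-means (Lloyd) rounds. Per cluster the package records:

* predicted overlap — the mean of per-hit overlap inferences;
* CSK — subject bases covered by the shared k-mers (union of k-mer spans);
* the evidence span (first/last hit positions on both reads) and the
  proportion of the overlap it covers, `(lastSubj − firstSubj + k) / overlap`
  clamped to (0, 1].

Up to two clusters with the most shared k-mers are retained, and only when
they support two distinct alignment configurations (start–start, start–end,
end–start, end–end). Clusters with fewer than 5 shared k-mers or a predicted
overlap below `w + k − 1` (the minimizer sharing guarantee) are noise and are
dropped. A cluster placing the whole query inside the subject (with 2k bp
slack) marks the query **embedded**: it gets no vertices and is later mapped
onto its host's contig. Cluster geometry decides the edge: positive centroid
and forward orientation means the subject 3'-end overlaps the query 5'-end
({S^e, Q^s}); reverse orientation flips the query end. The graph is simple —
one edge per unordered vertex pair, the best-supported cluster wins.

## Layout

**Safe edges** are edges that are the reciprocal best of both endpoints in
*both* overlap length and CSK, with both endpoint degrees below
mean + 3 SD (computed over all vertices). They seed the paths and the
feature model: overlap and CSK are fitted as normals (sample mean/SD, SD
floored at 1.0 to survive degenerate sets), the evidence proportion as a beta
via method of moments (values clipped to [1e−6, 1 − 1e−6], variance clamped
inside (0, m(1−m))). With fewer than 10 safe edges the model is flagged as
fallback and edges are ranked lexicographically by (overlap, CSK) instead.

Each remaining edge scores the sum of three **lower-tail** log P-values
(larger overlap / CSK / evidence proportion ⇒ more credible edge; of the two
possible tails, the lower one is the one that rewards strong edges), each floored at log(1e−300). Edges are traversed in
descending score; an edge is selected iff neither endpoint vertex is already
used and it does not close a cycle (disjoint set over reads, a read's two
vertices pre-united). Selected edges therefore always form a matching whose
union with the read-internal connections is a set of simple paths. Paths are
read off from free ends, orienting each read by the port it is entered
through, and canonicalised so the lexicographically smaller terminal read
name comes first.

Greedy selection can bypass a read whose neighbours chain around it; such a
read (or a short parallel chain) ends up as a redundant mini-contig. As with
embedded reads, any contig *all* of whose reads still have overlap edges into
a longer kept contig is absorbed: its reads are placed through their
best-supported edge and the contig is dropped. This never removes genuinely
novel sequence — contigs separated by coverage gaps, or haplotype-separated
contigs after edge pruning, have at least one read with no such edge.

## Consensus and polishing

The consensus of a path starts as the first oriented read; each next read is
end-aligned (banded, bandwidth 500 bp) against the consensus tail around the
edge-predicted overlap, and the consensus grows by the read's overhang. A
junction below 65% alignment identity splits the path — a conservative guard
against chimeric joins. Embedded reads are placed via their hosts.

Polishing (default 2 rounds, each a realign → substitution pass → indel pass
sweep) re-aligns all placed reads with a banded glocal alignment anchored at
their layout positions (band = 2.5% of read length, minimum 100 bp, plus the
150 bp placement pad):

* **Pass 1** replaces each column with the pileup-majority base; ties keep
  the consensus, and at least two reads must support the change (a single
  disagreeing read is no evidence).
* **Pass 2** finds **active regions**: columns where ≥ 2 reads report an
  insertion or deletion, dilated by ±5 bp and merged, so every base of a
  region is within 5 bp of an indel call. Read segments spanning the region
  (±20 bp flanks) feed a de Bruijn graph (k = 15); the heaviest path between
  consensus anchor k-mers present in at least half of the spanning segments
  replaces the region. Regions without anchors, without an anchored path, or
  with cycles in the reachable subgraph are left unchanged; regions are
  applied right-to-left so coordinates stay valid, and placements are shifted
  by the net length changes.

Polishing an already-perfect consensus with error-free reads is a no-op.
With origin sequences supplied, presumably-circular contigs are rotated so
the best origin alignment starts at position 0 (reverse-complementing first
when the hit is on the reverse strand).

Reads shorter than `minReadLength` (default 1,000 bp, the usual long-read
assembler floor) are excluded up front: a few-hundred-bp read carries too few
minimizers to be placed or even recognised as contained.

## Diploid phasing

The diploid pipeline assembles haploid-style, realigns the reads once, and
from the shared pileup calls heterozygous SNV candidates (depth ≥ 5, second
allele carrying 20–80% of the depth; both thresholds are this package's
defaults and configurable). Reads covering ≥ 2 het sites become
fragments of a reads × variants 0/1/NA matrix. Variants connected through
fragments form blocks; within a block a ReFHap-style heuristic — greedy
seeding plus randomized-restart single-fragment flips (10 + 2·n restarts,
seeded) — bipartitions the fragments to minimise the MEC score, where per
variant one haplotype allele and its complement are chosen to minimise
disagreements. On blocks of ≤ 10 fragments the heuristic is routinely
optimal (verified against exhaustive search in the test suite). Haplotype
alleles are per-variant majorities; ties take the first observed side-1
allele, which keeps the output symmetric under flipping all fragment alleles.

Blocks classify contig regions: both clusters at ≥ 25% of the block depth ⇒
**phased**; one cluster starved ⇒ **heterozygous deletion**; gaps longer than
the mean read length with no het sites ⇒ **homozygous**. Only inside phased
regions are graph edges removed, and only edges joining reads assigned to
different clusters of the same block — edge removal is deliberately
conservative. Layout, consensus and polishing are then repeated on the pruned
graph, and output contigs are tagged with the majority (block, haplotype) of
their reads.

Containment needs special care here. With read lengths comparable to the
template (20-kb reads on 50-kb test haplotypes most reads are contained in
some other read), a read embedded in a host from the *other* haplotype would
silently deposit its sequence on the wrong contig and starve its own. The
graph therefore retains all containment candidates and the overlap edges that
were set aside when a read was declared embedded ("shadow" edges). Before
re-layout, every cross-cluster-embedded read is re-hosted to its
best-supported same-cluster containment candidate; reads with no such
candidate are promoted back into the graph along with their shadow edges
(then subject to the same cross-cluster pruning). Without this step one
haplotype routinely loses multi-kilobase stretches whose reads happened to be
contained only in other-haplotype reads.

## The read simulator

`simulateReads` emulates a long-read instrument at the contract level: per
read a haplotype is drawn uniformly (diploid templates), a start uniformly, a
length from Normal(meanLen, sdLen) truncated to [200, templateLen − start]
(starts keep at least 200 bp of template), a strand uniformly; substitutions
are i.i.d. at `substRate`; indels occur at `indelRate`, split evenly between
insertions and deletions with lengths 1 + Geometric(0.5) (the even split and
the geometric length law are this package's choices).
Defaults are the HiFi-like study conditions: mean 20 kbp, SD 5 kbp, 0.5%
substitutions, 1% indels. Ground truth is encoded in the read name
(`r<i>:<template>:<start>-<end>:<strand>:<hap>`, 0-based half-open) and
round-trips losslessly through `readTruth`. One seeded RNG stream drives
everything; the same seed reproduces the same reads on any platform.

What the simulator does **not** model: homopolymer-biased (ONT-style) errors,
chimeric reads, quality-value structure, or coverage biases. Passing the
bundled end-to-end tests therefore demonstrates correctness of the algorithms
under the stated error model, not performance on real flow-cell data.

## Evaluation utilities

* `assemblyStats`: Nx/NGx curves; Nx is the length of the contig at which the
  cumulative sorted-descending length first reaches x% of the assembly (NGx:
  of the genome size; 0 when never reached).
* `alignmentAccuracy`: alignment rate and RMSE of |aligned − true start| over
  aligned reads, from truth-encoded names.
* `countSwitchErrors`: 20-kbp windows advancing 10 kbp are assigned to the
  parent with more parental-specific canonical 21-mers (ambiguous on ties or
  fewer than 10 hits); a switch is a parent change between consecutive
  assigned windows of one contig. Ambiguous windows are transparent.
* `assemblyIdentity`: per-contig identity from a banded global alignment with
  free terminal gaps on the truth side (uncovered genome ends are a property
  of the read sampling, not a base-level error of the assembler; every contig
  base still counts).

## Problem sizes and numerical choices

The bundled experiments run on a single CPU at desk scale: haploid
end-to-end on a 50-kb genome at 30× (2-kb reads), diploid end-to-end on two
50-kb haplotypes at 1% divergence and 40× total (20-kb reads), aligner
benchmarks on a 100-kb genome with 1,000 reads, and simulator calibration at
n = 10,000 reads on a 2-Mb template (large enough that end-truncation
distorts the length distribution by well under a percent). Oracle-agreement
checks (hash construction, per-window minimizer argmin, exhaustive layout
matching, exhaustive minimum-MEC) run on instances small enough for exact
enumeration. These sizes were chosen so that exact oracles are computable
and the full suite runs in minutes; the algorithms contain nothing specific
to them.

Fixed numerical guards worth knowing: alignment scores are match +2,
mismatch −3, gap −4; banded alignments return failure (never a wrong answer)
when the band is exceeded; beta fits clip proportions to [1e−6, 1 − 1e−6];
log-likelihood terms are floored at log(1e−300); counters saturate at
2^15 − 1 as in the fixed-array contract.

## Known limitations

* Repeat resolution relies entirely on edge prioritisation; there is no
  transitive reduction or string-graph cleaning, so long exact repeats above
  the read length will fragment or mis-join as in any pure OLC layout.
* The reference aligner reports k-mer-cluster alignments (start, strand,
  soft-clipped match span), not base-level CIGARs.
* Substitution-only error correction; indel errors are handled at the
  consensus stage, not per read.
* Phasing assumes a diploid sample and SNV het sites only.
* The haplotype-aware stage removes edges but does not scaffold with Hi-C or
  trio data.
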