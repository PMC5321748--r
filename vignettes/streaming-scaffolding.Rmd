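---
title: "Real-time hybrid scaffolding: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time hybrid scaffolding: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longscaff)
library(dplyr)
```

## The problem

Short-read assemblies of bacterial genomes fragment at repeat sequences
longer than the read length: an rRNA operon present at several loci, or an
insertion sequence flanking a genomic island, collapses into a single
contig and leaves gaps at every copy. Long (nanopore-style) reads span
those repeats, and because a nanopore device emits reads continuously, the
assembly can be completed *while sequencing is still running* — and the run
stopped as soon as the genome is closed. `longscaff` implements that
streaming completion: it consumes long-read-to-contig alignments in
generation order, joins single-copy contigs into scaffolds, fills the gaps
with repeat contigs, detects circular replicons (chromosomes and
plasmids), and reports contig count, N50, and circular-sequence count after
every batch.

## Copy-number classification from depth of coverage

Everything downstream rests on separating *unique* (single-copy) contigs
from *repetitive* ones. Collapsed repeats carry proportionally inflated
short-read depth: a contig present $k$ times in the genome has roughly
$k$ times the genome-wide depth. Writing $d_i$ and $\ell_i$ for the depth
and length of contig $i$ (sorted by decreasing length), the genome depth
$d_g$ is estimated as a length-weighted running mean over a prefix of the
largest contigs,

$$ d_g = \frac{\sum_{j \le m} d_j\,\ell_j}{\sum_{j \le m} \ell_j}, $$

accepting contigs one at a time while the next contig's depth ratio to the
current estimate, $\max(d_{m+1}/d_g,\; d_g/d_{m+1})$, stays below a
threshold $\theta$; accumulation also stops after `max_contigs` contigs or
at the first contig shorter than `min_contig_len`. The multiplicity of
contig $i$ is $\max(1, \lfloor d_i/d_g + 0.5 \rfloor)$ (round half-up),
and the contig is *unique* when the raw ratio $d_i/d_g < \theta$ — so a
ratio of 1.49 stays unique at the default $\theta$ while 1.51 does not.

Key parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `theta` | 1.5 | unitless depth-ratio threshold; halfway between single- and two-copy coverage |
| `max_contigs` | 20 | the estimate is stable over the ~20 largest contigs of a bacterial draft |
| `min_contig_len` | 20 000 bases | contigs this large are almost always single-copy in bacteria |
| `depth_stop` | `"symmetric"` | also stop on abnormally *low*-coverage large contigs (e.g. contamination, phage); `"high-only"` restores a one-sided test |

The symmetric stop is a deliberate design choice where the one-sided rule
would silently absorb a low-coverage outlier into the genome-depth
estimate; the flag preserves the one-sided behaviour for callers who want
it.

## Frames, spanning pairs, and bridges

Each long-read alignment is extrapolated into a *frame*: the interval the
whole contig would occupy in read coordinates (for a forward alignment,
`frame_start = read_start − contig_start`; for a reverse one,
`read_start − (contig_length − contig_end)`; the frame always has the
contig's full length and may extend past the read's ends). Two unique
contigs framed on one read expose their relative position directly:
ordering frames along the read, each *adjacent* pair becomes a placement
`(endA, endB, gap)` where `gap = frame_start(B) − frame_end(A)` (negative
= the contig ends overlap) and the ends follow from the orientations. Only
adjacent pairs are emitted — for a read touching A, B, C the chain A–B,
B–C — because long-range gap estimates compound indel noise; transitive
joins emerge when bridges merge. A read wrapping the origin of a circular
replicon aligns in two pieces to the *same* contig and yields a placement
joining that contig's tail to its own head, which is exactly how
single-contig plasmids circularize.

Placements accrete into *bridges*: a placement joins an existing bridge on
the same canonical endpoint pair when its gap is within
`max(200 bp, 0.2·|consensus|)` of the bridge's consensus; otherwise it
founds a second bridge on the same ends — a contradiction candidate
settled at commit time. The consensus gap is the quality-weighted median
of supporting gaps (robust to a single chimeric read) and the score is the
sum of per-read qualities, where a read's quality is the alignment
identity of its *weaker* anchor. Identity, not mapping quality, because
permissive aligner settings report multi-mapping records with MAPQ 0 while
their base-level identity is still informative. Anchors shorter than
`min_anchor = 300` bp on the contig or below `min_identity = 0.6` are
discarded before pairing; both knobs scale with read error rate and are
exposed.

## Greedy committing, conflict repair, circularization

Each unique contig has two *ports* (head, tail); a committed bridge
occupies one port on each endpoint. Since a port carries at most one
committed bridge, the committed set always decomposes into simple paths
and cycles — layout consistency is structural, not enforced by
bookkeeping. Commits are greedy by score (Kruskal-style): in batch mode
over the final bridge set, in streaming mode whenever a bridge reaches the
commit threshold (`min_score = 1.0`, i.e. one high-identity spanning read;
raise `min_support` for conservative runs). When an incoming bridge lands
on an occupied port, the smallest-scoring conflicting committed bridge is
broken — provided the newcomer outscores it — and the newcomer committed;
if several conflict simultaneously, minima are broken one at a time while
the newcomer still outscores the current minimum. Losing bridges stay
pending for the whole run and are retried as they gain supports. Joining
the two free ends of one path closes it into a circular component.

Gap filling happens when a bridge commits. The spanning subsequence of the
highest-quality supporting read becomes the backbone; repetitive contigs
are locally aligned against it and non-overlapping hits at identity ≥
`min_fill_identity = 0.75` splice their (short-read-accurate) bases over
the matched backbone segments. A repeat contig may fill several gaps — it
*is* a multi-copy element. Negative gaps are trimmed from the start of the
incoming segment at materialization; the layout records per-segment
provenance (`unique`, `repeat_fill`, `raw_read_fill`, `n_gap`). When a
committed bridge's support set later changes, its fill is refreshed unless
it has already settled on a repeat-contig splice (short-read bases cannot
be improved by a better backbone read); a final refresh over the complete
support sets runs at stream end, which is what makes the streamed layout
byte-identical to a batch pass over the same bridges.

## Real-time reporting and feature placement

"Real time" is modeled purely as stream order — no wall clock anywhere in
the core — so every run is deterministic given input and configuration.
After each batch of `report_every = 100` reads the engine appends a report
(cumulative bases, reads, sequence count at the 500 bp threshold, N50,
circular count), written as JSON-lines with a TSV mirror. Stopping is a
pure function of the timeline: a target sequence count, all sequences
circular, or no change for `stall_batches = 50` consecutive batches.

Features annotated on contigs (BED intervals — genes, AMR loci) are lifted
through the layout (offset plus orientation, strand flipped on reverse
placements) and tagged with a replicon status: `plasmid` when their
component contains a contig flagged as carrying a plasmid origin of
replication (flags are an input list, keeping the tool decoupled from any
origin database), `circular_plasmid` once that component closes,
`chromosome` for circular unflagged components, otherwise `unassigned`.
Status changes are logged with the cumulative bases at which they
occurred, which is what lets a user say "this resistance gene is
plasmid-borne" mid-run. Features on repetitive contigs keep their contig
coordinates: a multi-copy element has no single scaffold position.

## What the synthetic data emulates — and what it does not

The generator produces the structure the method assumes: a uniform-random
chromosome with identical repeat copies planted at non-overlapping loci
(≥ 8 kb apart, so every inter-repeat segment is a usable unique contig),
optional circular plasmids, a fragmented "assembly" whose unique contigs
draw depth from Normal(λ, (0.07λ)²) and whose collapsed k-copy repeats
draw from Normal(kλ, (0.07kλ)²), and log-normal long reads (median 8 kb,
spread `sdlog = 0.35`) with uniform per-base errors of 5% substitution /
3% insertion / 4% deletion — a 12% total approximating early-chemistry
nanopore data. Reads wrap circular origins and are emitted in random
order under the seed, modeling pore arrival. All generators are pure
functions of (config, seed).

Real data differ in ways the simulation deliberately omits: depth is not
Gaussian (GC bias, origin-proximity gradients), repeats are families of
diverged copies rather than identical plants, error is context-dependent
(homopolymers) rather than uniform, and chimeric reads exist (a flag is
reserved; the weighted-median consensus and the conflict repair are the
mitigations). Passing the synthetic suite therefore demonstrates the
*algorithmic* properties — classification, bridging arithmetic, greedy
repair, circular detection, streaming/batch agreement — not robustness to
every artefact of a real flowcell.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere internally; conversion to
  1-based inclusive happens only in the AGP writer.
- Length-sorting ties break by contig name; equal-score bridges break by
  endpoint names; linear scaffolds are oriented so the first contig name
  sorts before the last, circular ones start at their smallest-named
  contig in `+` orientation — all purely for determinism.
- Reverse-complement of `N` is `N`; lowercase input is upper-cased on
  ingestion.
- SAM reverse-strand records are flipped into original read orientation on
  parse, so frame arithmetic is identical for SAM and PAF input.
- An empty length set after the 500 bp filter is an error, not a silent
  zero; an alignment naming an unknown contig is a hard error; a feature
  on an unknown contig is a warn-and-skip.
- Statistics count sequences ≥ 500 bp, the common convention for
  reporting bacterial drafts.

## Problem sizes used in the checks

The reference scenario — 100 kb chromosome, one 5 kb repeat × 3, one 15 kb
circular plasmid, 25× reads at 12% error — is small enough that a full
simulate–align–stream cycle takes seconds, yet contains every structural
event the scaffolder handles: multi-gap chains, repeat fills, a
self-circularizing plasmid, and conflict-free streaming/batch agreement.
Classification recovery runs 100 seeded trials over λ ∈ {30, 60, 100} and
repeat copy numbers k ∈ {2, 3, 5} on drafts of a dozen unique contigs of
30–120 kb — a realistic size for a bacterial short-read assembly, and
enough length-weighted evidence for the 5% depth-recovery check to have
comfortable statistical margin — plus two collapsed repeat contigs.

## Known limitations

- Joins between two repetitive contigs are out of scope by design: repeats
  only ever fill gaps between unique contigs, so nested or tandem repeat
  structures longer than a read cannot be resolved.
- No consensus polishing of output sequences: raw-read fill segments carry
  read-level error (their provenance is recorded so downstream polishers
  can target them).
- Circular sequences are emitted unrotated (flagged, not canonicalized).
- The per-read quality model treats all reads identically; there is no
  separate weighting for higher-accuracy read classes.
- Coverage on the report x-axis requires a known genome size mid-run, so
  the timeline reports cumulative bases instead (convert downstream if a
  size estimate exists).

## A worked miniature

```{r example, eval = FALSE}
g  <- simulate_genome(seed = 7)                      # 100 kb + repeat x3 + plasmid
fa <- fragment_assembly(g, base_depth = 60, seed = 7)
ct <- classify_contigs(fa$contigs, estimate_genome_depth(fa$contigs))
rd <- simulate_long_reads(g, coverage = 25, seed = 7)
write_fastq(rd, "reads.fq"); write_contigs_fasta(ct, "contigs.fa")
paf <- align_long_reads("reads.fq", "contigs.fa")    # minimap2 wrapper
res <- run_streaming(ct, paf, reads = "reads.fq")
res$timeline                                         # per-batch N50 / counts
evaluate_assembly(res, fa$truth)                     # joins vs simulated truth
autoplot(as_timeline(res$timeline))                  # progress curves
```
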