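---
title: "Models and methods behind srnapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

srnapipe implements a complete desk-scale analysis of plant small-RNA
sequencing libraries. This vignette explains the statistical model, the
biological conventions adopted where the field leaves a choice open, the
synthetic-data generator that the test suite runs against, and the known
limits of both.

## The tag-count differential statistic

Two sRNA libraries are compared one tag (or one feature) at a time. Let
`x` be the tag's count in the control library with clean-read total
`N1`, and `y` its count in the treatment library with total `N2`. Under
the assumption that sequencing a tag is a rare event in a very large
read pool — so counts are Poisson and the depth ratio `N2/N1` scales the
rate — the probability of observing `y` given `x` is

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
  \frac{(x+y)!}{x!\,y!}\;
  \frac{1}{\bigl(1 + N_2/N_1\bigr)^{x+y+1}}$$

This is the classical Bayesian tag-sampling comparison for SAGE-style
count data. It is, term for term, the negative-binomial pmf with size
`x + 1` and success probability `N1/(N1+N2)` — a fact the test suite
exploits as an independent cross-check (`stats::pnbinom`) against the
package's own log-gamma implementation, which is the route actually
used so the statistic stays finite for counts up to $10^7$.

The two-tailed p-value accumulates `q = sum(p(y'|x), y' = 0..y)` and
doubles the smaller tail: `p = 2q` when `q <= 0.5`, else `p = 2(1-q)`.
Three numerical decisions:

* `q` exactly 0.5 yields `p = 1` — the "larger than" branch is strict.
* `p` is clipped to `[0, 1]`, because doubling can exceed 1 when `y`
  sits at the distribution's mode.
* When both counts are zero the comparison is vacuous: `p = 1`, call
  `equal`.

A useful and non-obvious property, verified exactly in the tests: the
two-tailed p is symmetric under swapping the samples,
`p(x, y, N1, N2) = p(y, x, N2, N1)`.

Counts are normalized to *per 15 million clean reads*
(`count / N * 15e6`) before the ratio is formed. A tag is called **up**
when `log2(treatment/control) > 1` and `p < 0.05`, **down** when the
log-ratio is below −1 at the same p cutoff, otherwise **equal**. Both
thresholds are strict inequalities and configurable. The raw p-value
drives the calls — this mirrors the single-library design the method
was built for — but a Benjamini–Hochberg column is emitted alongside
for transparency.

**Zeros.** When one normalized value is zero the log-ratio is undefined;
half a read (`0.5/N * 15e6`) is substituted *for the ratio only*. The
p-value always uses the true counts. A half-read pseudocount is the
smallest quantity distinguishable from a miss in count data and keeps
zero-count calls monotone in the non-zero count.

**Fold-change percents.** Microarray-style signal tables are reproduced
with `round(100 * treatment/control)`, halves away from zero. Published
tables of this kind are often computed from unrounded intensities, so
only cells that are arithmetically consistent with their printed
signals are used as worked examples; the inconsistent ones cannot be
reproduced from the printed inputs by any rounding rule.

## Annotation hierarchy

Tags map to the genome by exact search on both strands, all positions
kept, no mismatches — at a 50 kb mini-genome scale an index-free
Aho-Corasick pass (`Biostrings::matchPDict` with a trusted band over
variable tag lengths) is exact and fast, and a brute-force substring
scan serves as the oracle in tests. A tag supports a feature when its
interval is fully contained in the feature's. One category per tag is
chosen by the fixed priority GenBank structural RNAs > Rfam > known
miRNA > repeat > exon > intron > siRNA, with unannotated as the
fallback. Design choices:

* *Antisense* means the tag matches the reverse complement of the
  annotated transcript strand; exon and intron categories carry the
  sense/antisense split, with sense preferred for the single assignment
  when both exist at the same priority.
* Ties within a priority level resolve to the lexicographically
  smallest feature id (byte order, locale-independent) — determinism
  over biological meaning, which the tie does not carry.
* Multi-position tags are not count-split: the whole count follows the
  single assigned category, since the hierarchy is a rule about
  categories, not loci.
* Coordinates are 1-based closed intervals throughout, the native
  convention of IRanges/GenomicRanges and of GFF3 output; using one
  convention internally and externally removes a whole class of
  off-by-one errors at the cost of slightly clumsier interval
  arithmetic.

## Target-prediction rules

Duplexes are ungapped and antiparallel: miRNA position `i` (counted
from the miRNA 5' end, the plant-rule convention) pairs with site
position `L−i+1`. Six rules gate a site: (1) at most 4 mismatches,
G-U wobbles not counted; (2) no adjacent mismatch pair within positions
2–12; (3) no run of three or more mismatches anywhere; (4) no mismatch
at positions 10–11, the slicing site; (5) a 5'-region score over
positions 1–12 of at most 2.5, a mismatch costing 1 and a wobble 0.5;
(6) duplex energy at least 75% of the same miRNA's perfect-duplex
energy.

Rule 3's phrase "no more than two adjacent mismatches" is ambiguous
between *runs of ≤ 2* and *≤ 2 adjacency events*; it is implemented as
"no run of 3+ consecutive mismatches", the reading that composes
sensibly with rule 2, and flagged here deliberately.

The energy model is a stand-in: per-pair constants (GC −3, AU −2,
GU −1, mismatch 0) instead of a nearest-neighbour thermodynamic table.
Rule 6 is a *ratio* against the perfect duplex of the same miRNA, which
largely cancels the absolute scale; the pair-energy table is a single
pluggable argument (`pair_energy`) for anyone wanting calibrated
values. G-U wobbles count 0.5 only in rule 5's positional score — they
are never "mismatches" for rules 1–4, which is how the weighting is
attached in the plant literature.

## Novel-miRNA hairpin screen

Unannotated tags are screened for precursor evidence in a 250-nt
genomic window centred on each mapping position (every position of a
multi-locus tag is screened separately). The folder is deliberately
*not* a thermodynamic engine: candidate folds are enumerated over a
grid of loop starts and loop lengths (15–33 nt in steps of 3), each arm
pair scored by ungapped antiparallel pairing, and the stem truncated at
the best-scoring extension prefix under a per-mismatch penalty of +2 —
the maximal-scoring-segment idea, which stops arms where pairing stops
paying. The fold with the lowest penalized score wins. Acceptance then
requires the mature wholly on one arm, ≥ 17 of its 21 positions paired
(G-U allowed) against the star arm, a loop of ≥ 15 nt, and fold energy
≤ −25 on the stand-in scale. All four thresholds are exposed as
arguments with these defaults.

The mature-pairing requirement is the discriminative one: in shuffled
windows the chance of the best fold pairing ≥ 17/21 positions of a
fixed 21-mer is far below 5%, which the test suite verifies empirically
on 40 shuffles. Candidates are named `<tissue>_miRNA%04d_<arm>` in
descending order of summed count (ties: byte-order sequence), and the
reported set is gated at a summed count strictly above 100; the
count threshold is interpreted as summed across the tissue's libraries,
a documented choice where per-library counting would also be
defensible.

## tasiRNA phasing and the network

Only 21-nt tags enter the TAS analysis; they are matched perfectly and
sense-strand-only against each TAS cDNA, since phased products are
templated 5'→3' from the cleaved transcript. The phase register of a
read is `(start − cleavage_position) mod 21`, with the read starting
exactly at the cleavage site in register 0 — the canonical phasing
convention; the alternative anchor (transcript position 1) differs only
by a constant rotation of the 21 bins. Differential testing keeps
sequences with more than 10 reads in the better-measured of the two
libraries (a strict inequality, so exactly 10 is excluded), then
delegates to the core classifier unchanged.

The network has typed nodes (sRNA, TAS gene, MIR gene, PPR/TPR target)
and typed edges: `generated_from` (backed by a perfect-match mapping),
`targets` (backed by a six-rule-passing duplex), and `initiates` (the
initiator miRNA to each locus it cleaves; the initiator also connects
to its MIR gene). Every edge is re-derivable from its evidence, which
the tests check by reconstruction. Export is SIF and GraphML via
igraph — both load directly in Cytoscape.

## NAT-siRNA counting

Region membership is *full containment* of the read's mapped interval —
for 18–30 nt reads against multi-hundred-nt regions, containment versus
overlap changes only boundary reads and makes the OL ≤ WL invariant
exact. Orientation is the strand whose sequence the read matches.
Cis-pair OL counts are tested (orientations pooled, per-orientation
columns retained, since the production model involves both strands);
trans pairs count their two complementary segments and sum — note that
a read inside one segment necessarily also matches the other in the
opposite orientation, so trans OL counts come in matched pairs by
construction. Pairs called non-equal in the same direction against both
treatment lines make the "altered in both" set.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the rest of the package is exercised under:

* ~50 kb genome containing 8 known miRNA hairpins, 2 unannotated
  hairpins (the planted novel candidates), structural RNAs, 2 repeats,
  2 siRNA loci, 3 exon/intron genes, 4 TAS loci (cleavage at position
  100 of a 400-nt cDNA, with a perfect initiator site spanning it), 3
  cis NAT pairs (600 + 600 nt genes overlapping by 200) and 1 trans
  pair (150-nt complementary segments).
* 20 000 reads per library across eight libraries (leaf/root ×
  WT, *pap2*, OE7, OE21). Insert lengths for classes without a fixed
  biological size are drawn from weights peaked at 21 and 24 nt;
  miRNA/TAS reads are fixed at 21 nt, repeat- and siRNA-locus reads at
  24 nt, and the tRNA 5' fragment at 19 nt with a root weight of 0.30
  versus 0.05 in leaf — reproducing the two major peaks, the
  root-specific 19-nt peak, and the elevated root tRNA class fraction.
* OE conditions multiply designated sources: miR172/miR319/miR173 ×4,
  miR391 ×0.25, all four TAS loci ×4 and one cis NAT pair ×10 in leaf;
  a reduced set in root. Multipliers scale a source's weight in one
  global multinomial over sources, so at fixed library size the whole
  composition renormalizes — exactly as in real sequencing, where
  depth is fixed and spikes dilute everything else. The *effective*
  fold change of a 4× spike is therefore 4/Z with Z ≈ 1.4 the
  renormalization of the spiked condition; spike-recovery tests use
  composition-cancelling ratios against an unspiked source where the
  nominal factor is asserted.
* Phasing fidelity (default 0.9) is the fraction of TAS reads placed
  exactly in register; the rest start uniformly on the cDNA. At
  fidelity 1.0 every mapped 21-nt TAS read is in register 0, which
  works because background "genomic" reads are sampled from intergenic
  space only.
* Reads are emitted as insert + complete 3' adapter (no 5' remnant), so
  trimming is exactly invertible; 2% of reads are adapter-free decoys
  that the trimmer must discard; a per-read substitution noise rate is
  available and defaults to 0. Adapter sequences are arbitrary fixed
  strings declared in the config, as the real protocol's adapters are
  not part of the model.
* Everything derives from one integer seed (per-library streams are
  deterministic functions of it), and all internal ordering uses
  byte-order sorting, so outputs are bit-identical across runs and
  locales.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: sequencing error profiles and
quality-score structure, RNA degradation and ligation bias,
expression-level heterogeneity beyond the configured multipliers,
mismatch-tolerant mapping (real genomes need it; the exact matcher here
does not), and genome-scale repeat ambiguity. The pipeline's
correctness claims are about its defined operations, not about
robustness to those artefacts.

## Problem sizes and determinism

The bundled test suite runs the full stack on 8 000-read libraries (a
shared fixture) plus a 4-library end-to-end pipeline at 5 000 reads;
the acceptance script uses the default eight 20 000-read libraries.
These sizes were chosen so every statistical assertion has comfortable
counts (spiked miRNA genes exceed 50 reads per library) while a
complete run stays in the tens of seconds. All RNG flows from explicit
seeds; no test depends on the execution locale or environment.

## Known limitations

* Single libraries per condition: the statistic models sampling noise
  only, not biological dispersion. With replicates, a
  negative-binomial framework (DESeq2/edgeR) is the right tool; this
  package implements the unreplicated tag-comparison regime faithfully,
  including its permissiveness at large counts.
* The hairpin screen and duplex energies are calibrated stand-ins, not
  thermodynamics; their thresholds are honest about being screen
  parameters rather than free energies.
* Exact matching only. Tags with any sequencing error fail to map and
  fall into the unannotated class; at the default noise rate of 0 this
  is moot, and at realistic rates it is a known bias the generator can
  expose (`noise_rate > 0`) but the mapper does not correct.
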