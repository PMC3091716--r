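---
title: "Discovering cis-regulatory modules from orthologous non-coding DNA"
author: "crmminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cis-regulatory modules from orthologous non-coding DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcription factors (TFs) rarely act alone: their binding sites (TFBSs)
cluster in short stretches of non-coding DNA — cis-regulatory modules
(CRMs) — and the same combinations of binding motifs recur across the
regulatory regions of many genes. `crmminer` predicts both objects around
human genes, using only sequence: conservation against rodent orthologs
selects candidate regions, position weight matrices (PWMs) call candidate
TFBSs inside the conserved parts, and frequent-itemset mining finds motif
combinations that co-occur in significantly many regions. A motif module
is a set of two or more motifs whose TFBSs co-occur in many ~1 kb regions;
the regions supporting a module are its CRMs.

The method deliberately avoids multiple-genome alignments. Regulatory
regions tolerate rearrangement of their internal architecture, so two
orthologous regulatory regions may share conserved binding sites without
sharing a collinear alignment. The conservation measure below is built on
that observation.

## Non-coding territories

For each ortholog group (one human gene, one or two rodent genes) the
non-coding territory of a gene is: the upstream sequence from the nearest
coding-sequence boundary of the 5' neighbouring gene to the translational
start; the downstream sequence from the stop codon to the nearest coding
boundary of the 3' neighbour; and the gene's own introns. Because the
boundaries are codons rather than transcript ends, untranslated regions
fall inside the territory. Coordinates are 0-based half-open everywhere
internally (BED's native convention; GFF3 input is converted on read),
which keeps interval arithmetic free of off-by-one adjustments. Neighbour
genes of either strand count; a neighbour whose coding span overlaps the
focal gene truncates that flank to empty rather than producing a negative
interval — the annotation cases this handles (nested and overlapping gene
models) have no uniquely correct answer, and an empty flank is the
conservative one.

## Conserved segments: seed-and-extend alignment

Orthologous territories are aligned with a seed-and-extend local aligner
in the CHAOS/BLAST family. Exact shared words of 6 bp (no degenerate
matches) seed the search — TFBSs are at least about 6 bp, and functional
6-mers are frequently perfectly conserved between human and rodent — and
each seed is extended into a gapped local alignment until the running
score drops a fixed x-drop below the running maximum. Retained alignments
are the *conserved segments*.

Scoring defaults, all configurable through `align_params()`: match +1,
mismatch −1, gap open −3, gap extension −0.5 per column, x-drop 10, and a
minimum retained score of 12 (two chained clean words). The extension is
two-phase, as in the BLAST family: a cheap ungapped x-drop extension runs
along the seed diagonal first, and the full gapped dynamic program runs
only when the ungapped score already reaches the retention threshold.
Because the gapped optimum is never below the ungapped one, this loses
only alignments that cannot reach the retention score without gaps — with
indel-free conserved elements, essentially nothing — while making
genome-scale simulation affordable. `extend_seed()`, the single-seed
entry point, always runs the full gapped extension.

Each retained segment stores the column counts of its optimal path
(matches, mismatches, gap opens, gap columns), so its score can be
re-derived exactly — a self-consistency check the test suite exercises.
Overlapping segments are resolved greedily on the human sequence by score
(ties: smaller start, forward strand), so retained segments are mutually
disjoint on the human side. Ortholog minus-strand alignments are kept and
flagged; inversions are real.

N bases never seed, never match, and make PWM windows unscorable.

## Discontiguous similarity and blocks

The similarity of a 1 kb human window $R$ and an ortholog window $R'$ is

$$S(R, R') = \sum_{\text{segments } s \,\subseteq\, (R, R')} \text{score}(s),$$

the sum of the alignment scores of the conserved segments falling
entirely inside both windows. Divergent spacer between segments
contributes nothing, so a region conserved in scattered pieces scores
exactly as well as one conserved in a single run of the same total length
— the property that makes the measure robust to binding-site shuffling
within a module. The conservation of $R$ is

$$C(R) = \tfrac12\left(S(R, R') + S(R, R'')\right)$$

maximised over all 1 kb ortholog windows $R'$ (mouse) and $R''$ (rat);
with a single rodent ortholog, $C(R)$ is that species' best $S$. A
species whose ortholog aligned nothing contributes 0 and is still
averaged — the literal reading of the formula. The maximisation is a
sweep over segment endpoints, not a re-alignment, and the test suite pins
it to a brute-force scan over every candidate window start.

Candidate windows are anchored at conserved segment starts. Windows from
all ortholog groups are pooled, and the cutoff is the smallest score that
at most 5% of windows exceed (an empirical quantile without
interpolation; `cutoff_quantile` configurable). Pooling, rather than a
per-gene cutoff, is the reading under which "at most 5%" is a statement
about the genome as a whole. Windows truncated by a territory boundary
are scored as-is and flagged; excluding them would silently drop short
territories. Passing windows are merged by interval union and each merged
interval is trimmed on its 3' side back to the last base covered by a
segment — the 5' side is already anchored at a segment start. The result
is the set of *blocks*: disjoint, at most about 1 kb, each a CRM
candidate.

One geometric consequence of requiring segments to fall entirely inside
windows: a segment longer than the window length contributes to no window
at all. With the default x-drop this arises only when two conserved
elements lie close enough to be chained by the extension; it is the
reason the synthetic generator keeps its background elements at a
distance from the planted islands.

## Motif scanning

Motif libraries are read from TRANSFAC flat files or MEME minimal format
into 4 × width count matrices. Scores are natural-log odds against a
uniform background with a pseudocount of 0.01 of the column total
(background composition and pseudocount configurable; the log base is
recorded in the object). Both strands are scanned and the strand is kept
for the strand-preference statistics.

Each motif's score cutoff is calibrated so that a random background
position scores above it with probability below $10^{-4}$: the cutoff is
the empirical $1 - 10^{-4}$ quantile of the scores of every motif-width
window, both strands, pooled over a library of random non-coding 1 kb
regions (10,000 by default). The per-position reading — rather than
per-region — keeps the cutoff independent of region length. Note that for
very sharp matrices the score distribution is a coarse ladder and the
achieved hit rate can sit well below the target (the quantile falls
between two score levels); calibration guarantees "below", not "equal".
TFBS candidates are windows inside the conserved segments of blocks
scoring strictly above the cutoff; overlapping hits of one motif are all
kept.

## Mining motif modules

Each block becomes a transaction whose items are the motifs with at least
one TFBS candidate in it (presence/absence; multiplicity ignored).
Blocks with no hits stay in the universe — they count in $B$ below. An
FP-tree (frequency-ordered prefix tree with conditional pattern-base
recursion) enumerates every motif combination of size ≥ 2 with support of
at least 100 blocks (the `min_support` default; smaller values suit
desk-scale datasets). Two TRANSFAC matrices for the same factor are
distinct items.

Significance uses a Poisson clump approximation: under independence the
number of blocks containing all motifs of a combination has rate

$$\lambda = B \prod_i \frac{b_i}{B},$$

with $b_i$ the number of blocks containing motif $i$, and the p-value is
the upper Poisson tail at the observed support. Because overlapping
windows were merged into disjoint blocks upstream, clumping of
overlapping occurrences is already absorbed; the Poisson form is the
block-level limit, accurate when the $b_i/B$ are small. The test suite
bounds the approximation against a label-shuffle Monte-Carlo null in that
sparse regime ($\lambda \in [1, 20]$, frequencies ≤ 4.5% of $B$); at
frequencies of 15% and above the fixed-marginal null is visibly narrower
than Poisson and the analytic tail is conservative in the upper tail.
Combinations with a Bonferroni-corrected p-value below 0.05 — corrected
over the combinations actually evaluated, i.e. the frequent ones — are
emitted as motif modules, and their supporting blocks as CRMs.

## Downstream statistics

**Target genes.** The gene nearest a CRM (distance between the CRM
interval and the gene's coding span, ties toward the 5'-most gene and
logged) is its target; the CRM is labelled upstream, downstream or
intronic by the territory region holding its midpoint, and its signed
distance to the transcription start site is recorded (positive =
upstream).

**Gene-set overlap.** With $N$ genes in the annotation, $M$ in a set, $n$
module targets and $m$ in both, the p-value is the hypergeometric upper
tail $P(X \ge m)$, computed in log space; q-values are Benjamini–Hochberg
across all module–set pairs. The printed form of the distribution in the
source material normalises by $\binom{N}{M}$, which does not sum to one;
the standard $\binom{N}{n}$ normalisation is implemented.

**Order, strand, distance.** For a motif pair in a module, the 5'-most
site of each motif per CRM (ties by score) is the representative. The
order test counts the CRMs with motif A 5' of motif B and applies a
fair-coin binomial tail — upper if $m > n/2$, lower otherwise. One
caveat, verified by simulation: because the tail is chosen from the data,
the two directions together reject at up to ~6.5% at a nominal 5% (n =
50); each direction alone holds its level. The strand test is identical
with "same strand" as the success. Distances (edge-to-edge gaps, 0 when
sites overlap) are binned at 50 bp from zero to the largest observed
distance; the Poisson rate is the mean count per bin, each bin gets an
upper-tail p-value, Bonferroni over bins (BH selectable), and the
preferred range is the maximal run of adjacent significant bins. Location
preference tests each module's label counts against the pooled label
proportions of all CRMs (binomial upper tail, Bonferroni over the three
labels). The exposed defaults follow the corrections used for each
statistic (order: BH at 0.01; distance and location: Bonferroni at 0.05).

## The synthetic test bed

`simulate_dataset()` generates the study conditions every stage is tested
under. Each of 1000 ortholog groups (human, mouse, rat) is a 3 kb
non-coding territory followed by a short single-exon gene on its own
contig. Inside each territory:

* one **island** of 850 bp, copied to each rodent with 5% substitution
  and no indels — the strongly conserved element that should become a
  block;
* 24 **background conserved elements** of 25 bp at 10% substitution —
  stand-ins for the ancient repeats and miscellaneous constrained
  elements that dominate real conserved non-coding sequence. They exist
  so that the pooled 5% cutoff has a large population of weakly conserved
  windows to rank against; without them nearly every anchored window
  would be an island window and the 95% quantile would cut into the
  islands themselves. They are kept out of the 1 kb capture zone upstream
  of each island so that no background-anchored window contains a whole
  island, and at least 60 bp from its ends so that x-drop extension
  cannot chain them into a segment longer than a window;
* **spacer** drawn independently per species. Neutral mammalian DNA at
  human–rodent distance is mostly unalignable, and independent sequence
  is the cleanest model of that; `evolve_pair()` also supports a diverged
  mode (default 0.4 substitutions with geometric indels, mean 3 bp) used
  to test the aligner's divergence behaviour. At ±1 match/mismatch
  scoring, 50% identity is the zero-drift point of the extension walk, so
  spacer only becomes effectively unalignable above ~60% substitution —
  the aligner-recovery tests use 0.65.

The motif library holds 12 matrices of width 8–10 with per-column
dominant-base probability 0.97–0.99, drawn with a rejection step that
keeps every pair of consensus sequences at Hamming distance ≥ 3 over any
offset and strand: two near-identical matrices share sites, their items
co-occur through sequence identity rather than regulation, and the
independence null of the module test is violated by construction — the
synthetic library models a curated, non-redundant collection. One module of three motifs is
planted into the islands of 120 groups; each motif's total planted
frequency is held at 0.15 of the groups by adding individual sites to
non-module islands. Planted sites are consensus sites: with equal minor
counts the log-odds score ladder is discrete, a single off-consensus base
costs ~4 nats, and the calibrated cutoff often lands exactly on the
one-off level, so the consensus is the only site guaranteed to be called
— which is also the biologically sensible model of a functional
high-affinity site for matrices this sharp.

What the generator does **not** emulate: phylogenetic substitution-rate
structure (no transition/transversion bias, no CpG effects, no rate
variation), motif turnover between species, overlapping or nested genes,
alternative transcripts, and low-information motifs whose sites cannot be
separated from background at the calibrated cutoff. Passing tests
therefore show the machinery is correct under its stated model, not that
real TRANSFAC matrices on real genomes would behave as cleanly.

## Problem sizes and numerical choices

The test suite runs the default conditions (1000 groups) once for
planted-module recovery and twenty times with planting disabled for the
false-discovery check; smaller configurations (30–200 groups, planted
fraction kept at 12%) exercise the stages individually. Calibration
backgrounds in tests use 1000–2500 regions, enough to place the
$10^{-4}$ quantile with a few percent relative error; the pipeline
default remains 10,000. Determinism is end-to-end: every stochastic step
derives from the configuration seed, restoring the caller's RNG state
afterwards, and identical seeds give byte-identical datasets and outputs.

Degenerate inputs are handled explicitly: `compute_cutoff()` refuses
fewer than 20 windows; windows shorter than 1 kb are flagged, not
dropped; an all-equal score vector yields that value as the cutoff with
nothing above it; empty itemsets, empty windows and hit-less blocks flow
through as zeros or empty results rather than errors; `clump_pvalue()`
clamps at the smallest positive double rather than returning zero.

## Known limitations

* The clump p-value is an independence approximation; at high per-motif
  frequencies it is conservative near the centre and should not be read
  as an exact tail probability.
* The order/strand test's data-directed tail makes it mildly
  anti-conservative when both directions are of interest (see above).
* The conservation cutoff is a pooled quantile: a dataset consisting
  almost entirely of strongly conserved windows would push the cutoff
  into the conserved population. This is a property of the method, not of
  the implementation; the generator documents the anchor budget needed to
  avoid it.
* Segments longer than the window length contribute to no window (see
  the geometry note above).
* The aligner is not a full CHAOS replacement: no degenerate seed words,
  no rescoring with substitution matrices, no translated alignment.
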