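---
title: "Methods: comparative CRISPR-Cas characterization on planted-truth panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative CRISPR-Cas characterization on planted-truth panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprcomb)
```

## The problem

Bacterial genomes defend against phage by storing short sequences
("spacers") from past invaders in CRISPR arrays: runs of near-identical
direct repeats separated by the spacers. In acetic-acid-bacteria symbionts
of honey bees and similar clades, two system types co-occur: type I-E, whose
28-29 bp repeat folds into a hairpin topped by a variable 4-nt tetraloop,
and type II-C, with short arrays near a tracrRNA-like element. Arrays occur
both "canonical" (adjacent to the Cas operon) and "orphan" (far from any Cas
gene). Comparative questions — which strains share spacers, which spacers
point at prophages, whether orphan arrays are larger — require a pipeline
that detects arrays, types repeats, labels context, recovers spacers from
unassembled community reads, matches spacers across genomes, attributes
matches to prophage/genic/intergenic space, and quantifies test power.
`crisprcomb` implements that pipeline with a synthetic-data generator whose
planted ground truth makes every stage testable.

## Synthetic panels: what they emulate, and what they do not

`build_strain_panel()` turns declarative plans into multi-contig genomes.
Planted features (arrays, Cas operons, prophages, decoy genes) are placed
without overlap and with at least 700 bp between features so the 500 bp
canonical/orphan rule is never ambiguous. Canonical arrays sit 100-400 bp
downstream of a planted operon (I-E: cas3-cas8e-cas11-cas7-cas5-cas6e-cas1-
cas2; II-C: cas9-cas1-cas2 with a 24 bp reverse-complement anti-repeat
upstream, the tracrRNA-like element). Background sequence is i.i.d. uniform
ACGT. Prophage-sourced spacers copy a random subinterval of the planted
prophage on a random strand, optionally mutated at a stated per-base
substitution rate; shared spacers copy a donor strain's spacer verbatim.
`simulate_reads()` draws read pairs from community genomes by relative
abundance plus a host genome at a set fraction; fragments are uniform,
strands random, and at error rate 0 every read is an exact substring (or
reverse complement) of its source. The host decoy is random sequence
checked to share no 31-mer with the community.

One integer seed drives everything, in a fixed draw order (prophage
sequences, then spacers in plan order, then per-contig placement, then
reads), so identical plans and seed give byte-identical outputs.

What the generator does **not** emulate: phylogenetic divergence between
strains, indel sequencing errors (substitutions only), quality-score
structure (constant Phred), repeat degeneracy within an array, and
compositional bias. Passing tests on these panels therefore demonstrate
algorithmic correctness on clean, identifiable inputs — not robustness to
degraded real assemblies, where repeat copies mutate and boundaries blur.

Default dimensions were chosen once as genre-typical for these systems:
29 bp repeats, 32 bp spacers, I-E arrays roughly 8-30 spacers, II-C arrays
small (about 1-12), contigs tens of kb. The acceptance-style panels used in
the test suite plant II-C arrays with 7-12 spacers and I-E with 12-30: with
m repeat copies, the chance that a boundary column beyond the true repeat
is unanimously identical across copies is 4^-(m-1), so m >= 8 makes planted
boundaries identifiable in practice while staying inside the "small II-C
array" regime. Sizes are plan-driven; nothing is hard-coded.

## Array detection

Detection is seed-and-extend. Exact `seed_k`-mer (default 23) recurrences
at spacer-compatible spacings (repeat+spacer length bounds, defaults 19-38
and 19-48 bp, minimum 3 copies) seed candidates. Seed occurrences are
extended to repeat boundaries column by column; a column is included while
at least `boundary_agree` of the copies agree on the majority base. The
default is 1.0 — unanimity among copies covering the column. A lower value
(e.g. 0.75) tolerates degraded repeats but, with few copies, lets chance
agreement among i.i.d. flanking bases drag the boundary into the spacers
(with 4 copies, a 0.75 threshold over-extends a side about 20% of the
time), which is why unanimity is the default for clean assemblies.

Candidates are then extended outward by whole repeat units while a flanking
window stays within `max_repeat_edits` (default 3) of the consensus, and
boundaries are re-refined over the final copy set under the same agreement
rule — this guards against seeds that straddle the repeat/spacer junction
(a 23-mer spanning the repeat end plus a shared first spacer base recurs
whenever consecutive spacers start with the same base). Two quality filters
follow: a tandem-repeat guard (reject when mean pairwise spacer identity
exceeds 0.6, identity = 1 - edit distance / longer length) and a
repeat-degeneracy guard (reject when any copy exceeds `max_repeat_edits`
from consensus). Candidates from different seeds that converge on
overlapping intervals are deduplicated by most copies, then fewest total
edits to consensus, then leftmost start. `N` never matches and candidates
spanning `N` are dropped. Every reported array satisfies the reconstruction
invariant: repeats and spacers concatenate to the contig substring.

## Repeat typing and hairpins

`classify_repeats()` takes the nearest catalog entry under Levenshtein
distance (base R `adist`), minimized over both strands, ties by distance
then catalog order; a repeat is accepted as CRISPR at four or fewer edits.
The probability-score pathway of ML-based classifiers is deliberately
absent: it is not reproducible from a fixed catalog, and the edit rule is
the stated acceptance rule. The shipped catalog holds representative
I-E and II-C repeats matching the generator defaults; users supply their
own TSV for real clades.

`fold_hairpin()` searches all exact reverse-complement arm pairs (no G-U
wobble, no bulges) with the 5' arm left of the 3' arm, maximizing stem
length with ties broken by smallest loop then leftmost arm. Loops shorter
than `min_loop = 3` nt are excluded — the physical minimum for a hairpin
turn. Without that constraint the maximal-stem criterion degenerates: any
loop whose first and last bases pair would be absorbed into the stem,
leaving a 2-nt loop no real hairpin can close, and planted tetraloops whose
edges happen to be complementary (such as TTCA) would be misread. The
tetraloop census tallies I-E arrays per strain and context by their folded
loop; non-folding repeats count under loop `"NA"`.

## Context labeling

The gap between an array and a Cas gene is the number of bases strictly
between the intervals, 0 for overlap or abutment (bedtools-closest
semantics, ties to the leftmost feature). Canonical means gap <= 500 bp to
any Cas gene on the same contig; orphan means a larger gap or a Cas-free
contig; the boundary is sharp (500 canonical, 501 orphan). Distance is
measured to any Cas gene, not only same-type operons, because operon typing
from fragmented annotations is unreliable; a type-restricted run can be
had by pre-filtering the gene table.

## Read-space spacer recovery

Host-derived pairs are removed first, keeping a pair only when *neither*
mate maps to the host — the keep-both-unmapped flag semantics; a mapped
mate in either position excludes the pair. Mapping is a desk-scale
surrogate: a mate maps when it shares one exact 31-mer with either host
strand. This is exact for substitution-free synthetic reads and is
documented as a swappable contract, not an aligner.

Per read, a 23-mer recurring at least 26 bp downstream seeds a repeat;
k-mers co-occurring within reads are grouped (union-find, strand-canonical
form), and the group's repeat boundaries are refined by column agreement
(default 0.75) across all anchor instances in all reads — group-level
evidence is plentiful, unlike the per-contig case, so the lower threshold
is appropriate. Spacers are the sequences between consecutive exact
occurrences of the consensus within a read; flanking stretches at read
ends are partial spacers. Filters: spacers shorter than 16 bp are
discarded; stretches longer than `max_spacer_len` (48 bp) are treated as
non-spacer flank; groups need at least 2 repeat instances and 2 distinct
spacers. `merge_groups()` unifies groups with identical or
reverse-complement consensus (everything is stored on the lexicographically
smaller strand), removes exact duplicates, absorbs partials that are
substrings (either strand) of a full spacer in the group, and keeps sample
provenance per spacer. `rescue_known_repeats()` sweeps reads for exact
copies of known repeats and contributes their flanks under the same
filters — the recovery step for repeat families the de novo pass misses.

## Spacer matching and sharing

Matching is an exhaustive all-offsets scan on both strands: identity is
matching positions divided by spacer length (ungapped), and every placement
at or above `min_identity` (default 0.80) is reported, so results are a
superset of any seeded heuristic aligner's hit set at the same definition.
The denominator choice (spacer length, not alignment length) is the
conservative reading of "% matching nucleotides" and is stated openly. A
gapped mode aligns the spacer end-to-end against local windows of length
L±2 (identity `(L - edits)/L`); it is exhaustive but slower and meant for
short references. Self-hits — placements overlapping the query's own source
array interval — are removed. Deduplication collapses exact and
reverse-complement duplicates within a genome to the lexicographic
canonical strand. The sharing matrix counts, per ordered strain pair, query
spacers with at least one qualifying placement among the partner's unique
spacers; both directions are emitted because directional and symmetrized
counts differ under lenient identity.

## Prophage and genic attribution

Match intervals are padded by 32 bp per side (clipped at contig bounds) to
buffer annotation and strand error; a padded match counts toward every
prophage region it overlaps by at least 1 bp, with questionable and
incomplete regions pooled against intact. Mean identity per
(source, target, completeness class) uses the unpadded match identity —
padding affects attribution only. Matches clear of prophage regions are
dropped if they overlap a CRISPR array (self), then split genic/intergenic
by interval-only intersection with `type == "gene"` features (strand
ignored). The order — prophage first, then subtract, then genes — makes the
categories a partition; a padded match may legitimately count toward two
adjacent regions, and synthetic panels space regions at least 700 bp apart
so the per-region sum equals the attributed-match count there. Edge tables
(one file for intact, one for incomplete/questionable, deterministic row
order) carry source, target, count, and mean identity.

## Statistics and power

`wmw_test()` reports W as the number of (x, y) pairs with x > y plus 1/2
per tie; the two-sided p-value comes from `stats::wilcox.test`, exact when
n1 + n2 <= 12 with no ties (which equals full label-permutation
enumeration, verified in the tests), otherwise the normal approximation
with tie and continuity correction; fully tied zero-variance samples
return p = 1. `wmw_power()` draws `reps` replicate pairs from parametric
specifications given in the printed-call string form (`"lnorm(meanlog,
sdlog)"`, `"exp(rate)"`), runs the test at `alpha`, and returns the
rejection proportion, flagging (not enforcing) the conventional 80%
sufficiency bar. The default `reps = 10000` puts the Monte-Carlo standard
error near half a percentage point, comfortably inside a ±2-point
tolerance; one seed fixes the whole simulation. Distribution fitting is
out of scope: fitted parameters are inputs, since that is what a power
calculation consumes.

## Numerical and design choices, in brief

* Coordinates are 0-based half-open everywhere internally; GFF3 converts at
  the boundary (rtracklayer), the prophage BED variant carries its
  completeness label in column 7.
* All tie-breaks are deterministic and stated: lexicographic base in
  consensus columns, smallest loop then leftmost arm in hairpins, leftmost
  feature in nearest-gap ties, catalog order in typing, most-copies /
  fewest-edits / leftmost in detection dedupe.
* Degenerate inputs: empty catalogs, empty samples, unpaired mates, plans
  that do not fit their contig, and out-of-range identity thresholds are
  rejected with descriptive errors; empty inputs otherwise yield typed
  empty tibbles.
* Problem sizes in the test suite (20-strain panels of 30-60 kb contigs, a
  24 kb community at 20x coverage, 200 spacers against 50 kb, 100 random
  interval fixtures, 10,000 power replicates) were chosen to exercise every
  contract at full strength while keeping a laptop-scale single-CPU run.

## Known limitations

Detection assumes equal-length repeat copies (no indel degeneracy) and
loses arrays whose copy count falls below `min_repeats`; read-space
recovery reports 1 bp-truncated spacers when a group's spacer diversity is
so low that a boundary column agrees by chance; the host filter is exact
k-mer membership, not an aligner, and will not absorb host reads carrying
sequencing errors; the hairpin model has no wobble pairs or bulges; and the
Wilcoxon power simulation trusts the supplied parametric fits — data poorly
described by lognormal or exponential families make the resulting power
figures nominal rather than realistic.
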