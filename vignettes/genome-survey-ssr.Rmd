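---
title: "Genome survey characterization and SSR marker mining: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome survey characterization and SSR marker mining: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gssr)
library(dplyr)
```

Low-coverage ("genome survey") shotgun sequencing is a cheap way to get a
first look at a genome nobody has assembled: its GC content, how much of it
is recognizable repeat or gene sequence, and — the main practical payoff —
thousands of microsatellite (SSR) marker candidates with ready-made PCR
primers. gssr implements that survey pipeline end to end for paired-end
short-insert libraries, together with a flow-cytometry module that turns
fluorescence peak ratios into genome sizes, and a synthetic-data generator
that makes every stage testable without touching real data.

This vignette documents the models and procedures, the parameters that
matter, and the numerical choices made where a published description left
the design open.

## The fragment-reconstruction model

Libraries are assumed to be sheared to short inserts (target mean around
180 bases) and sequenced as 101-base paired ends, so that the two mates of
most fragments overlap in the middle. Processing order is fixed:

1. **Trim.** Each mate is clipped at the leftmost adapter occurrence
   (allowing up to 2 mismatches over at least 10 aligned bases), then
   truncated at the start of the first 4-base sliding window whose mean
   Phred quality falls below 15. A pair in which either mate ends shorter
   than 36 bases is discarded whole. All counts are tallied so that every
   input pair lands in exactly one terminal category.
2. **Artifact filter.** Pairs whose mates end in *identical* (same-strand)
   last-30-base tails indicate inserts read in an unexpected orientation
   (short inserts or ligation problems); a properly overlapping pair has
   reverse-complementary, not identical, tails. The comparison is exact
   and case-insensitive; `N` matches nothing; mates shorter than 30 bases
   cannot be evaluated and are kept but counted.
3. **Merge.** Mate 2 is reverse-complemented and slid against mate 1 over
   every overlap length from `min_overlap` (10) up to the shorter mate's
   length. The overlap with the smallest mismatch ratio wins, ties going
   to the longer overlap, and is accepted if the ratio is at most 0.25.
   Disagreeing bases take the higher-quality mate's call; exact quality
   ties are broken at random under the run seed. Pairs that do not merge
   pass both mates through as unmerged fragments — a valid outcome, since
   fragments longer than `2*read_length - min_overlap` cannot overlap
   detectably.

Two consequences of this model are worth knowing. First, a small fraction
(~0.25% in our simulations) of truly non-overlapping pairs will merge
through a chance low-mismatch overlap; this is inherent to
ratio-threshold merging. Second, when both mates end *inside* a tandem
repeat, several overlap offsets are exactly equivalent, and the merged
fragment can contract (or extend) the repeat run by a few copies. The
locus is still found, in the right place and motif class, but its copy
count is only trustworthy when a mate anchors in unique flanking
sequence.

## SSR mining

Only perfect tandem repeats of period 2, 3 and 4 are reported, under
inclusive copy-number windows chosen so that loci are long enough to be
polymorphic and short enough to genotype: 8-40 copies for dinucleotide
motifs, 7-30 for trinucleotide, 6-20 for tetranucleotide. The scanner
finds maximal runs where `seq[i] == seq[i + period]`; a run whose repeat
unit is itself a repetition of a shorter unit (homopolymers, `ATAT`)
belongs to the shorter period, so nothing is reported twice. `N` breaks
any run. The miner is validated against a brute-force per-start scanner
on a thousand random fragments.

Motifs are grouped into **canonical classes**: all cyclic rotations of a
motif and of its reverse complement describe the same locus read in a
different phase or strand, so `AG`, `GA`, `CT` and `TC` form one class,
named by its lexicographically smallest member. Enumeration gives exactly
4, 10 and 33 classes for periods 2, 3 and 4. Class tables published
elsewhere sometimes label rows by a non-minimal member (e.g. an
`ATG|TGA|GAT|CAT|ATC|TCA` row whose minimum is `ATC`); classes should be
matched by membership, not by label.

Marker-oriented filters follow: a locus needs at least 15 bases of
non-repetitive, `N`-free flank on each side (room for a primer), and two
loci separated by fewer than 15 non-SSR bases are a *compound SSR* —
both are removed, since neither can be amplified specifically. The 15-base
gap operationalizes "adjacent" and unifies the compound rule with the
flank rule.

Because low-coverage libraries sample some loci more than once,
SSR-bearing fragments are deduplicated before counting: fragments joining
by ≥95% identity over ≥50 aligned bases (best ungapped overlap alignment,
single linkage) form one cluster, represented by the longest member. This
is deduplication, not assembly — the intent is one count per genomic
locus. Both pre- and post-collapse counts are reported, since published
per-species tallies do not always say which they print.

Densities are loci per Mb of searched fragment sequence; class frequency
tables are rounded to integer percentages by largest remainder so each
period's column sums to 100.

## Content profiling

GC content and coverage are computed over merged (reconstructed)
fragments: `100*(G+C)/(A+C+G+T)` with `N` excluded from both sides, and
`coverage = fragment bases / genome size`. Mining uses all fragments
(merged plus unmerged mates); profiling fractions mirror the
"percent of reconstructed fragments" convention.

Repeat and gene content use a deliberately minimal seeded aligner rather
than an external search tool, so the package has no database dependency:
exact-word seeds located by a hash join, extended without gaps under an
x-drop rule. Nucleotide search (repeat classification against a
user-supplied library whose headers carry `#class` tags, e.g.
`rnd1#Gypsy`) seeds on 12-mers and scores +1/−2 with x-drop 12; a
fragment takes the class of its best hit scoring ≥30. Protein search
(gene-likeness) translates fragments in all six frames, breaks peptides
at stops, seeds on exact 4-mers, extends with BLOSUM62 (Biostrings' copy)
and converts scores to expectation values with the matrix's published
ungapped Karlin-Altschul parameters (λ = 0.3176, K = 0.134), E =
K·m·n·e^(−λS). A fragment is gene-like if any hit has E below 1e-5.
Reference-gene representation assigns each gene-like fragment to its
single best-scoring transcript (translated-vs-translated; ties to the
lexicographically lowest id) and reports the percent of transcripts hit
at least once.

These choices preserve the *classification logic and thresholds* of the
original tools without reproducing them bit for bit; gapped alignment is
out of scope, which slightly lowers sensitivity to diverged repeats.

## Primer design

Flanks are first masked for low complexity with a windowed triplet
statistic: in each 64-base window, `S = Σ c_t(c_t−1)/2 / 62` over the 62
overlapping triplets, and windows with `S > 2·level` are masked (level 1
by default). Random DNA scores about 0.5; a 40-base dinucleotide stretch
about 5.5; the threshold separates them cleanly. The original masking
tool's "level" semantics are not published, so the threshold scaling is
exposed as configuration.

Primer pairs are then found by exhaustive enumeration under the printed
constraint set (optimum length 20 in 18-25, no `N`s, product 100-200,
Tm 55-65 optimum 60, GC 40-60%, no homopolymer longer than 3, two
3'-terminal G/C, no overlap with masked or SSR bases). Melting
temperatures use nearest-neighbor thermodynamics (SantaLucia 1998 unified
parameters, entropic salt correction `0.368(N−1)ln[Na+]` at 50 mM
monovalent salt, 50 nM primer under the CT/4 convention) — verified to
four decimals against an independent implementation. Among all feasible
pairs the designer minimizes
`|len_L−20| + |len_R−20| + |Tm_L−60| + |Tm_R−60|`, breaking ties toward
the smaller product and then the leftmost left primer, so selection is
deterministic. A locus with a surviving pair is a PAL (potentially
amplifiable locus). Yield is strongly GC-dependent: on synthetic 35%-GC
flanks roughly one locus in five yields a primer pair, against ~90% at
50% GC — which is why AT-rich plant genomes convert only a minority of
gSSRs into PALs.

## Genome sizing from flow cytometry

Sample nuclei are co-stained with an internal standard of known DNA
content (shipped values: chicken red blood cells 2.5 pg/2C, soybean
2.45, rice 0.96, Arabidopsis 0.36). Each replicate gives
`2C = (sample peak mean / standard peak mean) × standard 2C`; replicates
are pooled with equal weights into a mean and SD. The estimate is
scale-invariant in fluorescence units. Conversion to genome length uses
the standard relation 1 pg ≈ 978 Mbp: `1n Mbp = 2C/2 × 978`, rounded to
the nearest Mbp. Published tables that print pg to two decimals
back-convert to within ±0.5% of this constant, which is the agreement the
package's tests require. Histogram modeling and peak calling are out of
scope; inputs are peak means.

## The synthetic-data generator

`make_genome()` draws an i.i.d. background at a target GC and plants
non-overlapping features recorded in a 0-based feature table: perfect
SSRs, copies of repeat templates mutated to an exact Hamming identity,
and in-frame reverse-translated protein fragments (uniform synonymous
codons) on either strand. `simulate_reads()` draws fragment lengths from
a truncated normal on `[read_length−30, 2·read_length]` (default mean
180, sd 25 — chosen so both merging and non-merging pairs occur, and so
adapter read-through never exceeds the 33-base synthetic adapter),
simulates read-through on short fragments, plants same-tail artifact
pairs at a configurable rate, applies i.i.d. substitution errors, and
emits constant Q38 qualities with an optional fraction of Q2 tails so the
trimmer has something to do. One integer seed drives every draw; output
is byte-identical across runs.

What the generator does *not* emulate: position- or GC-dependent error
and coverage bias, indels, optical duplicates, real quality decay. Tests
passing on this generator therefore demonstrate the pipeline's logic
(thresholds, bookkeeping, recall on covered loci), not its behavior on
instrument-specific noise.

Study-scale checks in the test suite use a 1 Mb genome and 20,000 read
pairs (~3.6X fragment coverage); at that depth random sampling leaves a
few percent of planted loci uncovered by any fragment with full flanks,
so recall is asserted — at 100% — over the covered loci only.

## Known limitations

* Ungapped alignment only; diverged or indel-rich repeat copies score low.
* Copy numbers inside merged fragments can be contracted when both mates
  end inside the repeat run (see above).
* The artifact-pair model plants identical tails mechanically without
  modeling the physical cause, which published descriptions also leave
  open.
* Primer thermodynamics cover duplex Tm only — no hairpin or cross-dimer
  screening.
* Collapse identity (95% over ≥50 bases) can merge distinct loci that
  share a long identical repeat run with similar flanks; with short
  flanks this is a property of any identity-based deduplication.
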