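---
title: "Discovering centromeric satellite monomers from long reads and optical maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering centromeric satellite monomers from long reads and optical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satseeker)
```

## The problem

Primate centromeres are built from megabase-scale tandem arrays of a short
satellite monomer, often organized into higher-order repeats (HORs): larger
units of several diverged monomer copies that themselves repeat near
perfectly. These arrays are systematically missing from draft assemblies —
they collapse into short scaffold stubs that terminate in satellite
sequence or sit against runs of Ns. Two single-molecule data types still
see them: long reads, which capture dozens to hundreds of monomer copies
per read, and optical (Bionano-style) maps, where a nicking enzyme site
falling once per HOR unit renders the array as a strikingly constant label
spacing along molecules spanning hundreds of kilobases.

satseeker implements that discovery loop end to end for the gray mouse
lemur style of analysis in which a 53-bp centromeric monomer (`mm53()`)
was identified: detect tandem repeats in reads, find the enriched base
monomer and its consensus, annotate its arrays in an assembly, mine label
periodicity in optical maps, and reverse-engineer which nicking enzyme
would make a newly discovered HOR unit visible on maps.

## Tandem-repeat detection

`scan_sequence()` follows the classic detection/verification split of
Tandem Repeats Finder, with the same scoring parameterization: match +2,
mismatch −6, indel −6, expected match rate 0.80, expected indel rate 0.10,
minimum score 50, maximum period 2,000 bp, and reads below 8,000 bp skipped
in read mode.

**Detection** (`propose_periods()`): distances between consecutive
occurrences of exact 12-mers are collected; a distance $d$ is a candidate
period when at least $\max(3, \lceil 0.8\,w/d \rceil)$ seed pairs at
distance within $\lceil 0.1\,d \rceil$ of $d$ fall in some window
$w = \min(10d, \text{sequence length})$ — the density a real array implies
under the expected match and indel rates. Seed pairs are clustered along
the sequence so multiple arrays on one scaffold get separate anchors, and
a candidate must be seed-supported across at least two copies
(anchor span $\ge 2d$).

**Verification** (`wraparound_align()`): the anchor window is aligned
against an infinitely repeated consensus by wraparound dynamic
programming, local within the window with a free start/end phase. The
zero floor means flanks are excluded and a noise-free array scores exactly
$2\times$ its length. The starting pattern is one observed copy taken from
the window center rather than a vote over period-phased columns: with
indels, phase drifts by roughly one base per hundred and phased columns
decohere within a few copies, while a single real copy is always a valid
pattern. The consensus is then re-estimated from the alignment itself —
per-column majority vote, deletion-dominated columns dropped, insertions
present in more than half the copies added — for up to two rounds, with
the total length change clamped to ±10% of the starting period. Percent
identity is matches over aligned columns; copy number is consensus columns
consumed divided by the period.

Overlapping hits (≥50% reciprocal) are merged keeping the higher score,
ties broken toward the smaller period. Candidates that are integer
multiples of an already-accepted hit over the same span are not refined
separately; they would lose that merge anyway.

**Harmonic collapsing** (`collapse_harmonics()`): detectors report a
tandem array at its monomer length *and* at integer multiples of it. A
hit collapses to a smaller period present in the hit set when the period
is within 5% of an integer multiple and the smaller period's consensus
tiles the hit's consensus at ≥70% identity under the best rotation and
strand. When no supported period applies — typically because the overlap
merge kept a long consensus that "memorizes" several diverged copies at
once — the hit's own consensus is scanned for internal tandem structure
and the refined sub-period becomes the base. The second route is what
makes the planted-period recovery robust on diverged arrays: on 100
seeded reads with 5% substitutions and 2% indels the planted monomer
length is recovered within ±1 bp in well over 95 reads (the acceptance
suite asserts ≥95/100).

## Monomer mining

`filter_hits()` applies the mining thresholds — monomer ≥10 bp, ≥4 copies,
≥70% identity — on the base-monomer scale, so a harmonic hit counts its
copies of the underlying monomer. `build_spectrum()` plots each hit by
detected period and array length (the familiar scatter in which a
satellite monomer and its harmonics form vertical bands) and bins total
array bp by base period; `top_monomers()` ranks by array bp because long
arrays, not hit counts, are the centromere signal (hit-count ranking is
available by flag). "Minimum tandem repeat unit of 4" is read as at least
four monomer copies, consistent with the copy-number semantics of the
detector.

`build_consensus()` reduces each contributing consensus to base-period
tiles, orients every tile to the first hit's canonical monomer by the
rotation/strand minimizing Hamming distance, and takes a per-column
majority vote; hits below a 70% identity gate against the provisional
vote are excluded and counted. A full multiple alignment is deliberately
avoided: post-gate monomers are short and near-identical, so
minimal-Hamming rotation is sufficient and orders of magnitude cheaper.
All monomer identity is rotation- and strand-invariant via
`canonical_monomer()` — the lexicographically smallest rotation of the
sequence or its reverse complement — because a monomer discovered on one
strand is probed on the other.

## Assembly arrays and statistics

`annotate_arrays()` rescans scaffolds, keeps hits whose period is within
10% of an integer multiple of the monomer length and whose consensus
matches the monomer at ≥70% identity, merges neighbors closer than one
monomer, and reports arrays ≥2,000 bp — the ">2 kb" census convention.
The 70% association gate and the merge distance are package choices; the
original census did not state its criterion. `flag_context()` marks
arrays within 10 kb of a scaffold end or 5 kb of an N-run ≥25 bases
(both margins are package defaults for "near"; exposed as parameters).
`split_contigs()`/`assembly_stats()` compute scaffold and contig N50
under the convention of splitting on runs of 25 or more Ns; the
percentage of bases in scaffolded contigs is defined as contig bp in
scaffolds of ≥2 contigs over total contig bp.

## Optical-map analytics

`digest_in_silico()` nicks both strands at a fixed offset from every
IUPAC-expanded motif match (minus-strand labels at the reflected offset);
`N` in the sequence never matches, and labels within 1 bp are
deduplicated. `filter_molecules()` applies the raw-molecule production
filter: ≥150 kb and ≥8 labels.

`find_label_repeats()` searches, for each composite order $m = 1..5$, the
series of sums of $m$ consecutive spacings for maximal runs of ≥4 values
within ±10% of their running median. Composite orders catch units
carrying more than one label per repeat; overlapping runs of different
order collapse to the smallest $m$, and units outside 2–35.5 kb (the
observed reporting window) are dropped. The ±10% tolerance reflects
Irys-scale sizing error and the run length of 4 mirrors the
sequence-side copy threshold. Note one documented consequence of
applying the order-collapse before the unit-range filter: a sub-2 kb
base run suppresses its in-range harmonic rather than being replaced by
it.

`call_hor_regions()` stitches runs separated by less than two units,
calling a region `simple` when it is a single run with one unit mode and
`complex` otherwise; spans below 400 kb are reported but flagged.
`select_enzyme()` closes the reverse-engineering loop: on a circularized
HOR unit it ranks nicking enzymes preferring exactly one site per unit
(the geometry that renders an array as a constant label spacing equal to
the unit length), then few sites all ≥1.5 kb apart — an approximation of
optical label resolution, since no published figure exists.

## Simulators and what they do not show

The `make_*` generators are pure functions of their parameters and a
seed. `make_satellite_read()` plants a mutated tandem array between
random flanks (defaults used in the test suite: 5% substitutions, 2%
indels, 2.5 kb flanks — PacBio-like divergence at the read-length floor);
`make_hor_array()` builds diverged-monomer HOR units with one enzyme
site per unit; `make_molecule()` applies multiplicative sizing noise to
spacings (stretch error acts on intervals, not absolute positions), 10%
label miss, and Poisson false labels at 0.5 per 100 kb;
`make_toy_assembly()` reproduces the scaffold-with-gap geometry. The
simulators emulate i.i.d. noise only: no context-dependent PacBio error,
no chimeric molecules, no array-internal subfamily structure. Passing
recovery tests therefore demonstrate correctness of the algorithms under
the stated noise model, not performance on any particular instrument's
error profile.

Problem sizes in the test and acceptance suites — reads of ~8–10 kb with
~3 kb arrays, 100-read recovery panels, 400 kb molecules — were chosen as
the smallest sets that exercise every code path at stable rates.

## Numerical and degenerate-input choices

* N scores as a mismatch everywhere; scan windows with >20% N are
  skipped; consensus tiles containing N yield no canonical form.
* The minimum reportable period defaults to 10 bp (configurable to 2) so
  homopolymer and dinucleotide noise does not dominate read scans.
* Ties in majority votes resolve to the alphabetically first base;
  enzyme-ranking ties resolve by name; merge ties by smaller period.
* Empty inputs return empty, typed results (empty FASTA → empty stream;
  no labels → no runs); invalid coordinates, alphabets and motifs raise
  errors naming the violated constraint.
* The wraparound DP computes each row in two passes so a deletion chain
  may wrap the cyclic consensus once; a positive indel penalty makes a
  full extra cycle unprofitable, so two passes are exact (the test suite
  checks equality against a fixpoint-relaxation oracle).

## Known limitations

Monomer subfamily classification and phylogeny are out of scope, as are
optical-map assembly and molecule-to-map alignment. The BNX/CMAP support
is a minimal faithful dialect (molecule header plus channel-1 positions;
extra channels and quality rows ignored). Qualities are carried through
FASTQ I/O but never used by the algorithms.
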