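# satseeker

Centromeric satellite discovery from long reads, genome assemblies and
optical (Bionano-style) maps.

Primate centromeres are tandem arrays of a short satellite monomer —
often organized into higher-order repeats (HORs) — that collapse out of
draft assemblies and survive only in single-molecule data. satseeker is
an R toolkit for the discovery loop that identified the 53-bp mouse
lemur centromeric monomer (shipped as `mm53()`):

1. **Scan** long reads for tandem repeats with a seed-and-extend
   wraparound dynamic-programming detector (TRF-style parameterization:
   match +2, mismatch −6, indel −6, PM 80, PI 10, min score 50, max
   period 2,000 bp; reads ≥ 8 kb).
2. **Mine** the enriched base monomer: harmonic collapsing of
   multiple-of-the-monomer periods, filtering (monomer ≥ 10 bp, ≥ 4
   copies, ≥ 70% identity), a monomer-length × array-length spectrum,
   and a rotation/strand-canonical consensus.
3. **Annotate** satellite arrays ≥ 2 kb of that monomer across assembly
   scaffolds, flagging proximity to scaffold ends and N-gaps, plus
   scaffold/contig N50 statistics under a 25-N contig convention.
4. **Map** analytics: in silico nicking digestion, the 150 kb / 8-label
   molecule filter, detection of near-constant label spacing runs
   (composite orders catch multi-label units), unit-size spectra with
   doubled-unit flags, and HOR-region calls on consensus maps.
5. **Pick an enzyme**: rank nicking endonucleases on a circularized HOR
   unit, preferring exactly one site per unit — the geometry that makes
   a centromeric array visible as a constant label spacing (Nt.BspQI,
   `GCTCTTC`, in the mouse lemur case).

Seeded simulators (`make_satellite_read()`, `make_hor_array()`,
`make_molecule()`, `make_toy_assembly()`) generate every input class the
pipeline consumes, so the whole stack is testable without any download.

The core alignment is wraparound dynamic programming: the window is
aligned against an infinitely repeated consensus `c` of period `p`, with
score `S(i,j) = max(S(i-1, j-1 mod p) ± s, S(i-1,j) - δ, S(i, j-1 mod p) - δ, 0)`,
local in the window with free start/end phase, so a noise-free array of
length `L` scores exactly `2L`. Monomer identity is always taken on the
canonical form — the lexicographically smallest rotation of the sequence
or its reverse complement — because tandem detectors report arbitrary
rotations and strands.

## Worked example

A simulated PacBio-like read — 100 copies of the 53-bp monomer at 3%
substitutions and 1% indels between 2.5 kb random flanks — and the
discovery steps on it:

```r
library(satseeker)

sim  <- make_satellite_read(mm53(), copies = 100, substitution_rate = 0.03,
                            indel_rate = 0.01, seed = 7)
hits <- collapse_harmonics(scan_sequence(sim$record, read_mode = TRUE))
hits[, c("start", "end", "period", "base_period", "copy_number",
         "percent_identity", "score")]
#>   start  end period base_period copy_number percent_identity score
#> 1  2499 7795     53          53    100.0189         96.18708  9024

mine_monomer(list(sim$record))$consensus
#> <monomer_consensus> 53 bp, 1 hit(s), 5296 array bp, mean identity 100.0%
#>   ACACAGCCAGATCCGCACTGCGCCCTGCCTGCCCGTCTGCCGTGGGTGAGTGG
```

The detector reports one merged array covering the planted interval
(truth: 2,500–7,800) at base period 53; the mined consensus equals
`canonical_monomer(mm53())`, i.e. the planted monomer up to rotation and
strand. The HOR construction closes the loop with optical maps:

```r
hor <- make_hor_array(mm53(), monomers_per_hor = 74, n_hors = 20,
                      variant_divergence = 0.05, site_motif = "GCTCTTC",
                      seed = 1)
mol <- digest_in_silico(hor$record, nicking_enzymes()[[1]])
unique(diff(mol$labels))
#> [1] 3922                       # one label per 74 x 53 bp HOR unit

select_enzyme(substr(hor$record$bases, 1, hor$truth$unit_len))
#>      enzyme sites_per_unit spacings rank
#> 1  Nt.BspQI              1     3922    1
#> 2 Nt.BstNBI              1     3922    2
```

A 74-monomer HOR unit carrying one Nt.BspQI site digests to twenty
labels at a constant 3,922 bp spacing — the unit length — and
`select_enzyme()` ranks Nt.BspQI first with one site per unit.

## Command line

`inst/scripts/satseeker` is a thin Rscript over `run_pipeline()`:

```sh
satseeker scan-reads --input reads.fa --out scan
satseeker mine --hits scan.hits.tsv --out mine
satseeker annotate --assembly asm.fa --monomer mine.monomers.fa --out ann
satseeker digest --input asm.fa --enzyme Nt.BspQI --out asm.bnx
satseeker map-repeats --bnx molecules.bnx --out runs
satseeker pick-enzyme --unit unit.fa
satseeker simulate reads --seed 7 --out sim
```

Each run logs the record counts surviving every filter to standard error
and writes a JSON report of the fully merged parameter values
(defaults < config file < flags).

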