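---
title: "Methods: from hybridoma amplicon reads to scored V domains"
author: "hybseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from hybridoma amplicon reads to scored V domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybseq)
```

## The assay this package models

Hybridoma cells transcribe their rearranged immunoglobulin light- and
heavy-chain genes; a 5′-RACE-style library preparation captures these
transcripts as amplicons of the form

```
barcode (5-8 nt) · TSO · 5'UTR/leader · V domain · constant-region stub · rc(nested primer)
```

of roughly 500–550 bp, sequenced as 300 bp paired-end reads so the mates
overlap by at least 50 bp. The inline barcode identifies the well of a
96-well plate; the nested constant-region primer at the other end identifies
the chain class (heavy, kappa or lambda). Because nearly all mouse
hybridomas derive from the Sp2/0 myeloma fusion partner, every well also
contains an *aberrant*, non-productive kappa transcript inherited from the
myeloma; it must be recognized and excluded before any abundance statistics
are computed.

The package processes such data in five stages — read processing,
denoising, IMGT annotation, replicate scoring, and construct design — and
ships a simulator that generates plates with known ground truth under
exactly this amplicon anatomy.

## Read processing

Reads are demultiplexed on the R1 prefix by exact barcode match (default; a
mismatch allowance exists but barcodes of 5–8 nt are short enough that
tolerance invites collisions). When barcodes nest, the longest match wins;
equal-length double matches are ambiguous and the read stays unassigned.
The TSO must follow the barcode within 20 nt — a cheap guard against
barcode false positives. Chain assignment allows one mismatch in the
~25 nt nested primer, which is long enough that a single error cannot cross
chains.

Quality trimming is run-based: the maximal 3′ run of bases below Phred 10
is removed and interior low-quality bases are left alone. A windowed
trimmer would also have been defensible; the run-based rule is the simplest
reading of "remove low-quality bases from the 3′ end" and is what the tests
pin down.

Merging reverse-complements R2 and picks the overlap maximizing matched
bases subject to a 10 % mismatch cap and a 20 nt minimum overlap. The
search is seed-and-extend (exact 15-mers from the start of the
reverse-complemented mate locate candidate offsets; an exhaustive offset
scan is the fallback), which finds the true overlap whenever any 15-mer
near the mate's start is error-free — essentially always at the error
rates of interest. At a disagreement the higher-quality base wins and keeps
its quality; where mates agree the merged quality is `min(q1+q2, 41)`, a
standard consensus convention. Merged reads shorter than 385 nt are
discarded: that threshold sits safely above primer-dimer and truncation
artifacts but below the shortest genuine amplicon interior.

Every stage keeps counts, and the partition `assigned + unassigned +
discarded = input` is asserted in the test suite.

## Denoising

The denoiser is deliberately simple: sequences are dereplicated, visited in
decreasing abundance (ties broken lexicographically so input order can
never matter), and a sequence at Hamming distance *d* (1–4) from an
already-accepted variant is absorbed into it iff its abundance ratio is at
most 2^−(αd+1) with α = 2. This is an abundance-skew rule in the UNOISE
tradition rather than a parametric error model; the contract it must honor
— true sequences recovered, error reads absorbed, read counts conserved —
is what the tests check, including an oracle comparison against the
simulator's truth table on small wells.

Aberrant-transcript removal aligns each light-chain variant to the
configured reference (local alignment, Biostrings) and flags it at ≥ 97 %
identity over ≥ 90 % of the shorter sequence. The thresholds leave a wide
margin in both directions: sequencing-error satellites of the aberrant
transcript sit above 99 % identity, while any productive V domain differs
from the reference across its CDRs and by the reference's frameshift
(≈ 92 % identity on simulated data). Removal happens *before* the ≥ 10 %
read-support filter, so light-chain fractions renormalize over productive
reads only; the order is configurable because the original workflow does
not state it.

The 10 % filter's denominator is reads per well *and* chain
(`ReadsPerPrimerWell` read as "per chain-specific primer within a well"),
also configurable.

## IMGT annotation without an HMM

A germline-profile aligner assigns IMGT numbers by aligning to curated
antibody HMMs. This package instead exploits the four anchors the IMGT
scheme fixes positionally in every productive V domain: the first cysteine
at position 23, the conserved tryptophan at 41, the second cysteine at 104,
and the J-motif F/W-G-x-G whose aromatic residue is position 118. Framework
lengths between anchors are constants of the numbering (FR2 17, FR3 39
slots); CDR lengths float within IMGT bounds (CDR1 5–12, CDR2 0–10, CDR3
2–25). The annotator enumerates anchor arrangements satisfying these
spacing constraints in all three frames, rejects any containing a stop
codon or lacking an upstream ATG, and keeps the arrangement covering the
most residues.

Short CDRs receive the IMGT middle-of-loop gaps (slots filled from both
ends, front half taking the extra residue); CDR3 loops beyond 13 residues
receive lettered insertions in the IMGT order 111A, 111B, …, 112B, 112A.
Validity follows the published filters verbatim: no empty FR or CDR, the
first 10 FR1 positions and last 10 FR4 positions all present, a start
codon upstream, no stop codon in the span. Trimming returns exactly the
codons of the IMGT span, and variants identical after trimming are grouped
additively (counts summed, fractions recomputed) — the grouping key is the
trimmed nucleotide sequence, stricter than amino-acid identity; an
amino-acid-level option exists.

Two limitations are worth stating. First, anchor detection assumes a
full-length FR3 (39 residues); genuinely gapped FR3s, rare in mouse V
genes, would be rejected rather than renumbered. Second, when a read
begins mid-FR1, the residues preceding the first cysteine are numbered
backwards from 23 without any content check — the FR1-completeness filter
is what catches such truncations, not the numbering itself. On heavily
mutated frameworks an HMM aligner may number sequences this method rejects
(and vice versa); the acceptance surface here is the simulator and the
explicit validity rules, not bit-compatibility with any particular tool.

## Replicate scoring

The mAb-ID convention `Project/Parent.Subclone` defines the replicate
structure: biological replicates are distinct subclones of one parent;
technical replicates are distinct sequenced samples (wells/vials) of one
subclone. For each curated sequence, BR and TR count the *other* samples of
its parent group carrying the identical trimmed sequence for the same
chain (the focal sample is not its own match; an option includes it), and

```
MatchScore = (BR + 0.75·TR) − (1 − (BR + TR)/TotalSeqs)
TotalScore = clamp(3·ln MatchScore, 0, 3) + 2·(ReadPerSequence/ReadsPerPrimerWell)
```

`TotalSeqs` is read as the number of sequenced replicate samples in the
parent group for that chain, which makes `(BR+TR)/TotalSeqs` a detection
fraction bounded by 1; the alternative reading (distinct sequences returned
for the group) is available behind a switch. `3·ln(MatchScore)` is
unbounded above and undefined at MatchScore ≤ 0, so the match component is
clamped to [0, 3] — this reproduces the published 0–5 star range and the
"up to 3 points" description, and it is the only reading under which the
score is always defined. Scores below 3 are filtered.

Chain multiplicity per parent is the mean number of distinct retained
sequences per sample, rounded to the nearest integer with halves away from
zero (the plain-language "rounded to the nearest integer" does not specify
the tie rule; away-from-zero means a sequence must be retained in at least
half the group's samples to count as an additional chain, which matches
the requirement that additional chains be consistent across replicates).
The census then classifies each unique parent: lacking a V_L or V_H, both
present, no additional chain, one extra V_L, one extra V_H, or one of
each, with percentages over the whole cohort and optional stratification
by a covariate such as fusion method.

## Construct design

Curated IMGT-trimmed sequences feed two deterministic designers. R-mAb V
fragments are the trimmed V_L (positions 1–127) and V_H (1–128) coding
regions flanked by the four published 50 bp Gibson overhangs, emitted
verbatim; internal NotI/AscI/BssHII sites inside the inserts are warned
about because they would break the downstream subclass-switching digest,
whose layout `subclass_switch_check()` verifies. The scFv designer builds
leader–V_H–linker–V_L (orientation switchable) followed by HA, sortase and
His6 tags and a stop codon. Leader (`MGWSCIILFLVATATGVHS`) and linker
(`GGGGSGGGGSGGGGSGGGS`) are the published peptides; the tag peptides and
their direct concatenation are documented assumptions (the original
junctions are not printed), as are the synthetic vector homology arms. All
peptides are reverse-translated with a fixed one-codon-per-residue mouse
table — no codon sampling, so every design is reproducible byte for byte.

## The simulator and what passing tests mean

`make_reference_set()` builds clones from synthetic mouse-like consensus V
scaffolds — real enough to carry every IMGT anchor and region, but not
copies of any germline database entry — with CDR residues randomized per
clone from an alphabet free of C/W/F so no spurious anchor can arise inside
a loop. Clones can carry an additional productive light chain at a set
fraction. `make_plate_spec()` lays out biological and technical replicates
under the mAb-ID convention; `simulate_plate()` writes 300 bp paired FASTQ
with substitution errors only (no indels by default — the cleaning stages
address substitutions and N's, and indel-free simulation keeps the ASV
ground truth exact), per-base qualities derived from the error rate plus
seeded jitter, and the aberrant kappa contaminant mixed into every well's
light-chain reads at a configurable fraction (default 0.2, a typical
contamination burden; tests also exercise 0.3). The bundled aberrant
reference is a synthetic frameshifted derivative of the light scaffold
(4 nt deletion at the FR3/CDR3 junction), shipped also as
`inst/extdata/sp2_0_aberrant_kappa_synthetic.fasta`.

Default study conditions: 96-well plates as parents × (3 biological + 1
technical) replicates, 50 reads per well and chain, 0.2 % per-base error.
The test suite scales these down where full size adds nothing (6-well
plates at depth 40 for most module tests; one full 96-well error-free plate
at depth 25 for the end-to-end recovery check) — sizes chosen so the whole
suite exercises every path at plate scale while remaining quick to run.

What the simulator does *not* emulate bounds what passing tests show about
real data: no indels, no PCR chimeras or index hopping, no quality-by-cycle
structure, no between-well contamination, and framework sequences far more
uniform than real somatically-mutated repertoires. The pipeline's
correctness on the simulator therefore demonstrates the plumbing and the
contracts (recovery, conservation, filters, scoring arithmetic), not
robustness to every artifact of a real MiSeq run.

## Numerical and design choices, collected

- Barcode match exact, primer match ≤ 1 mismatch, TSO within 20 nt
  (defaults, all configurable).
- Merge: min overlap 20 nt, mismatch cap 10 %, agreeing-quality cap 41.
- Denoiser: α = 2, max distance 4, lexicographic tie-break.
- Aberrant filter: ≥ 97 % identity over ≥ 90 % coverage, before the 10 %
  filter.
- Score: match component clamped to [0, 3]; BR/TR exclude the focal
  sample; TotalSeqs = replicate samples; halves round away from zero.
- Degenerate inputs: empty FASTQ → empty database with zeroed QC; zero
  read denominators score 0 with a warning; unparseable mAb IDs fail the
  sample-sheet validation up front.
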