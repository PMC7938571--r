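---
title: "Methods: finding translation evidence on circular RNAs"
author: "circribo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finding translation evidence on circular RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circribo)
```

## The problem

Circular RNAs (circRNAs) arise from back-splicing: a downstream splice
donor is joined to an upstream acceptor, producing a covalently closed
transcript. The only sequence feature that distinguishes a circRNA from
its linear host transcript is the back-splice junction (BSJ), so every
kind of translation evidence this package handles is anchored there:

* a ribosome-profiling footprint proves ribosome association only if it
  *spans* the BSJ — a footprint mapping inside an exon is explained
  equally well by the linear mRNA;
* an open reading frame is circRNA-specific only if its codon run crosses
  the BSJ;
* a mass-spectrometry peptide proves translation only if it covers the
  junction-crossing codon and occurs nowhere in the linear proteome.

`circribo` implements this junction-anchored evidence chain end to end:
footprint-based detection of ribosome-associated circRNAs, rolling-circle
ORF prediction, annotation of translation-supporting cis-elements (IRES,
m6A, conservation), cross-species conservation by reciprocal best hits,
and classification of proteomic junction peptides.

## Coordinate conventions

All coordinates are 0-based and half-open. Position 0 of a circRNA
sequence is defined as the back-splice acceptor — the first transcribed
base after the junction — so the BSJ sits between positions `L-1` and `0`.
Nothing in the underlying biology fixes an origin on a circle; this
convention is arbitrary but is applied consistently, and all junction
arithmetic below is written against it. Minus-strand circRNAs store their
sequence already reverse-complemented into transcript orientation while
their exon blocks stay in genome orientation; `circle_genome_map()` is the
single bridge between the two.

Ambiguity is handled conservatively throughout: a window containing `N`
never supports an exact footprint match, an `N`-containing codon ends ORF
extension, and `N` is scored as a mismatch against everything (including
itself) in alignments.

## Detecting ribosome-associated circRNAs

For each circRNA the 23 nt on either side of the BSJ are concatenated into
a 46-nt junction pseudo-reference (`build_pseudo_reference()`); circles
shorter than 46 nt wrap around, so a matching footprint may tile the
circle more than once — permitted and reported as such. Footprints are
first screened against the linear transcriptome: any read occurring as an
exact substring of a linear reference is removed
(`exclude_linear_mappers()`), mirroring the usual map-to-linear-first,
remap-the-remainder order. The survivors are matched exactly (hash-based
substring lookup, zero mismatches by default) against the
pseudo-reference, and a circRNA is called ribosome-associated when all
three criteria hold simultaneously:

1. at least 2 *unique* junction-spanning reads,
2. each overlapping the junction by at least 3 nt on both sides,
3. each 25–35 nt long (the typical ribosome footprint range).

"Unique" means distinct read *sequences*, not distinct read identifiers or
distinct offsets: PCR duplicates share a sequence and should count once,
and one sequence matching a reference at two offsets is still one piece of
evidence (both placements are reported in the hits table). A
mismatch-tolerant scan is available via `max_mismatches`, but the default
is exact matching, which keeps the matcher deterministic and trivially
auditable against a brute-force all-offsets scan (the test suite does
exactly that comparison).

## Rolling-circle ORF prediction

A circle supports translation past its own end, so `enumerate_corfs()`
concatenates the sequence four times and reads the result linearly. Four
copies is the conventional depth: it lets a stop-free frame demonstrate at
least three full junction crossings, which is taken as evidence of
rolling-circle (infinite) translation. Start codons (AUG by default) are
only accepted in the first copy — later copies exist to extend reading,
not to multiply starts, and every circular ORF would otherwise be reported
once per copy. From each start, extension proceeds in codons until:

* the first in-frame stop — a finite cORF; the stop is excluded from
  `nt_len` and the peptide;
* the template end — an *INF-cORF* (`is_infinite = TRUE`), the signature
  of a frame with no in-frame stop on the circle;
* a codon containing `N` — treated exactly like the template end, so the
  ORF carries no stop codon and is flagged infinite; the minimum-length
  filter removes most such fragments.

ORFs must reach 20 aa (initiator methionine counted, stop excluded — the
conventional accounting; the reported peptide length always equals
`nt_len / 3`) and, by default, must span the BSJ. Junction spanning is
tested against the *first* junction image (template position `L`): any ORF
crossing a later image necessarily crosses the first. Finally only the
longest cORF per reading frame is kept (`select_longest_per_frame()`),
with deterministic tie-breaks: smaller start coordinate first, then finite
before infinite. Frames are defined as `start mod 3` on the linearised
circle.

INF-cORF peptides are reported as the full translation of the 4x template
from the start codon, truncated to whole codons. A consequence worth
spelling out: the truncation point depends on where the start sits inside
the template, so the *tail* of an INF peptide is not invariant under
rotation of the circle, while its first `L` residues always are (from any
start `p < L`, at least `3L + 1` template nucleotides remain). The test
suite's rotation-invariance property therefore compares finite cORFs
exactly and INF-cORFs on their first `L` residues; consumers needing more
rolling-circle copies can re-roll from `nt_len` and the circle sequence.

Translation uses the standard genetic code by default; `codon_table`
accepts any NCBI code identifier for organisms where that matters.

## Cis-element annotation

**IRES elements.** Library sequences are locally aligned
(Smith–Waterman, affine gaps) against the doubled circle
(`seq + seq[0..L-2]`, length `2L-1`), which makes every junction-crossing
placement visible exactly once. A hit requires at least 80% identity over
at least 30 alignment columns. Two conventions needed fixing because the
cutoffs alone do not determine them: identity is counted over *alignment
columns* (gap columns included), and the scoring scheme is megablast-like
(+2 match, −3 mismatch, a gap of length *k* costs 5 + 2*k*); both are
configurable in `ires_params()`. One hit — the best local alignment — is
reported per (circRNA, IRES) pair; distinct placements of the same
element on the same circle are collapsed to the best-scoring one.

**m6A sites.** Methylation peaks are intersected with the circRNA exon
blocks, covered genomic positions are mapped to circle coordinates
(strand-aware), and every `RAC` consensus occurrence (R = A/G; the central
A is the putative m6A site) whose A lies in covered sequence is emitted.
The motif is read circularly, so junction-adjacent sites are found. No
peak calling is performed and no minimum number of supporting tools is
imposed; `n_tools` simply records how many distinct peak sources cover the
site, and a "site" is each RAC occurrence rather than the peak itself.

**Conservation.** `score_peptide_conservation()` maps a cORF's circle
positions to the genome and averages per-base conservation scores
(phastCons-style, in [0, 1]) over the positions present in the track.
Uncovered positions are excluded from numerator and denominator alike;
zero covered positions yield a missing value, never 0. A rolling-circle
ORF traverses the same base repeatedly; each base of the genomic footprint
is counted once, which keeps the mean invariant under block fragmentation
and ORF length beyond `L`.

## Cross-species conservation

The unit of comparison is the genomic BSJ flank sequence: the last 50
genomic bases of the circRNA span (donor side) concatenated with the first
50 (acceptor side), in transcript orientation, so the junction sits at
index 50. Note these flanks come from the *reference genome* span, not
from the spliced circle sequence — unlike the detection module's 23-nt
pseudo-reference — because cross-species coordinates are only comparable
on the genome. Candidate pairs are restricted to circRNAs whose host
genes are orthologous (the search-space restriction is applied before
alignment), then aligned all-vs-all with +1/−2 scoring. A pair is reported
when each flank is the other's best hit (raw score; ties broken by
alignment length, then identifier), the alignment spans at least 80
columns, and the bit-score reaches 150 bits under the Karlin–Altschul
normalisation

$$\mathrm{bits} = \frac{\lambda \cdot S - \ln K}{\ln 2},
\qquad \lambda = 1.28,\; K = 0.46,$$

the published constants for +1/−2 nucleotide scoring. A perfect 100-nt
flank match scores 185.8 bits; a perfect 80-nt match scores 148.8 bits and
so sits just *under* the 150-bit cutoff — the two thresholds are not
redundant.

## Proteomic junction-peptide evidence

`build_search_database()` concatenates the linear proteome with the cORF
peptides (namespaced `cORF|...`); redundancy with linear entries is kept
but flagged, since search engines handle it. Downstream of the external
search, `classify_peptides()` applies the package's own computable rule: a
peptide is evidence for circRNA translation iff it

1. **spans the junction** — some occurrence of the peptide within its cORF
   covers the junction-crossing codon. When the junction falls between
   codons, one residue on each side is required; when it splits a codon,
   that codon's single residue suffices. All junction images (`k·L`)
   reached by a rolling-circle ORF qualify, because they are the same
   biological junction and INF-cORF peptides are periodic;
2. **is unique** — not a substring of any linear proteome entry
   (exact and case-insensitive by default; an I=L collapse flag exists for
   search engines that cannot distinguish the isobaric pair);
3. is at least 7 aa long, the conventional minimum for confident
   identification.

`summarize_evidence()` then marks a circRNA as evidenced when at least one
such peptide exists, counting distinct peptide sequences once per circRNA.

## The synthetic-data generator

`generate_fixture_bundle()` builds, from a single seed, a complete
miniature study: a synthetic chromosome with 25 embedded circRNAs
(120–300 nt, one- and two-exon, both strands), 5 of them planted as
ribosome-associated with 3 distinct junction-spanning footprints each,
5 decoys with exactly one such footprint (below threshold by design), and
20 footprints from linear transcripts; a designed circle carrying exactly
one 30-aa junction-spanning cORF (its filler regions are stop-rich and
free of AUG in every frame, so the truth table is exact by construction);
a junction-straddling IRES and an interior one; a planted `GAC` site
covered by three peak sources; a constant-0.8 conservation track over the
designed cORF; an ortholog flank series diverged in 5% steps from 0 to
50% (mutation sets are *nested* along the grid, so the raw alignment
score is non-increasing by construction); and tryptic-like fragments of
the planted cORF peptide with known spanning/uniqueness status.

The generator emulates the *logical* structure of such experiments, not
their noise: reads are error-free exact windows, expression levels and
footprint periodicity are absent, and sequences are i.i.d. uniform.
Passing the planted-recovery tests therefore demonstrates correctness of
the decision rules, not robustness to sequencing artefacts — the
thresholds themselves (2 reads, 3 nt, 25–35 nt, 80%, 150 bits, 7 aa) are
the robustness mechanism on real data.

Problem sizes used by the test-suite properties were chosen to exercise
the combinatorics thoroughly at desk scale: 500 random instances for the
matcher-vs-oracle equivalence, 500 random circles (all rotations each)
for ORF rotation invariance, and 100 flank pairs for reciprocal-best-hit
symmetry.

## Numerical and degenerate-input choices

* Exact matching uses hashed substring lookup; with `max_mismatches > 0`
  a direct scan is used instead.
* The local aligner is `Biostrings::pairwiseAlignment` under the package's
  scoring conventions; the test suite cross-checks it against an
  independent affine-gap dynamic program on small inputs.
* Circles shorter than `2 x flank` wrap during pseudo-reference
  extraction; circles shorter than 3 nt are rejected for ORF prediction.
* Empty inputs (no reads, empty IRES library, empty track, no orthologs)
  yield empty results, never errors; genuinely impossible requests
  (genomic mapping without exon blocks, flanks past the chromosome end,
  a peptide absent from its claimed cORF) raise errors naming the record.
* All outputs are sorted deterministically; rerunning any subcommand on
  the same inputs is byte-identical.

## Known limitations

* Detection is exact-match and sense-stranded by default; indels,
  quality-aware alignment and genome-scale performance are out of scope.
* Ribosome-frame periodicity is not modelled, so "ribosome-associated"
  must not be read as "actively translated"; the proteomic module exists
  precisely because footprints alone cannot close that gap.
* The IRES annotator reports one placement per element per circle.
* The conservation module compares two species at a time; multi-species
  clique finding is not attempted.
* Spectral search, FDR control and modification handling belong to the
  external search engine; this package consumes its identified-peptide
  table.

## A worked mini-example

```{r example}
circ <- circ_rna("demo", "AAATAGATGGCA")
enumerate_corfs(circ, corf_params(min_aa = 2))
```

The 12-nt circle carries one AUG at position 6; reading crosses the
junction (position 12 on the template) and terminates at the `TAG`
planted at circle positions 3–5, seen on the template at 15–17: peptide
`MAK`, finite, junction-spanning.

```{r example2}
bit_score(100)  # a perfect 100-nt BSJ-flank match, in bits
```
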