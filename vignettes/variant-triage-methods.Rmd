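---
title: "Variant triage and read-evidence browsing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant triage and read-evidence browsing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genevista)
```

## Scope and model

genevista triages a single patient's variant calls over a phenotype-derived
gene panel and lets the user audit each call against the raw read
alignments. It deliberately does **not** call variants from reads: the VCF
is taken as the statement of candidate variants, and the alignments are
used as independent evidence for or against each candidate. The two
evidence channels are kept separate throughout:

* the **VCF channel** carries positions, alleles, rsIDs and an
  allele-frequency value (`AF` from INFO, else alt-AD/sum(AD) from the
  sample's FORMAT `AD`, else absent). Filtering and per-gene summaries
  operate on this channel only.
* the **read channel** carries per-variant supporting-read counts computed
  from CIGAR projections. Zygosity calls come from this channel only.

This split resolves the ambiguity in the phrase "allele frequency", which
in clinical filtering panels can mean either a population frequency or the
in-sample read fraction: here the filter bounds apply to whatever AF the
VCF provides, and read fractions are always reported separately as
`gv_support` objects.

## Coordinates

All internal coordinates are 0-based half-open `[start, end)`. Conversions
happen only at format boundaries: VCF and SAM `POS` are 1-based (subtract
one on load, add one on write), browser-style locus strings
(`chr1:100-199`) are 1-based inclusive. This single-convention rule is the
reason the interval arithmetic in windowing, partitioning and pileup code
contains no `+1`/`-1` corrections outside the readers and writers.

## Gene models and junction flanks

Gene models are read from UCSC refFlat-dialect tables; each row is one
transcript, grouped by gene symbol, and a gene's span is the union (min
start, max end) of its transcripts. Interval queries run through
GenomicRanges. When a gene has several transcripts the exon view defaults
to the longest coding transcript (ties broken by span, then accession) —
a deterministic, commonly used display convention; any transcript can be
requested explicitly.

Exon windows extend each exon by a flank into the intron,
`[max(0, s - flank), min(contig_len, e + flank))`, merging windows that
overlap or abut. The default flank is **30 bp**, targeting the splice
donor/acceptor region where deleterious intronic variants concentrate; it
is a parameter everywhere it appears (windowing, filtering, summaries,
views). A variant "belongs to" a gene for counting purposes iff its locus
overlaps any exon window of any transcript, so near-junction intronic
variants are counted but a variant 40 bp into an intron is not (it enters
at flank 50).

## Variant normalization and classification

Multi-allelic VCF records are decomposed into biallelic variants; each
allele pair is normalized by trimming the shared trailing suffix, then the
shared leading prefix, always keeping at least one base on each side (the
indel anchor base survives). Classification then reads off lengths: equal
length 1 → SNP, equal length >1 → MNV, longer alt with shared leading base
→ insertion, longer ref → deletion. Length-changing pairs without a shared
anchor are rare complex substitutions and fall into MNV rather than getting
a bespoke class. Normalization makes dbSNP matching well-defined: a variant
is *known* iff a catalog entry matches exactly on (chrom, start, ref, alt),
and an entry at the same position with a different alt leaves the variant
novel. MNVs pass type filters only when explicitly selected.

## Read processing

QC filtering is a pure predicate: drop reads with any of the flags
unmapped/secondary/QC-fail/duplicate/supplementary, or mapping quality
below 1. Nothing is mutated, so the filter is idempotent; duplicates are
honored from the flag, never re-detected.

CIGAR projection maps each read deterministically onto reference
coordinates. The one convention worth stating is the insertion anchor: an
inserted sequence attaches **after the last reference-consuming position**
preceding the `I` operation. That matches VCF's left-anchored insertion
records, so a VCF insertion (`REF=C`, `ALT=CCTC` at anchor `p`) and a read
insertion (`aM 3I bM` with the `I` after reference position `p`) compare
directly on `(anchor, sequence)`. `N` operations advance the reference but
are recorded as skips, not deletions, so spliced input would not fabricate
deletion evidence.

The partition index registers each read in every fixed-size bin whose
*extended* range `[b*P - overlap, (b+1)*P + overlap)` its span overlaps.
Defaults are P = 16384 bp and overlap = 512 bp — the overlap needs to be at
least the longest expected read span so windowed retrieval never misses a
boundary read; 512 bp comfortably covers short-read data. The index is an
accelerator only: `fetch_window()` re-checks true overlap and is tested to
be extensionally identical to a linear scan, which is also why correctness
is insensitive to the two size parameters.

Pileups count, per reference position, the projected bases, deletions and
anchored insertions of the covering reads. The conservation law
`depth = A + C + G + T + N + del` holds on every column; insertions do not
consume a column and are tallied at their anchor instead of contributing to
depth.

## Zygosity from supporting-read fractions

For one variant, `n_cover` counts reads that consume (match or delete) the
whole variant locus — for insertions, the anchor base; for deletions, the
anchor plus the deleted interval — and `n_support` counts reads whose
projection carries the alt event exactly (same bases, same deleted
interval, same inserted sequence at the same anchor). The call bands on
`fraction = n_support / n_cover` are 0.2 and 0.8, with `low_coverage` below
8 covering reads. The bands are configurable; the defaults sit symmetric
around the diploid expectations of 0.5 (heterozygous) and 1.0 (homozygous)
and are wide enough that, at depth 40, binomial noise around 0.5 stays
inside the heterozygous band with high probability (P(|X/40 − 0.5| ≥ 0.3)
≈ 2·10⁻⁴), which the parameter-recovery acceptance test confirms
empirically across 20 seeds.

## Views and rendering

Two view models replace an interactive browser's panels:

* the **exon view** has one track per merged exon window with the variants
  and pileup restricted to the window. Each exon's `has_variant` flag is
  true iff a variant overlaps the exon *body*; flank-only variants are
  listed but do not flag the exon — the flag answers "is the exon itself
  hit?" while the listing answers "what is near the junction?".
* the **genome view** is a single window whose width is clamped to
  [59, 121704] bp. At or below 200 bp it switches to per-base mode
  (reference row, translated amino-acid rows for coding transcripts,
  stacked reads); above that it draws gene structure only. The 200 bp
  threshold is a display choice: beyond it, one base per character column
  stops being legible at typical terminal widths.

Read stacking is greedy by start position: each read takes the lowest row
with no horizontal overlap, which is the standard minimal-row layout for
interval scheduling. Rendering is a pure function of (view model, spec):
text mode uses `#`/`=` for exons with/without variants (the color scheme
maps these to blue/green in SVG) and `*`/`+`/`-` glyphs for
SNP/insertion/deletion markers; deletions show as gap runs in read rows and
insertions as `^pos+SEQ` notes. Determinism is asserted byte-for-byte in
the tests.

## The synthetic-fixture generator

The generator builds a seeded world: a uniform-random contig (default
20 kb), evenly spaced plus-strand genes with three fully coding 150 bp
exons and 250 bp introns, uniform-start single-end 100 bp reads at a target
mean depth (default 40x), flat placeholder base qualities, and a
configurable fraction of reads duplicated with the duplicate flag set. Each
spiked variant sits at the midpoint of a chosen exon; reads spanning the
event are made carriers independently with probability equal to the allele
fraction, so observed fractions are binomial draws around the truth. For
indels, only reads spanning the full event (anchor plus deleted interval,
or anchor plus room for the insertion) enter the carrier draw, keeping
carrier and reference reads on the same footing and the expected fraction
unbiased. The VCF written next to the reads contains exactly the spiked
variants with `AF` set to the true fraction.

What the generator does **not** emulate: realistic error profiles (a flat
per-base substitution rate is available but defaults to 0), paired-end
structure, mapping ambiguity, alignment artifacts around repeats, or
structural variants. Tests passing on these fixtures therefore demonstrate
the correctness of the bookkeeping — projection, indexing, counting,
thresholding — not robustness to messy real-world alignments, which is why
the zygosity thresholds remain user-adjustable.

## Problem sizes and numerical choices

The test suite and acceptance script run on deliberately small worlds:
20 kb contigs at 10–40x (500–8000 reads), 200-variant tables, 200 random
windows/criteria for the oracle-equivalence checks, and 20 seeds × 3
fractions for parameter recovery. These sizes give the binomial arguments
above comfortable margins while keeping a full run in the low minutes.
Degenerate inputs are defined rather than rejected where a definition
exists: zero-width intervals overlap nothing, empty VCFs load as empty
tables, zero-coverage pileup columns have depth 0, a variant with no
covering reads gets `low_coverage` with an undefined fraction, and unknown
chromosomes in region queries return empty results. Ties in transcript
selection and read stacking are broken deterministically (accession order,
start order) so every output is reproducible byte for byte.

## Known limitations

Consequence labels are minimal (synonymous/missense for substitutions via
codon lookup, frameshift/inframe by indel length, `non-coding` outside the
CDS); there is no UTR/splice-site model and no alternative genetic codes.
Genotype likelihoods are out of scope — zygosity is a threshold rule on the
read fraction, not a caller. Multi-sample VCFs use one sample at a time.
The dbSNP catalog reader is build-agnostic and matches purely on normalized
keys; it does not attempt liftover between genome builds.
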