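---
title: "Consensus read generation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus read generation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensr)
```

## The problem

Deep sequencing of low-input DNA — circulating tumor DNA being the extreme
case — relies on PCR amplification, so most read pairs are duplicates of a
much smaller set of original fragments. Treating duplicates as waste (mark
and drop) discards exactly the information that makes low-frequency
variant calling possible: a substitution seen in *every* duplicate of a
fragment is evidence of a real variant, while one seen in a single
duplicate is almost certainly a library or sequencing error. `consensr`
therefore merges each duplicate cluster into one consensus read pair and
uses the disagreement structure, base qualities and the reference genome
to decide every base.

Cell-free DNA makes position-only clustering unreliable: fragments peak
near 167 bp, so at 10,000× depth distinct molecules frequently share both
endpoints. Unique molecular identifiers (UMIs) — random barcodes ligated
before amplification — disambiguate them, and the pipeline uses them
whenever the read names carry them.

## Clustering model

**Position keys.** A read pair's fragment key is
`(chrom, left_pos, right_pos)`: the minimum aligned start and the maximum
aligned end (0-based, inclusive right edge) over the two mates, counting
only reference-consuming CIGAR operations. Internally all coordinates are
0-based (half-open for intervals); SAM text is converted at the boundary.
This removes the ambiguity of "leftmost/rightmost mapping position", which
has no fixed convention across tools.

**Streaming release.** Input must be coordinate-sorted (declared in the
header and verified record by record). Because pairs complete in order of
their left positions, a position group can be released for consensus
processing as soon as the current read starts past the group's right edge;
finished records then wait in a position-keyed queue and are written once
the *watermark* — the least position any still-open group or half-joined
pair could still produce — passes them. One pass, no temporary files, no
re-sort, and output order was verified identical to `samtools sort`.

**UMI clustering.** UMIs arrive as the last `:`-separated field of the
read name (optionally prefixed `UMI_`), the convention of UMI-moving
preprocessors. A dual UMI `A_B` and its reciprocal `B_A` are the two
strands of one fragment, so both map to the canonical
`min(A_B, B_A)` and merge; the two orientation counts are kept and
reported on the consensus read (`fs`/`rs` tags). Within a position group,
canonical UMIs are ranked by member count (ties lexicographic) and each
joins the first *seed* within `umi_tolerance` mismatches (Hamming; for
duals, the better of the direct and swapped part alignments; `N` counts
as a mismatch). Merging is deliberately **non-transitive**: distance is
always measured to the seed, so errors cannot chain unrelated UMIs
together through intermediates, and the result is deterministic
regardless of input order. Frequency-aware directional networks
(UMI-tools style) are out of scope; with the tolerance of 1 and typical
UMI lengths, the greedy partition differs only in pathological cases.

## Scoring and consensus

Every base starts at `initial_score = 6`. Mate overlap is the one place a
single pair carries internal replication, so it is scored first: where the
two mates cover the same reference position, agreement raises both bases
to `agree_bonus = 8`; disagreement keeps `disagree_keep = 3` on the
strictly higher-quality base and drops the other to `disagree_drop = 0`
(quality ties drop both — no evidence either way). Scores are then summed
per column and base across the cluster, and each column is called:

1. **Dominant base** — a unique base holding at least
   `dominant_fraction = 0.8` of the column's total score is called, with
   quality equal to the best Phred seen among its carriers.
2. **Reference fallback** — otherwise, if any read carries the reference
   base at Phred ≥ `high_qual = 30`, or every covering base is below
   `moderate_qual = 15`, the reference base is called at `moderate_qual`.
   A base discordant with the reference is a priori more likely to be an
   error, which is what this asymmetry encodes; the preference is
   implemented as this fallback order rather than a numeric down-weight.
3. **Unresolved** — the top-scoring base (reference wins ties, then
   alphabetical) at Phred 2, explicitly flagging the column as
   low-confidence. A column with no score at all (all `N`) yields the
   reference base at Phred 2.

Insertion and soft-clipped columns have no reference base; rules 2 and 3
run with the fallback disabled.

The numeric schema (8/3/0, Q30/Q15, 0.8) is this package's own default and
every value is a `scoring_schema()` argument. The values were chosen so
that a single disagreeing duplicate cannot outvote two agreeing ones
(12/18 < 0.8 ≤ 24/30) and so that mate-confirmed bases (8) outrank
unconfirmed ones (6), which outrank overlap losers (3, 0).

**Template and heterogeneous CIGARs.** The consensus pair inherits name,
flags, positions, CIGARs from the member with the highest summed mate
MAPQ (ties: smallest name — deterministic, favors the best mapping).
Members whose CIGAR or position differs from the template's are excluded
from scoring and counted in the report rather than realigned: indel
realignment inside a deduplicator adds far more failure modes than the
handful of excluded reads justifies. A cluster whose members all disagree
with the template (impossible when the template is itself a member, but
kept as a guard) emits the template unchanged.

**Filtering.** Clusters below `min_supporting_reads` are dropped and
counted. The default of 1 keeps everything; 2 is the documented
recommendation for ultra-deep data, where fragments without any PCR
duplicate carry no error-suppression evidence.

**Orphans and passthrough.** Unmapped, secondary and supplementary
records, and paired reads whose mate is unmapped, on another chromosome
or never arrives, pass through byte-identically and are counted as
orphans where applicable. They are never merged: a lone read would bypass
pair scoring entirely.

## Reports

The JSON report has a fixed schema (`summary`, `pre_filtering`,
`post_filtering`, `duplication_histogram`, `coverage`, `bed_regions`,
`options`, `version`); undefined rates are `null`, never `NaN`, and
histogram keys are ascending cluster sizes. Mismatch rates are computed by
direct comparison against the reference FASTA, not from MD tags — consensus
reads have no regenerated MD tags, so direct comparison is the only way the
pre/post numbers are commensurable. The HTML report is a single
self-contained page: it embeds the JSON model verbatim and renders the
figures from it with a small inline SVG charting layer (hover values,
chromosome selector), so the two formats cannot disagree and the file
views offline.

## The simulator, and what passing tests mean

`simulate_fixture()` emulates the data this tool is built for: a uniform
random reference; fragment lengths normal around the cfDNA peak
(mean 167 bp, sd 10, clipped below at the read length); uniform fragment
positions (distinct keys by default); duplicate counts
`1 + Poisson(dup_mean − 1)` so every fragment is observed; proper FR
pairs with all-M CIGARs; i.i.d. substitution errors; a two-level quality
model (Q36 with a 5% fraction of Q11 by default); and single or dual UMIs,
dual duplicates alternating reciprocal orientation. Ground truth
(error-free sequences, duplicate counts, planted variants) is written as a
JSON sidecar.

It deliberately does **not** model indels, quality-by-cycle decay,
strand-specific error signatures, adapter artifacts, GC-biased coverage or
mapping ambiguity. Passing tests therefore demonstrate the correctness of
clustering, scoring, consensus arithmetic and stream ordering — not
performance on real instrument data, where heterogeneous CIGARs (excluded
members) and non-uniform errors will dilute, though not structurally
change, the error-suppression ratios measured here.

Validation problem sizes, chosen to exercise every code path while keeping
the suite quick: oracle equivalence against an independently written
brute-force score-table implementation on 500 random clusters (≤ 6
members, reads ≤ 20 bp); error suppression on 1,000 random clusters
(duplication ≥ 3, 1% error, 150 bp reads) requiring improvement in ≥ 99%;
end-to-end fixtures of 200–1,000 fragments; 50 randomized fixtures for
sortedness and partition properties.

## Numerical and degenerate-input choices

- Phred qualities are capped at 93 (SAM printable range); consensus
  qualities are the carrier maximum (dominant), `moderate_qual`
  (reference fallback) or 2 (unresolved).
- Chromosome order is the BAM header order; the (chrom, position) total
  order is encoded exactly in doubles (`idx · 2³² + pos < 2⁵³`).
- Empty inputs are valid everywhere: a header-only SAM produces a
  header-only output and a zeroed report with `null` rates.
- Duplicate primary alignments for one read name, unsorted input, a BAM
  chromosome missing from the FASTA, and `end ≤ start` BED lines are
  fatal, with the offending record or line named.
- Mixed UMI presence within one position group is fatal rather than
  silently split: it always indicates broken preprocessing.

## Limitations

Single-end data, CRAM, and consensus across reads with `N` CIGAR
operations are unsupported (such records pass through). Indel consensus
across heterogeneous CIGARs is not attempted. Duplex two-stage calling
(per-strand consensus, then strand comparison) is out of scope — strand
orientation counts are reported so downstream tools can filter on them.
The implementation holds each chromosome's open state in memory; the
streaming release keeps this small for sorted input, but a pathological
file with massive position ties will grow the open-group map.
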