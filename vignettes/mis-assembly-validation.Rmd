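---
title: "Validating mis-assemblies with reference alignments and paired-end reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating mis-assemblies with reference alignments and paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misasm)
```

## The problem and the model

A draft assembly differs from a reference genome for two reasons that
demand opposite responses: assembly errors (misjoins, erroneous
insertions, erroneous deletions), which should be corrected, and
structural variation between the sequenced organism and the reference
strain, which must be left alone. Alignment alone cannot tell the two
apart; read evidence alone miscalls unevenly covered but correct
sequence. `misasm` therefore treats alignment differences as
*hypotheses* and the paired-end reads as the *test*: reads were sampled
from the true genome, so a region that is assembled correctly — however
much it differs from the reference — looks locally normal to its reads
(even coverage, unanimous pileups, concordant inserts), while a
mis-assembled region cannot, because no true genomic fragment spans the
artificial junction.

The pipeline has three stages.

**1. Non-redundant chaining.** All alignments of a scaffold are reduced
to one ordered chain. A uniquely aligned scaffold keeps its single
segment. Otherwise, after discarding segments whose scaffold interval is
contained in another's, the chain starts at the highest-scoring segment
and is extended toward the 3′ and then the 5′ end; at each step the
candidate whose overlap or gap with the chain end is smallest is chosen,
provided it is at most `max_adjacency` (1 kbp); when no candidate is
that close, the one with the globally smallest overlap/gap is admitted.
Ties on score prefer the longer, then the leftmost segment; ties on
overlap/gap prefer the higher score. These tie-breaks are our own
(the selection rule needs determinism for testing); they only matter for
degenerate inputs.

**2. Difference classification.** For adjacent chained segments with
scaffold gap $g_s$ and reference gap $g_r$ (signed; negative =
overlap):

* different reference sequence, opposite strands, $g_r$ larger than
  `misjoin_distance`, or $g_r < -$`max_adjacency` (order inconsistent
  with strand) → **misjoin**;
* $g_s - g_r >$ `indel_min` → **middle insertion** of estimated size
  $g_s - g_r$; the reverse → **deletion**;
* smaller discrepancies are alignment jitter, absorbed silently.

Unaligned scaffold prefixes/suffixes longer than `end_min` and entirely
unaligned scaffolds are treated as insertions of novel sequence. A
difference intersecting a run of ≥ `gap_run_min` Ns is a *gap report*:
scaffold gaps reflect missing read coverage, are normal, and are never
corrected.

**3. Validation.** Every difference receives a breakpoint region
$[M_L, M_R)$ and an evidence bundle, and exactly one verdict:
`ERROR_MISJOIN`, `ERROR_INSERTION`, `ERROR_DELETION`, `CORRECT_SV`,
`WARNING`, or `GAP_REPORT`.

## Evidence features and their thresholds

All thresholds are strict inequalities, exactly as the rules state
them, and all are exposed through `misasm_config()`.

| feature | definition | threshold |
|---|---|---|
| disagreement | pileup column with majority fraction below 0.8 at depth ≥ `min_depth` | majority < 0.8 |
| coverage anomaly | 50-bp sub-windows of the region (extended by one read length per side) vs the scaffold mean | > 1.5× (high), < 0.5× (low), ≥ 2 windows |
| single-cell variant | same windows vs mean ± 1.5 sd of the scaffold's 50-bp window coverages | ≥ 2 windows |
| zero coverage | any base of the region proper at depth 0 | — |
| multi-align ratio | multi-placed fraction of reads overlapping the region | > 0.1 |
| discordant pair | not inward-facing FR, or \|fragment − μ\| > 3σ, or mates on different scaffolds | ratio > 0.1; max over 500-bp sub-regions for long regions |
| fragment-size test | mean fragment of pairs spanning the region vs μ and the estimated indel size | \|Δ − est\| < 2σ |
| disagreement rate | disagreements per kbp of region | > 1 |

The fragment size of a pair is the distance between its two 5′ read
ends; a pair belongs to a region when its fragment interval overlaps
it. Membership by fragment interval (rather than read intervals) is our
reading of "pairs in the region" — it lets pairs that straddle a
junction without touching it still testify about it, which is exactly
the signal the insert-size tests rely on.

Verdict rules:

* **misjoin**: error iff (abnormal high/low/zero coverage or > 1
  disagreement) or multi-align ratio > 0.1. Misjoins arise from
  collapsed repeats, so the junction attracts reads from both repeat
  copies: multi-placed reads are the signature.
* **middle insertion**: with ≥ `min_span_pairs` spanning pairs and
  \|(span mean − μ) − est\| < 2σ, error iff at least two of
  {disagreements ≥ 1, low coverage, discordant ratio > 0.1}; without a
  fragment match (insertions longer than the read length leave no
  spanning signal), error iff > 1 disagreement/kbp.
* **deletion**: mirror image, with the coverage clause widened to
  high/low/zero.
* **end insertion / unaligned scaffold**: error iff any disagreement or
  zero-coverage base; the correction is an end trim.
* **SV classification** for everything unvalidated: `CORRECT_SV` iff no
  coverage anomaly, zero disagreements and discordant ratio < 0.1;
  otherwise `WARNING`. A region with fewer than `min_region_reads`
  reads and no spanning pairs is always a warning — absence of reads is
  not evidence of correctness.

Misjoin margins are trimmed outward past contiguous pileup columns
whose majority base contradicts the scaffold (alignment tails reaching
into the wrong repeat copy), capped at `trim_cap` = 200 bp per side; the
cap is ours, since unbounded trimming could consume a flank.

## Corrections

A validated misjoin splits its scaffold, removing $[M_L, M_R)$ from
both pieces — the region is the mis-collapsed repeat whose two true
copies each live elsewhere, so neither piece can keep it with known
coordinates. Validated end insertions are trimmed. Middle indel errors
are reported but not edited: splicing sequence in or out without local
reassembly would fabricate bases. Fragments below `min_out_len` =
200 bp are dropped as unusable downstream. Calls are matched to a truth
table by scaffold, kind class and breakpoint overlap within
`match_slop` = 100 bp (breakpoint estimates wobble by up to a read
length).

## What the synthetic scenarios emulate

`simulate_scenario()` builds the complete evaluation design: an i.i.d.
random genome (default 1 Mbp — large enough that scaffolds dwarf the
insert size while the full pipeline runs in well under a minute per
stage on one CPU; the bacterial-genome scale remains a parameter),
scaffolds carrying injected errors, a reference carrying the
six-modification SV preset (one 1-kbp duplication, one relocation —
default 20 kbp at this genome scale — two insertions of 70/30 bp, two
deletions of 70/30 bp, together producing exactly eight expected
differences, three of them from the relocation's junctions), and 50×
paired-end reads drawn from the *true* genome with Gaussian inserts
(μ = 368, σ = 61, 100-bp reads, 0.5% base error).

Misjoins are constructed the way assemblers create them: a 500-bp
repeat is planted at two loci 30 kbp apart; the mis-joined scaffold
runs up to the end of the first copy and resumes after the second,
while the intervening sequence (ending in the second copy) becomes its
own companion scaffold. Both repeat copies are therefore present in
scaffold space, reads from either copy have two equal-best placements,
and the multi-align ratio at the junction rises for the same reason it
does in real data — the evidence is generated, not asserted.

Injected error sizes are fixed design choices: middle insertions
250–450 bp and end insertions 200–500 bp (repeat-expansion scale, large
enough that the inserted novel sequence produces zero-coverage windows
and insert-size shifts beyond 3σ), deletions 110–180 bp. The deletion
range is bounded above by spanning-pair geometry: a pair can only
testify about a deletion if its fragment contains both 100-bp reads
*plus* the deleted span, so deletions beyond roughly μ − 2·read length
leave fewer than `min_span_pairs` spanning pairs and the fragment-size
test starves.

What the generator does **not** emulate: platform-specific error and
quality profiles, PCR duplicates, chimeric fragments, indel sequencing
errors, and the amplification bias of single-cell MDA data (the
single-cell thresholds are exercised on constructed coverage profiles
in the tests instead). Passing tests therefore demonstrate the
machinery and the rule arithmetic under clean sampling assumptions, not
performance on real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open on the forward strand everywhere
  inside the package; conversion happens only at I/O boundaries (blast6
  is 1-based inclusive with reversible subject intervals; PAF and the
  internal convention agree).
* Zero-width junction regions (a clean deletion breakpoint) are widened
  to 1 bp so evidence can be evaluated; coverage windows extend the
  region by one read length per side so junction ramps are visible.
* The scaffold mean coverage excludes N-runs, which would otherwise
  depress the mean and fabricate high-coverage flags.
* Multi-placed reads are assigned uniformly at random among their
  equal-best placements (seeded through the R RNG) so repeat regions
  keep coverage instead of collapsing to zero.
* `estimate_library()` discards fragments outside [1, 5×median] before
  taking mean and sd, and refuses to estimate from fewer than 1000
  proper pairs.
* Empty inputs (no alignments for a scaffold, zero verdicts, an empty
  pair table) flow through as empty chains, unaligned-scaffold
  differences, and identity corrections rather than errors.

## Known limitations

* **Deletion recall under short-read end-to-end placement.** The
  built-in read aligner places reads full-length with at most
  `max_mismatch` mismatches. Around a deletion junction the observed
  fragment of a mapped pair can never be shorter than 2×read length;
  with 100-bp reads and μ = 368, σ = 61 that floor (200) exceeds
  μ − 3σ = 185, so size-discordant pairs cannot exist, and the
  junction's disagreement columns reach `min_depth` only intermittently
  at 50×. Mid-size deletions therefore sometimes retain only one of the
  required two supporting features and are reported as warnings rather
  than validated errors. They are never classified `CORRECT_SV` — the
  junction coverage ramp always fails the cleanliness test — so
  precision and SV classification are unaffected; recall of deletions
  is the price of the conservative two-of-three rule. A clipping or
  split-read aligner would recover the short-fragment signal.
* Breakpoints are alignment-derived and wobble by up to a read length;
  no split-read refinement is attempted.
* The pileup is not base-quality aware and duplicates are not marked.
* Corrections never re-scaffold or fill gaps; middle indels are
  reported but left in place.
* The naive long-sequence aligner assumes exact shared k-mers outside
  difference loci, which holds for the synthetic designs but not for
  diverged real genomes; real scaffolds should be aligned externally
  and supplied as blast6/PAF.

## A small worked run

```{r example, eval = FALSE}
sc <- simulate_scenario(seed = 101, genome_len = 300000, n_misjoin = 1,
                        n_ins_mid = 2, n_ins_end = 1, n_del = 1,
                        svs = NULL, depth = 40)
res <- run_misasm(sc$scaffolds, sc$reference,
                  reads = list(read1 = sc$read1, read2 = sc$read2),
                  insert_mu = 368, insert_sd = 61, truth = sc$truth)
res$verdicts
write_outputs(res, tempfile("misasm"))
```

The full-scale designs (the 27-error scenario and the eight-difference
SV-only scenario, both at 1 Mbp) are exercised by
`tests/testthat/test-acceptance.R` and recomputed from scratch by
`scripts/acceptance.R`.
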