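---
title: "Detecting tandem duplications from split reads by pattern growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tandem duplications from split reads by pattern growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemdup)
```

## The problem

A tandem duplication (TD) copies a genomic segment immediately after
itself. In short-read data a TD leaves a characteristic split-read
signature: a read sequenced across the novel junction aligns only
partially to the reference, with the remainder soft-clipped, because the
junction joins the *end* of the duplicated unit back to its *start*.
General-purpose structural-variant callers frequently report such events
as insertions or miss them entirely, particularly below the read length.
`tandemdup` detects TDs from 10 bp up to multi-kilobase scale at single
nucleotide breakpoint resolution, using only split-read evidence (no
read-depth or discordant-insert signal), and ships a simulator and
evaluator so the whole pipeline can be exercised against planted truth.

## Signal extraction

From a coordinate-sorted BAM the caller keeps read pairs in which
exactly one read is a reliable **anchor** — primary, mapped with a
single aligned-match run (`Nn M` CIGAR), mapping quality strictly above
`anchor_quality` (default 30) — while its mate is soft-clipped or
unmapped. Hard-clipped mates are skipped because their stored sequence
is incomplete, and pairs mapping to different contigs are not
considered. The **anchor point** is the 3' reference coordinate of the
anchor. Mapped mates are stored reference-forward in the BAM already;
unmapped mates of forward anchors are reverse-complemented so that
every mate sequence reads left-to-right along the reference.

One geometric point deserves emphasis, because it determines where the
search windows go. Consider a junction-spanning mate: its 5' part
matches the reference ending at the unit's end (`td_end`) and its 3'
part matches starting at the unit's start (`td_start`). The anchor of
that mate sits within about one insert size of the junction *in donor
coordinates*. Working through the fragment geometry, the anchor of a
forward-strand pair lands upstream of `td_start`, while the anchor of a
reverse-strand pair lands inside (or beyond) the duplicated region,
downstream of `td_start`. Consequently the step-2 search window of
width `2 x insert_size` lies **downstream** of the anchor point for
forward anchors and **upstream** of it for reverse anchors — and for
TDs longer than the insert size only the reverse-anchor configuration
exists at all. A design that mirrored the entire problem
(reverse-complementing mate and window) would place the window on the
wrong side for those events; the implementation therefore mirrors only
the window placement and always works on the reference-forward mate.

## Pattern growth

Given the mate and a reference window, substrings are grown from a read
end one base at a time — suffixes when growing from the 3' end,
prefixes from the 5' end — and matched exactly against the window. The
set of match positions can only shrink as the substring grows, which
the engine (in C++) exploits: one scan seeds the position set, then
each extension filters it, so a window of size w costs O(w + total
surviving positions). Growth stops at the first length with zero
occurrences or when the read is exhausted. The **minimum unique
substring** is the shortest grown substring with exactly one occurrence
and length at least `min_distance_to_the_end` (default 8 bp; shorter
matches are indistinguishable from chance hits in windows of a few
hundred bases); the **maximum unique substring** is the longest grown
substring still occurring exactly once. Matching is exact: sequencing
errors terminate growth rather than being absorbed, and error-bearing
reads are instead rejected later by the reconstruction gate, leaving
the consensus to error-free reads.

## Size-stratified detection

TD lengths are classified against the read length `L`: `small` below
`L/2`, `medium` between `L/2` and `L`, `large` above `L` (both
boundaries assigned to the wider class so every length has a class).
Detection per signal:

1. **Step 2** grows the mate's 3' end in the window of `2 x
   insert_size` at the anchor point, giving the maximum match `m3`
   whose mapped start `p` estimates `td_start`.
2. **Step 3** grows the 5' end in a region that encodes the size
   hypothesis: `[p, p + max_td_size)` for large (default
   `max_td_size` 10 kb, covering the largest simulated events with
   headroom), or `[p - max_span_size, p + max_span_size)` for
   medium/small (default `max_span_size` = read length, which covers
   every sub-read-length geometry centred on `p`). The small attempt
   additionally requires match start positions strictly below `p`; for
   a short duplication the 5' match straddles `p`, and the restriction
   prevents the search from sliding onto the second copy.
3. **Combination.** With `j` the leftmost read offset covered by `m3`
   and `k` the rightmost covered by `m5`, the pair is accepted only
   when `j <= k` — the two matches together explain the complete read.
   Both maxima are grown independently, so junction micro-homology
   lets each extend a few bases past the true junction; the homologous
   run shows up as the overlap `k - j` of the read spans, and

   `td_len = (m5.ref_end - m3.ref_start) - max(0, k - j)`

   is invariant to that over-extension (and to window truncation).
   Placing the junction at the leftmost consistent read offset makes
   the reported interval the left-shifted canonical placement
   directly; a final normalisation step slides it through any homology
   extending beyond the read's evidence. Large and medium candidates
   are accepted on reconstruction alone. Small candidates must pass
   the copy check: the `td_len` bases before the junction parse and
   the `td_len` bases after it — the two inferred copies, cut at the
   *same* parse so homology cannot shift them out of frame — must lie
   within edit distance strictly below 4 (Levenshtein, via
   `utils::adist`). Reads that do not contain both complete copies
   cannot perform the check and yield no candidate.

   The three size hypotheses are attempted in order large, medium,
   small, and each read pair contributes at most one candidate.

## Support and merging

Candidates are grouped by exact breakpoint identity; support counts
distinct read names, and groups with at least `min_support` (default 2)
become calls. Remaining redundancy — the same event recovered by
different strategies or with error-shifted boundaries — is removed by
clustering calls that overlap by at least one base and satisfy the
strict length criterion `|len_i - len_j| < 2 * min(len_i, len_j)`,
transitively, then keeping each cluster's most frequent member (highest
support; ties broken by smaller start, then larger length, for
deterministic output). The representative keeps its own support rather
than absorbing the cluster's, and clustering is iterated to a fixed
point, so the operation is idempotent. Calls are written as VCF 4.2
(`<DUP:TANDEM>` with `SVTYPE`, `END`, `SVLEN`, `SUPPORT`) or BED4.

## The simulator and what it does (not) emulate

`simulate_genome` draws an i.i.d. nucleotide sequence at a chosen GC
fraction (default 0.41, the approximate GC content of a large human
chromosome) with homopolymer runs capped at 8 bp. `plant_tds` places
non-overlapping unit intervals at least two insert sizes apart and one
insert size from the contig ends and builds the donor with each unit
duplicated in place; the piecewise-linear donor-to-reference map is
retained. `simulate_reads` is a wgsim-style paired-end simulator:
15x coverage, 2x100 bp reads, Normal(400, 50) fragments and 0.5%
per-base substitution error by default — the benchmark's study
conditions. `emulate_alignment` places each read at its true position,
soft-clipping the shorter reference-consistent flank of
junction-spanning reads, which isolates the caller's logic from aligner
behaviour and gives exact ground truth; the `bwa mem` path exercises
the pipeline a real user runs.

A uniform random reference has no segmental duplications, tandem-repeat
arrays or low-complexity tracts, which in real genomes both generate
TD-like alignment signals (false positive pressure) and destroy
substring uniqueness (false negative pressure). Perfect scores on the
emulator path therefore demonstrate the correctness of the breakpoint
arithmetic, not field performance; the aligner-based benchmark adds the
clip-versus-gap behaviour of a real aligner and sequencing error, but
still underestimates the difficulty of repeat-rich genomes.

## The scaled benchmark

The packaged benchmark (`run_td_benchmark`, also driven by
`scripts/acceptance.R`) plants 14 length classes
{10, 15, 20, 25, 50, 75, 100, 150, 250, 500, 1000, 2000, 5000, 9000}
bp, 25 TDs per class, on one 5-Mb reference, simulates 15x paired-end
reads at the study conditions, aligns with `bwa mem`, calls at default
parameters and matches calls to truth by 50% reciprocal overlap
(one-to-one, greedy). Because all classes share one genome, a false
positive has no intrinsic class; unmatched calls are attributed to the
class nearest in log-length before computing per-class precision.
Problem sizes were chosen so the whole benchmark runs in a few minutes
on a single core while keeping 25 Bernoulli trials per class.

Two behaviours of this benchmark are worth understanding rather than
being surprised by:

* **Sub-30 bp recall is aligner-limited.** `bwa mem` represents a
  short duplication as an insertion (`I` CIGAR) when the junction falls
  mid-read, and such mates are not split reads, hence not signals. The
  clip-versus-gap trade-off only favours clipping when the junction
  lies within roughly 20 bp of a read end, leaving on the order of
  three usable junction reads per 10-bp TD at 15x — so per-class
  recall there is governed by small-number statistics, and class
  metrics for the shortest units fluctuate by several points between
  seeds.
* **Correlated duplicate fragments can validate a spurious
  candidate.** Two identical error-free junction reads (same fragment
  start) find the same chance-unique 5' match in the large search
  window and can jointly clear the support threshold. This is rare
  (a few calls per several hundred events) and is the dominant false
  positive mode on random sequence.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; VCF conversion happens
  only in the writer.
* Search windows are clamped to contig bounds; a window that clamps to
  zero length yields no matches rather than an error.
* A mate that matches the reference along its entire length produces
  identical 5' and 3' maxima; the overlap-corrected length is then
  non-positive and the pair is discarded, so error-clipped but
  reference-consistent reads cannot become length-`L` artefacts.
* `estimate_insert_size` is the median absolute template length over
  the first 100,000 proper pairs; an explicit `insert_size` overrides
  it, and a BAM without proper pairs is an error instructing the user
  to supply one.
* Ambiguity codes other than N are rejected at reference load time;
  they do not occur in the simulation and indicate upstream problems.
* `simulate_genome` refuses lengths below 100 bp; every downstream
  stage assumes a genome much longer than the insert size.

## Known limitations

* Split-read evidence only: no genotypes are emitted, and events whose
  junction-spanning reads all fail to clip (very short TDs aligned as
  insertions) are invisible.
* Only intra-contig pairs are considered.
* Multi-copy expansions surface as a single TD call; the copy count is
  not resolved.
* Exact matching in the growth search trades sensitivity on
  error-bearing reads for breakpoint precision; at 0.5% error and 15x
  this costs a few points of recall, concentrated in the shortest
  classes.
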