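---
title: "Promoter activity screening from 5' RACE-Seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter activity screening from 5' RACE-Seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racescreen)
```

## The screen

Phage RNA polymerases (T7, SP6) are the workhorses of in vitro transcription
(IVT). Their core promoter (-17..-1, with transcription starting at a +1 G)
is well characterized, but the *initially transcribed region* (ITR) - the
first ~8 transcribed nucleotides, inside the extended initiation bubble -
also modulates output. A massively parallel way to measure this is to
transcribe a template pool whose +2..+16 region is randomized, read out the
5' ends of the resulting RNAs by 5' RACE sequencing, and compare each
motif's read frequency with its frequency in a directly sequenced aliquot of
the template pool (the *background library*). The ratio

$$\mathrm{rel}(m) \;=\; \frac{c(m)/C}{b(m)/B}$$

(read count over total, divided by background count over background total)
is the motif's relative transcriptional activity; an unbiased motif has
rel = 1. `racescreen` implements this screen end to end as *simulation +
analysis*: a generative model of the library chemistry with known ground
truth, the exact read-filtering cascade, and the motif statistics - plus
promoter design utilities that consume the resulting motif tables.

## Generative model

`simulateTemplateLibrary()` draws a finite pool of template molecules whose
+2..+16 bases are i.i.d. per position from a configurable synthesis bias
(defaults: uniform, $10^{10}$ molecules, roughly the molecule count of a
10 ng short dsDNA pool). Because positions are independent, the pool is
stored factorized as multinomial counts over the +2..+8 7mer and the +9..+16
8mer; every downstream statistic depends only on these marginals, and the
factorization is what makes realistic library sizes tractable.

`buildActivityModel()` sets the latent truth. Transcription weight over
+1..+8 factorizes into:

* a **+2/3 dinucleotide class factor** - in `t7_like` mode, 1.5 per G in the
  dinucleotide, so G-triplet starts (GGG) are strongest. This value is a
  package choice: it reproduces the qualitative class ordering of T7 screens
  with a mid-sized (2.25x) effect; no published numeric class effect exists.
* a **+4..+8 ITR factor** - 1024 values, exactly log-uniform (equally spaced
  in log space after a rank transform) with max/min equal to `foldRange`
  (default 5). A uniform random score plus an additive AT-content tilt
  decides *which* motifs land high, so AT-rich ITRs tend to be strong, as
  observed for T7; the rank transform keeps the marginal exactly
  log-uniform, which makes the recovered fold range interpretable.
* `sp6_like` mode instead spreads 16 log-spaced class levels over
  `foldRange` (A-rich dinucleotides highest) and sets the ITR factor to 1 -
  SP6 output is determined by +2/3 only.

5' end events: transcripts starting on a G triplet receive one extra
(slipped) G with probability 0.79 and two with probability 0.02; other
classes slip with probability 0 (slippage requires a G run; published
per-class values exist only for the G-triplet class). Independently of
class, reverse transcription appends one non-templated C with probability
`pRtC` (default 0.05). On the antisense Read1 both events are visible as
extra Cs after the C complementary to the +1 G; the generator caps visible
extras at 2 because the structural filter's whitelist cannot represent more.

`makeReads()` emits the paired reads:

```
Read1 (35 nt): [revcomp(+16..+2), 15 nt][C][0-2 extra C][poly(A) fill]
Read2 (35 nt): [UMI, 5 nt][constant fill]
```

PCR duplication re-emits a molecule's pair (identical 15mer and UMI) with
probability `dupRate` (default 0.1 - a realistic duplicate load; the
published screens do not report theirs). Substitution sequencing errors are
then applied independently per sequenced copy at `errorRate` (default
0.001/base), as a binomially drawn number of error events placed uniformly
over the (read, position) grid with at most one event per base. Qualities
are constant `"I"`: nothing downstream consumes them. An optional
*dark-cycle loss* drops reads whose Read1 contains a G homopolymer, mimicking
the two-channel sequencer artifact that motivates homopolymer filtering; it
is off by default and the homopolymer flag is applied regardless, as a
structural exclusion.

What the generator does **not** emulate: indels, quality-dependent errors,
PCR sequence bias beyond duplication, abortive transcripts shorter than the
read, and UMI-specific amplification bias. Tests passing on these
simulations therefore validate the pipeline's statistical machinery and its
contracts, not every artifact of real sequencing data.

## Filtering cascade

`processRun()` applies, in order: (1) contaminant removal by exact k-mer
lookup (k = 21, both strands - an in-repo replacement for read mapping;
disabled when no contaminant is configured); (2) removal of duplicate
15mer-UMI combinations (first occurrence kept; the order relative to the
structural filter is configurable via `dedupAfterStructure`); (3) the
structural 5' end filter: position 16 must be C, positions 17-18 one of
AA/CA/CC (0/1/2 extra Cs), followed by a poly(A) check; (4) reverse
complementation of the 15mer to RNA sense, rejecting reads with N; (5) a
constant-sequence filter that discards reads whose +2..+11 10mer lies within
Hamming distance 1 of any window of the configured constant sequences
(template backbone, adapters), both strands - implemented by hashing the
radius-1 neighborhood of all windows.

Numerical choices worth stating:

* **Poly(A) rule.** The protocol only requires the extra-C block to be
  "followed by a poly(A) sequence"; the package makes this precise as: at
  least 90% A within the 10 bases starting at the first tail A (position
  17, 18 or 19 for AA/CA/CC). Both knobs are configuration keys. Note a
  consequence of the whitelist: a read with three or more 5' events shows
  `CC` at 17-18 and its surplus Cs fall into the poly(A) window, so such
  reads pass only while the window still clears the 90% threshold.
* **Positions are 1-based in reads, TSS-coordinates (+1, no zero) on the
  promoter** - mirroring how such protocols are written.
* **Stats telescope.** Every stage reports removed counts and
  `input = removed + accepted` holds by construction (validity-checked).
  N-containing 15mers are counted with the structural stage.

For deep simulated runs the package uses a streaming path: reads are
assembled and filtered chunk-wise inside a small C kernel without
materializing R strings, with all random draws taken in R in exactly the
order of the string-building path. The two paths are bit-identical on the
same seed (asserted in the test suite); 2 x 10^7 reads process in about two
minutes on one core.

## Motif statistics

`countMotifs()` pools reads by their sequence over any span within +2..+16
(the protocol's analyses use +2..+8 and +4..+8). `normalizeMotifs()` forms
the frequency-ratio relative abundance above. The background total is the
background library's own read total - the scale-invariant reading of
"divided by the corresponding counts in background libraries"; any global
rescaling of the background leaves rel unchanged. Motifs with fewer than
`minBg = 10` background reads are flagged and excluded from ranking: below
that the denominator's variance dominates. `flagHomopolymers()` excludes
motifs whose +1-prefixed sequence carries a run of >= 4 identical bases
(any base, by default). The exact homopolymer rule used in published screens
is not recoverable from their text, so the rule is fully configurable; the
default is one admissible reading that removes dark-cycle-biased motifs.

Ranks are dense, 1-based, by descending relative abundance, ties broken
lexicographically - deterministic by construction. Group summaries by +2/3
dinucleotide use type-7 (linear interpolation) quantiles with whisker bounds
at 1.5 IQR beyond the quartiles; `activityRange()` is the ratio of type-7
quantiles of rel (defaults 1% and 99%; (0, 1) gives max/min). Extra-G
fractions are reported per +1..+3 class with Wilson 95% intervals, and the
headline number is the fraction with *any* extra C, uncorrected for RT
C-addition - the per-class report makes the RT baseline visible in non-GGG
classes, where slippage is absent.

## Promoter design

`loadMotifTable()`/`scorePromoter()` look up the +4..+8 (or any configured
span) motif downstream of the core promoter consensus; designs not starting
GGG carry a context warning because ranks from a GGG-context table are not
directly comparable. `optimizeInsert()` enumerates *all* combinations of up
to 3 single-base insertions and 3 substitutions inside an editable window
(TSS coordinates on the evolving sequence), collapses duplicate outcomes to
their minimal edit count, and sorts candidates by rank, then edit count,
then sequence. This reproduces the design move of inserting a GA
dinucleotide at +3/+4 to improve a primer's ITR rank while keeping the
primer short. `assemblePrimer()` concatenates an AT-rich upstream element
(warning below 75% AT), the core, the ITR and a tail with TSS-coordinate
annotations. The core consensus ships as a default (canonical T7/SP6) but is
user-overridable, and the upstream element is a required user input - its
exact published sequence lives in oligo supplements, so the package does not
hard-code one.

## Problem sizes and what the checks mean

The package's acceptance-style tests run the full pipeline at the depths a
desk check affords, chosen once as study conditions: parameter recovery of
the 5-fold ITR effect at 2 x 10^7 reads (three seeds), replicate correlation
at 10^7 reads, null calibration at 10^7 reads, and extra-G recovery over 50
replicates of >= 10^5 G-triplet reads each (error-free, to isolate the 5'
event model from read-error leakage across classes). Background depth
defaults to foreground depth - the published screens used roughly 2.8x, but
equal depth is the neutral choice and the normalization is scale-invariant.
For the extra-G experiment the template bias fixes +2/+3 to G so that every
simulated read is informative for the G-triplet class.

Known limitations: relative abundances are ratio estimates without
shrinkage, so low-background motifs are excluded rather than stabilized; the
activity model factorizes class x ITR and cannot represent interactions
between +2/3 and +4..+8 (real data suggest combinatorial crosstalk); and the
constant-sequence filter slightly depletes specific 10mers from the
foreground only, a (tiny) asymmetry the null-calibration test bounds rather
than removes.
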