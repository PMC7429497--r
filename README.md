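# racescreen

Simulation and analysis of massively parallel promoter-activity screens read
out by 5′ RACE sequencing.

Phage RNA polymerases (T7, SP6) drive most in vitro transcription (IVT)
workflows — RNA synthesis, linear amplification for single-cell genomics,
biosensors. Beyond the well-characterized core promoter (−17..−1), the
*initially transcribed region* (ITR, roughly +1..+8) modulates transcriptional
output. A 5′ RACE-Seq screen measures this at scale: a template pool
randomized from +2 to +16 is transcribed in vitro, the 5′ ends of the
resulting RNAs are deep-sequenced (Read1 carries the randomized 15mer in
antisense orientation, Read2 a 5 nt UMI), and an aliquot of the untranscribed
pool is sequenced directly as a *background library*. Each motif m over a
position span (e.g. +2..+8) gets a background-normalized relative activity

    rel(m) = (count(m) / total reads) / (bg_count(m) / bg total)

so rel = 1 means "transcribed exactly as often as it was synthesized".

`racescreen` is for people building or analyzing such screens (and for
benchmarking their statistics). It provides:

* **synthetic screens with ground truth** — template synthesis bias,
  motif-dependent transcription weights (T7-like: +2/3 class × +4..+8 motif
  effects; SP6-like: +2/3 only), polymerase slippage (extra 5′ G on
  G-triplet starts: 79% one, 2% two), non-templated RT C-addition, poly(A)
  tailing, PCR duplicates, sequencing error, optional dark-cycle loss;
* **the exact read-filtering cascade** — contaminant k-mer filter, 15mer–UMI
  deduplication, the structural 5′-end filter (C at position 16, AA/CA/CC at
  17–18, poly(A) check), reverse complementation to RNA sense, and a
  Hamming-distance constant-sequence filter on the +2..+11 10mer;
* **motif statistics** — background-normalized abundances with
  low-background and homopolymer flags, deterministic ranks, position-wise
  composition, +2/3 dinucleotide group summaries, extra-G fractions with
  Wilson intervals, activity fold-ranges, replicate correlation;
* **promoter design** — scoring a promoter + ITR against a motif table and
  exhaustively searching small insertion/substitution budgets (e.g. the GA
  insertion at +3/+4), plus annotated primer assembly with an AT-rich
  upstream element.

Deep runs stream through a small C kernel (reads are generated and filtered
in chunks, never held as strings), so a 2 × 10⁷-read screen with matched
background processes in ~2 minutes on one core.

## Worked example

```r
library(racescreen)

model <- buildActivityModel("t7_like", foldRange = 5, seed = 7)
res <- runScreen(model = model, nReads = 2e6, nBackground = 2e6, seed = 7)
res
#> ScreenResult
#>                    stage   reads
#> 1                  input 2200298
#> 2    contaminant_removed       0
#> 3          dedup_removed  192368
#> 4       structure_failed    5154
#> 5           polyA_failed      69
#> 6 constant_match_removed    9730
#> 7               accepted 1992977

activityRange(res@table48, 0.025, 0.975)
#> [1] 4.517221
```

2.2 M read pairs went in (2 M molecules plus ~10% PCR duplicates); dedup
removed the duplicates, the structural filter dropped reads whose 5′ end
lost its expected layout to sequencing errors, and the constant filter
removed 15mers resembling library constants. The recovered +4..+8 activity
range (ratio of the 97.5% to the 2.5% quantile of rel) is ~4.5 for a
generating model whose ITR effect spans 5-fold. The strongest motifs are
AT-rich, as the model encodes:

```r
head(as.data.frame(res@table48)[order(res@table48@table$rank),
                                c("motif", "count", "bg_count", "rel_abundance", "rank")], 5)
#>  motif count bg_count rel_abundance rank
#>  TTATA  4035     1905      2.125574    1
#>  AATTT  3919     1908      2.061221    2
#>  TGAAT  3954     1927      2.059125    3
#>  ATATC  3847     1875      2.058963    4
#>  AATAC  3803     1869      2.041948    5

res@extraG[res@extraG$class == "GGG", c("class", "n", "frac_ge1", "frac_eq2")]
#>  class      n  frac_ge1   frac_eq2
#>    GGG 221237 0.8181362 0.05983176
```

82% of G-triplet-start transcripts show at least one extra 5′ C on Read1:
the 79% slipped-G rate compounded with the 5% RT C-addition baseline
(0.81 + 0.19 × 0.05 ≈ 0.819). Scoring and improving a promoter design
against the resulting table:

```r
tb <- res@table48
seq <- paste0("TAATACGACTCACTATA", "GGG", "TCGAG", "TT")
scorePromoter(seq, tb)                       # rank of the current +4..+8 motif
optimizeInsert(seq, tb, maxInsertions = 2)   # all <=2-insertion candidates, best first
```

A command-line front end over the same functions is at
`inst/scripts/racescreen.R`
(`simulate | process | analyze | design | run-all | fixture`).

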