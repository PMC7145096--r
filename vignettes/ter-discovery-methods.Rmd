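---
title: "Identifying telomerase RNA candidates: models and methods"
author: "TERscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying telomerase RNA candidates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TERscreen)
```

## The problem

The RNA subunit of telomerase (TER) carries a short template domain,
complementary to roughly 1.5 copies of the telomere repeat, that the
telomerase reverse transcriptase copies onto chromosome ends. Unlike the
protein subunits, TERs diverge so quickly at the nucleotide level that
homology searches alone rarely find them. A productive alternative is to
immunoprecipitate the telomerase ribonucleoprotein, sequence the associated
RNAs, and winnow the assembled transcripts down to those that (i) are
reproducibly enriched, (ii) are not fragments of known genes, (iii) can
actually template the telomere repeat, and (iv) have template-bearing
orthologs in related species. TERscreen implements that winnowing funnel for
the plant telomere repeat TTTAGGG, together with two companions: a
substrate-register model that predicts telomerase product-length differences
from substrate annealing positions, and a small likelihood-ratio helper for
branch-sites tests of selection on the telomerase protein subunits.

## Template permutations and scanning

A *permutation* of the repeat is a fixed-length window of the infinite
tandem repetition of the unit, indexed by the circular offset at which the
window begins. With a 7-nt unit there are 7 windows per length per strand;
over the template-length range 9–19 nt and both strands this yields
`2 x 7 x 11 = 154` distinct sequences:

```{r}
length(enumeratePermutations("TTTAGGG", 9, 19, both_strands = TRUE))
```

Scanning (`scanTemplates()`) reports *collapsed maximal matches*: maximal
runs of agreement between the subject and the infinite repetition in some
circular phase, per strand. Runs contained within a longer run on the same
strand are dropped, and reported lengths are capped at the enumeration
maximum (19 nt), so a perfect 21-nt triple repeat is reported once, from the
run start, at length 19. We chose run-based collapsing rather than raw
occurrence lists because the quantity of biological interest is the length
of the longest template domain, not the number of overlapping windows that
tile it; the raw occurrence list remains available with `collapse = FALSE`.
Matching is exact and case-insensitive; characters outside ACGT never match
and no IUPAC wildcard expansion is attempted, because the screen is defined
over exact windows of the repeat. Coordinates are 0-based half-open
internally and in match tables; GTF input/output uses the format's 1-based
closed convention.

## The candidate funnel

`runFunnel()` applies four stages in a fixed order, with per-stage
accounting (the order is part of the report contract even though the
expression and template screens commute mathematically):

1. **Expression.** Counts are converted to transcripts per million:
   per experiment, `rate = count / length_kb` and
   `TPM = 1e6 * rate / sum(rate)`. A transcript survives when its
   arithmetic mean TPM across *all* experiments (zeros included, missing
   treated as zero) is strictly greater than 1 — "over 1" is read as a
   strict inequality.
2. **Known-gene overlap.** Any candidate with at least 1 bp of exonic
   overlap with an annotated gene is discarded, on either strand by
   default (strand-restricted mode is available via
   `funnelConfig(stranded_overlap = TRUE)`), since an immunoprecipitation
   library cannot distinguish sense from antisense fragments of an
   annotated locus without additional evidence.
3. **Template domain.** Survivors need a collapsed template match of at
   least 9 nt on either strand.
4. **Conservation.** From a 12-column homology hit table, each relative
   species is marked *present* when it has a hit at E-value ≤ 1e-5, and
   *present-with-template* when the best such hit (highest bit score) has a
   subject sequence that itself carries a ≥ 9 nt template. Survivors need
   template-bearing orthologs in at least 3 relatives. "Ortholog" is
   operationalized as the single best-scoring passing hit per species —
   reciprocal-best checking is not attempted, which matches how bulk lncRNA
   conservation screens are usually run. The full subject sequence is
   scanned (not only the aligned region), since divergent template flanks
   may still align poorly while the template itself is conserved.

Final candidates are ranked by descending mean TPM, ties broken
lexicographically by id for determinism.

```{r}
ds <- generateDataset(syntheticConfig(seed = 1))
report <- runFunnel(ds)
report
```

## The synthetic data generator

`generateDataset()` emulates the *downstream products* of a telomerase RIP
study — assembled transcripts, a counts matrix, an annotation, ortholog
sequences with hit tables — never raw reads or alignments. Its defaults are
the study conditions under which the package validates itself:

* **20 experiments**, matching the pull-down design the funnel averages
  over.
* **1000 background transcripts** of 400–1500 nt, rejection-sampled so that
  no background transcript carries a ≥ 9 nt telomeric run on either strand.
  This is the desk-scale stand-in for the tens of thousands of features a
  real assembly produces; it keeps a full 20-dataset recovery study in the
  minutes range while leaving every decision in the funnel non-trivial.
* **Negative-binomial counts** (mean 100, size 10 per experiment) — the
  minimal statistical structure that makes a TPM filter meaningful; the
  original study used real libraries and specifies no count model.
* **A planted TER** carrying an 11-nt template (a realistic template-domain
  detection length between the 9-nt floor and the ~10.5-nt 1.5× repeat
  span) at a random position and strand, with counts enriched 50-fold to
  emulate immunoprecipitation.
* **One decoy per stage**: a low-expression transcript (mean count 0.1 on a
  5000-nt transcript, putting its expected mean TPM near 0.2 — clearly
  below threshold but not degenerately zero), a gene-overlapping
  transcript, an 8-nt short-template decoy, an 11-nt template carrying a
  central substitution, and a template-bearing transcript conserved in only
  2 relatives.
* **An 8-relative panel plus outgroup** with Brassicaceae-style names, each
  ortholog derived by per-site substitution at rate 0.1 with the planted
  template window shielded, and hit-table E-values far below (or, for the
  non-conserved decoy's remnants, above) the 1e-5 cutoff.

What the generator does *not* emulate: positional count correlation,
assembly fragmentation, multi-exon structure, alignment-dependent E-values,
or any RNA secondary structure. Passing the recovery tests therefore shows
that the funnel's logic and accounting are correct under its stated
assumptions — not that the thresholds are optimal for any particular real
library.

## The substrate-register model

In a TRAP assay, substrates of different lengths and 3′-end composition
yield product ladders whose offsets reveal where each substrate anneals on
the template. `predictRegister()` models annealing as contiguous
Watson–Crick pairing (A–U, T–A, G–C, C–G) of the substrate's 3′-terminal
nucleotides: among all registers in the template region, the one with the
longest contiguous 3′-terminal pairing wins, ties going to the register
closest to the template's 3′ end, where annealing initiates. Extension is
assumed processive to the template region's 5′ boundary, so the nucleotides
added equal the distance from the annealing site to that boundary; products
from two substrates then differ by
`(length + nucleotides_added)` difference modulo the repeat period,
giving the integer 0–6 scale for a 7-nt repeat. A substrate with no pairing
register returns a flagged no-anneal result rather than an error, mirroring
a blank lane. Mismatched pairing upstream of the 3′ terminus is ignored —
only contiguous terminal pairing counts — because terminal pairing is what
positions the catalytic site.

Observed ladders are digitized with `assignQuadrant()`: the interval between
two consecutive baseline bands is divided into seven bins,
`floor(7 * (band - lower) / (upper - lower))`, clamped to 0–6. Species
profiles (`buildProfile()`) are compared with a mean absolute difference by
default (Hamming mode treats the scale as categorical), and clustered with
a hand-implemented UPGMA (`upgmaCluster()`) whose tie-break — merge the
pair whose lexicographically smallest member labels sort first — makes the
topology deterministic under tied distances; `stats::hclust` with average
linkage is used as an independent cross-check in the test suite, not as the
implementation, precisely so both routes exist.

```{r}
tpl <- templateRNA("CUAAACCCUAAACCC")
ggg <- substrateOligo("N15-GGG", 18, "GGG")
tta <- substrateOligo("N15-TTA", 18, "TTA")
predictRegister(tpl, ggg)
predictProductDifference(tpl, tta, ggg)
```

## The branch-sites LRT helper

`branchSiteLRT()` takes the two model log-likelihoods as inputs (codon-model
fitting itself is out of scope) and applies
`statistic = max(0, 2 * (lnL_alt - lnL_null))` against a plain chi-squared
distribution with 1 degree of freedom — the convention under which the
widely quoted critical improvement of 1.92 arises, since
`qchisq(0.95, 1) / 2 = 1.9207` rounds to 1.92 at two decimals. We use the
plain chi-squared rather than the 50:50 point-mass mixture because the
1.92/3.84 threshold corresponds to the plain distribution's critical value.
Significance is the strict rule `p < 0.05`: an improvement of exactly 1.92
sits a hair above the exact critical value's p (p = 0.05004) and is reported
as the boundary case it is. Negative improvements clamp the statistic to 0
with p = 1.

## Numerical and design notes

* **TPM zero columns.** An experiment with no counts keeps an all-zero TPM
  column instead of dividing by zero; columns with any counts sum to 1e6
  within 1e-6 relative tolerance.
* **Half-open abutment.** A candidate ending exactly where a gene begins
  does not overlap it; GTF's closed coordinates are converted on input.
* **Missing subject sequences.** A passing hit whose subject sequence is
  unavailable leaves the species *present* with template status unknown
  (warning), never silently absent — the conservative choice for a
  presence screen.
* **Quadrant edges.** A band exactly on the lower baseline rung scores 0;
  the upper rung itself belongs to the next repeat interval and is
  rejected as out of range.
* **Problem sizes.** The default validation study is 20 seeded datasets of
  ~1000 transcripts x 20 experiments, and the scanner is cross-checked
  against a naive substring oracle on 1000 random kilobase sequences;
  these sizes make the full suite run in minutes on one core while keeping
  every filter's decision statistically meaningful.

## Limitations

The funnel starts from assembled transcripts and counts — read mapping,
assembly and lncRNA classification beyond known-gene overlap are out of
scope, as are degenerate telomere repeats (no IUPAC wildcards), RNA folding
or covariation evidence, kinetic models of telomerase processivity, and the
codon-model fits whose log-likelihoods the LRT helper consumes. The funnel
reproduces the published screen's *structure* (stage order, strictness,
report fields); its published survivor counts depend on the original
sequencing libraries and are not reproducible from synthetic data, which is
why validation here is parameter recovery against planted ground truth.
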