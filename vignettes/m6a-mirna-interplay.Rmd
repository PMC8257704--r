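---
title: "Methods: screening miRNA seeds for m6A consensus motifs and quantifying m6A-dependent target regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m6A/miRNA interplay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Amir)
```

## The problem

N6-methyladenosine (m6A) and microRNA binding are the two dominant
post-transcriptional control layers acting on 3'UTRs.  m6A is written
within a degenerate consensus, RRACH (R = A/G, H = A/C/U, the central
A methylated), whose strongest form is GGACH.  A miRNA represses a
transcript when its seed (mature positions 2–8) pairs with a
complementary 3'UTR site.  When the reverse complement of a seed
itself contains the m6A consensus, every target site of that miRNA is
a potential methylation substrate, and m6A status becomes a candidate
modifier of that miRNA's repression strength.  This package provides
the complete computational side of that question: motif-in-seed
screening, target/m6A annotation, overlap and score statistics, and
stage-wise regulation summaries, plus a generator of fully synthetic
inputs with planted truth so that each claim the pipeline makes is
testable offline.

## Screening model

For each mature miRNA the seed is the 1-based inclusive span
`seed_span` of the mature strand, default (2, 8) — the canonical 7-nt
convention; position 1 is excluded because it does not pair.  The
mRNA-strand *site sequence* is the reverse complement of the seed.  A
5-nt motif cannot equal a 7-nt site sequence, so "the site contains
the motif" is operationalised as contiguous containment: the motif
must occur as one of the three possible 5-nt windows inside the 7-nt
site.  All window positions are reported rather than requiring a
particular anchoring, and classification is by containment:

* `FULL` — the stringent motif (GGACH by default) occurs in the site;
* `PARTIAL` — only the relaxed motif (RRACH) occurs;
* `NONE` — neither.

Since every GGACH match is an RRACH match, `FULL` implies the relaxed
condition; both tiers are computed in one pass so that
"k-of-N relaxed" and "m-of-N stringent" summaries come from the same
screen.

Degenerate matching is exact set membership per position against the
IUPAC expansion table.  An `N` in a *scanned sequence* matches nothing
by default — an undetermined base is never taken as evidence for a
motif — with an `n_matches_all` flag for the permissive reading.  All
coordinates are 0-based half-open internally (BED-compatible);
conversion to 1-based happens only in rendered reports.

## Target sites and m6A annotation

Because published target lists come from RISC/AGO2 pull-down
databases that do not define sites mechanically, the pipeline uses the
canonical seed-match taxonomy as its operational stand-in, anchored on
an exact match to the reverse complement of seed positions 2–7:

| type | requirement | width |
|------|-------------|-------|
| 6mer | core match (positions 2–7) | 6 |
| 7mer-A1 | core + `A` in the UTR opposite position 1 | 7 |
| 7mer-m8 | core + match to position 8 | 7 |
| 8mer | both | 8 |

Each anchor is reported once with its strongest type; the default
floor is `min_site_type = "7mer-m8"`, matching the 7-nt seed span used
by the screen.  The A1 position requires an adenosine regardless of
the miRNA's position-1 identity, per the standard convention.

A gene is an *m6A-modified target* under the default rule when it is a
target AND belongs to the supplied m6A gene set (e.g. from
m6A-RIP-seq) AND carries the consensus motif in its UTR — mirroring
the two-step filter of RIP-derived gene set then motif presence.  The
stricter rule additionally requires a motif hit to intersect a site
interval (half-open intersection), the reading in which the
methylated A lies inside the target sequence itself; the strict
classification is always a subset of the default one.  The package
scans whatever sequence the caller supplies as "the UTR": if the
region of interest includes the stop-codon vicinity, the caller
includes it in the FASTA, and the annotation semantics are unchanged.

## Overlap and score statistics

Set overlaps are exact integer arithmetic; the directional percentage
(share of set A falling in B) is rendered **half-up at 2 decimals**
(270/894 renders 30.20, 102/416 renders 24.52); base `round()`'s
half-to-even is deliberately not used for rendering.

Enrichment scores are compared with an unpaired two-tailed two-sample
*t* test; the default is the classical pooled-variance Student test
(df = n1 + n2 − 2), with Welch available because real enrichment
scores are heteroscedastic.  One score per gene is assumed (the
published tables are per-gene); genes without a score are excluded
from the comparison but not from the overlap, and a stratum with
fewer than two scored genes marks the comparison not-computable
rather than failing.  Degenerate inputs are defined, not special-cased
downstream: all values identical across both groups gives t = 0,
p = 1; zero variance with different means gives t = ±Inf, p = 0.  No
multiple-testing correction is applied: the pipeline performs single
planned comparisons per report, and the report says so.

## Stage dynamics

Regulation between a reference and a comparison stage is
`log2((v_cmp + pseudocount) / (v_ref + pseudocount))` with a
symmetric threshold: DOWN at ≤ −log2(fc), UP at ≥ +log2(fc), else
UNCHANGED; `fc_threshold = 1` gives sign-only calls with exact ties
UNCHANGED.  The default threshold is 1.5 with pseudocount 0 — a
conventional proteomics choice; because the underlying studies do not
state their cutoff, the threshold is exposed and results can be
bracketed at 1.2/1.5/2.0.  A zero reference abundance with zero
pseudocount makes that gene's call not-computable; it is excluded
from counts (counts are conserved:
down + up + unchanged + not-computable = genes).

Per target set the summary is the down:up ratio (flagged infinite when
nothing is up-regulated), and across two sets the fold difference of
those ratios.  Stratified percentages use down/(down + up), excluding
UNCHANGED, because the two-category rendering is what the stage-wise
figures show.  A Sham/TAC hypertrophy design is the same machinery
with the reference set to Sham and UP as the highlighted category.
Multi-stage trajectories are repeated pairwise calls against the
reference, one summary per stage.

## The synthetic-data generator

The generator emulates the assumed statistical structure of the real
inputs, with defaults set to the study conditions the pipeline
targets:

* catalogue: 139 miRNAs, 1 stringent-matching and 9 relaxed-only
  planted seeds, mature length 22;
* genome: 3,000 genes, Poisson UTR lengths (mean 200 nt, floor 40),
  target probability 0.3 (≈ 900 targets), m6A gene-set membership
  0.302 given target (the ≈30% overlap) and 0.25 otherwise, uniform
  base composition (a GC knob exists but defaults to 0.5);
* scores: Normal(base 1 + delta 1 × \[m6A-modified\], SD 1) per target
  gene — the simplest model reproducing the observed score shift;
* time course: lognormal reference abundances, planted DOWN
  probability 0.862 for m6A-modified targets versus 0.723 for other
  targets, regulated genes scaled by exactly 4-fold, non-regulated
  genes jittered within ±1.2-fold.

Two choices make the *discrete* planted truth exact rather than
probabilistic, which the round-trip tests require.  First, background
sequence is rejection-screened against accidental GGACH windows and
accidental ≥7mer-m8 site text, with local resampling of offending
windows; every assembled UTR is then verified against the package's
own scanners and reassembled if planting created an unexpected hit.
Second, regulated genes move by exactly the configured fold while
unchanged genes stay inside the jitter band, so any caller threshold
in (1.2, 4) recovers the planted calls exactly.  Note that for a
GGACH-class screen miRNA (the miR-133a analogue) the planted site
text itself contains the motif, so every target's UTR carries GGACH
inside a site interval by construction — the strict and default
annotation rules then coincide on targets, which is the biologically
intended geometry; a separate motif-in-site switch would either be a
no-op or destroy the planted site, so none exists.

What the generator does **not** emulate: real UTR length and
composition distributions, multiple sites per gene, site-context
efficacy, conservation, read-level noise, replicate structure, or
correlated scores.  Passing round-trip tests therefore demonstrates
the pipeline's logic is exact on its own assumptions, not that those
assumptions hold in any real dataset.

All generators are pure functions of the configuration and its
`rng_seed` (Mersenne–Twister, inversion normals, rejection sampling
for `sample()`, pinned explicitly), each sub-generator offsetting the
seed by a fixed constant, so emitted files are byte-identical across
runs and platforms.

## Numerical and testing choices

* Percentage rendering: half-up at 2 decimals with an epsilon guard of
  `sqrt(.Machine$double.eps)` so decimal-intended halves (e.g. 2.675)
  round up despite binary representation.
* The *t* statistics delegate to `stats::t.test`; the test suite
  checks them against independently coded textbook formulas, and the
  motif scanner against both a naive window oracle and
  `Biostrings::matchPattern(fixed = FALSE)`.
* Problem sizes in the test and acceptance runs are scaled to keep
  full runs quick while leaving no sampling question open: 1,000
  random sequences for the scanner property; 100 generator seeds of
  full 139-miRNA catalogues for exact screen recovery; 500 null and
  200 effect replicates at n = 100–200 per stratum for calibration
  and power; 250-gene genomes over 10 seeds for the end-to-end
  round trip; 2,000 genes for the stratified-dynamics recovery, where
  planted rates must fall inside the binomial 95% CI of the
  estimates.

## Known limitations

The site taxonomy is a stand-in for database-derived target lists; no
thermodynamic or context scoring is attempted.  m6A peaks are accepted
only in UTR-relative coordinates — there is no genome-to-transcript
lifting.  The dynamics stage is a direction-of-change count summary,
not differential-expression modelling (no variance shrinkage or
replicate-aware testing), faithful to the figures it reproduces.  The
published catalogue-level counts that depend on third-party datasets
(which 10 of 139 miRNAs match, the 2,818-gene motif list, the
specific fold ratios) are not desk-reproducible without those
datasets; the property suite substitutes exact recovery on planted
catalogues with the same structure.
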