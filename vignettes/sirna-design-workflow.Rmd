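---
title: "The siRNA design workflow: models, filters and their assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The siRNA design workflow: models, filters and their assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnadesign)
```

## The problem

A small interfering RNA (siRNA) is a ~19–21-nt double-stranded RNA whose
guide strand loads into the RNA-induced silencing complex (RISC) and directs
cleavage of complementary mRNA. Designing an effective and *specific* siRNA
against a gene is a multi-factorial filtering problem:

1. the 19-nt target site must exist identically in **every transcript
   isoform** of the gene, or some isoforms escape silencing;
2. it must not overlap a known **SNP**, since a single central mismatch
   between guide and target can abolish silencing;
3. the duplex sequence must satisfy **efficacy rules** learned from
   experimental screens (base preferences by position, GC composition,
   thermodynamic end asymmetry);
4. the target site must be **structurally accessible** — RISC binds
   single-stranded RNA and cannot unwind stable mRNA structure;
5. the duplex must be free of **off-targets**, both catalytic (19/19 or
   18/19 matches anywhere in the transcriptome, on either strand) and
   miRNA-like (guide seed, positions 2–7, matching an unintended 3' UTR).

`sirnadesign` implements this workflow as conjunctive filters over all
19-nt windows of the admissible sequence space, each filter independently
testable against a brute-force oracle.

## Sequence space: conservation and SNP masking

Conservation is defined as **exact contiguous substring presence in every
sibling transcript** — the un-gapped, 100%-identity notion of a consensus.
This is stricter than a gapped multiple-alignment consensus that tolerates
isolated mismatches, and deliberately so: a window that differs in any
isoform is useless for complete gene silencing, and the exact-substring
definition is deterministic and needs no external aligner. `conserved_blocks()`
returns all maximal qualifying intervals (0-based, half-open). Maximal
intervals can in principle overlap in staircase-like conservation patterns;
candidate enumeration de-duplicates windows by start, so this representation
choice has no downstream effect.

SNP positions arrive 1-based (the VCF convention) and are converted at the
boundary; each masked position splits its interval. `N` bases are masked the
same way — an ambiguous base can be neither scored nor trusted to pair.
There is no published minimum conserved-block length for design, so the
package exposes `min_block_len` with default 19 — one full site — rather
than guessing more.

## Candidates and coordinate conventions

Candidates are every 19-nt window of the masked space, advancing one
nucleotide at a time. The literature mixes coordinate conventions freely;
this package states one and uses it everywhere: **scoring rules index
positions 1–19 along the sense target site, 5'→3'; guide positions count
1–19 from the guide 5' end**, so guide position *i* faces sense position
20 − *i*. The duplex overhang defaults to `"UU"` (the RNA-alphabet analogue
of classical dTdT ends) and is configurable; published designs fix the
19-nt core but not the overhang.

## Multi-score intersection filter

Two scorer families plug into the same registry:

* **First-generation rule tables** — weighted position/composition rules
  (`rule_table()`), or ordinal condition sets (`ordinal_table()`). The two
  shipped defaults are documented YAML files in `inst/extdata/scorers/`:
  an additive table rewarding low-GC, A/U-rich 3' ends with an A at
  positions 3 and 19 and penalizing G/C at the 3' terminus, and an ordinal
  set requiring G/C at sense position 1, A/U at 19, ≥4 A/U among positions
  13–19 and no G/C run of ≥9.
* **Second-generation linear models** — intercept plus position×base
  weights predicting percent inhibition (`coefficient_table()`). Published
  trained weights belong to their respective publications, so the engine
  and file schema are the contract here; a clearly labelled synthetic demo
  table ships for testing the machinery.

Acceptance is the **intersection** of all registered scorers, which trades
sensitivity for specificity by construction. First-generation windows are
derived as `mean ± 2·SD` (sample SD) of the scores of experimentally
high-efficacy training siRNAs — `derive_thresholds()` implements exactly
this. The shipped `thresholds.yaml` carries the canonical published
windows verbatim; for a few scorers these differ from recomputed
`mean ± 2·SD` by ≤ 0.1 because the published SDs are rounded, and the
published values are treated as authoritative. Second-generation scorers
accept at a predicted inhibition of ≥ 70 (configurable), and the final
ranker threshold defaults to 93 on a 0–100 scale.

Two ordinal details are package decisions and worth stating: classes are
encoded worst-to-best (III < II < Ib < Ia) by the count of satisfied
conditions (all → Ia, one short → Ib, ...), and the default acceptance
class is Ib — accepting from the bottom class would accept everything and
demanding the top class alone discards near-ideal designs, so the
second-best class is the defensible default. The "no internal hairpin" criterion is implemented as
absence of a self-complementary stretch of ≥ 5 nt — a deterministic proxy
for a duplex-melting-temperature cutoff that is otherwise under-specified.

## Target-site accessibility

The structure model is a **Boltzmann-weighted base-pair-sum over nested
secondary structures**: each admissible pair contributes a fixed energy
(defaults G:C −3.0, A:U −2.0, G:U wobble −1.0 kcal/mol; `NA` disables a
pair type), hairpin loops must enclose ≥ 3 unpaired bases, and RT defaults
to 0.6163 kcal/mol (37 °C). This is *not* the nearest-neighbour Turner
model — there are no stacking or loop-entropy terms. The simplification is
the point: the partition function stays self-contained and exactly
verifiable against exhaustive structure enumeration (the test suite checks
agreement to 1e−9 on sequences up to 18 nt), while a pluggable backend
slot (`accessibility_filter(profile = ...)`) accepts per-position unpaired
probabilities from any external folding engine.

Per-position unpaired probabilities are computed exactly as
`Z(i unpaired) / Z`, each term from an O(n³) inside recursion; positions
with no admissible partner short-circuit to probability 1. Double-precision
partition sums stay far below overflow for folding windows up to a few
hundred nt, which bounds the usable window length; the default local-folding
window of 80 nt with step 10 (averaging per-position probabilities over all
windows covering a position) mirrors the standard local-folding concept and
reduces exactly to a global fold when the window covers the transcript.

A candidate passes when

* `site_accessibility()` — the geometric mean over configured sub-windows
  (defaults: the 8 nt at the site 3' end, where RISC nucleates target
  recognition, and the full 19 nt) of mean unpaired probability — reaches
  `min_accessibility` (default 0.1), and
* the total interaction energy `dG_total = dG_hybridization + dG_open` is
  negative, where hybridization sums the 19 guide:site pair energies and
  `dG_open = −RT·ln P(site unpaired)` approximates the joint opening
  probability by the product of per-position probabilities. A probability
  of zero yields `+Inf` and rejection.

These two thresholds are package configuration values, not published
constants: accessibility screens in the literature each carry their own
tool-specific window and threshold parameterizations, and any values
supplied in the configuration are honoured in their place.

## Off-target filtration

Published pipelines delegate this step to seeded heuristic alignment; this
package instead uses a **guaranteed-complete pigeonhole k-mer search**: for
at most one mismatch over 19 positions, at least one of the two halves
(1–9, 10–19) is exact, so exact 9-mer lookups followed by verification find
every complete (19/19) and near-complete (18/19) match, on both strands,
deterministically. A two-mismatch radius is available through
configuration and falls back to a naive full scan; the default radius
is 1.

Seed matching scans unintended 3' UTR records for exact occurrences of the
Watson–Crick complement of the guide seed, defined as guide positions 2–7
from the guide 5' end — the standard seed for miRNA-like translational
repression. Plain 6-mer matching is used — no A1 anchoring or position-8
refinement.

The verdict follows a fixed decision order: any full-homology hit rejects
(`reject_full`); otherwise any seed hit rejects (`reject_seed`); otherwise
the candidate is off-target free. Transcripts of the targeted gene
(`intended_ids`) are never counted as off-targets. An optional
immunostimulatory-motif screen (5'-UGUGU-3', 5'-GUCCUUCAA-3', poly-G ≥ 4)
is available but **off** by default, since it is not one of the core
workflow stages.

## Pipeline semantics

The three filters are conjunctive, so the accepted set cannot depend on
their order; the suite asserts this under all six permutations.
`stage_order` therefore only controls which stage a doubly-failing
candidate is *attributed* to. At the desk scales this package targets,
every stage is evaluated for every candidate (the per-stage annotations
are themselves useful); ordering cheapest-first matters only as a
large-scale optimization, where off-target scanning is the rate-limiting
step. The final ranker is a pluggable efficacy model (function or
coefficient table); with none configured the ranking stage is skipped and
logged, since trained production rankers carry weights that belong to
their own publications and are not redistributable here. When zero candidates survive, the result is an empty
accepted set plus the full per-candidate table — thresholds are never
auto-relaxed.

Outputs are deterministic: identical configuration and inputs give
byte-identical FASTA and TSV, with numbers at 4 significant digits.

## What the synthetic data emulates — and what it does not

`make_gene()` emulates multi-isoform genes (1–13 transcripts, the typical
human range) as shared exonic blocks interleaved with per-transcript unique
exons, with planted SNPs; the shared blocks are the ground-truth conserved
regions, and construction is rejection-sampled until an independent check
confirms no accidental conservation. `make_decoy_transcriptome()` builds
GC~50% random backgrounds rejection-sampled so that no 19-mer of a
protected site (or its reverse complement) occurs within one mismatch and
no protected seed 6-mer occurs in a UTR; planted exact/one-mismatch copies
and seed complements are then re-verified by naive scans, so planted ground
truth is exact, not probabilistic.

`make_design_fixture()` plants three handcrafted high-scoring sites on an
{A,G}-alphabet reference. With no C or U in the reference, no base pair
can form, so the gene is maximally accessible *by construction* — the
fixture isolates scoring and off-target behaviour from folding. Problem
sizes throughout (transcripts of a few hundred nt, decoy transcriptomes of
~1 kb, folding windows of 80 nt) are chosen so each property holds at a
scale where the brute-force oracle is also computable; they exercise every
code path of the real method.

Passing these tests therefore demonstrates the *machinery* — exact
conservation arithmetic, complete approximate matching, a partition
function that matches enumeration, correct threshold algebra — not
biological performance. Real transcriptomes bring compositional bias,
repeats, paralogy and Turner-model thermodynamics that synthetic uniform
backgrounds and the pair-sum energy model do not capture; published
sensitivity/specificity figures for this class of workflow depend on
external experimental datasets and trained model weights that are not
reproduced here.

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviation in `derive_thresholds()`; two or more
  finite scores required, zero SD collapses the window to a point.
* Stable sorting in `final_rank()`, ties broken by candidate start.
* Empty sequence space, zero candidates, or an empty scorer registry fail
  fast with clear errors (registry) or produce structured empty results
  (space/candidates).
* Partition probabilities are clamped to [0, 1] only against rounding at
  the 1e−12 level; the recursions themselves are exact in double
  precision.
* Candidate windows containing `N` are skipped; `N` never pairs and never
  matches in scans.

## Known limitations

* The energy model ignores stacking, loop entropies and pseudoknots;
  accessibility values are comparable within a run, not calibrated
  free energies.
* Conservation is exact-match only; genes whose isoforms differ by a
  single polymorphism inside an otherwise shared exon lose that window.
* Off-target completeness is guaranteed only for the configured mismatch
  radius (≤ 1 by index, 2 by naive scan); RNA-bulge off-targets are out of
  scope.
* First-generation scorers whose published parameters are not re-derivable
  from their papers' text ship as thresholds only; their engines accept
  user-supplied tables.
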