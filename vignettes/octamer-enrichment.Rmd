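---
title: "Octamer enrichment statistics and promoter scanning with octascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Octamer enrichment statistics and promoter scanning with octascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octascan)
```

## The model

`octascan` predicts cis-regulatory elements by exhaustive enrichment
statistics over all 65,536 DNA octamers, rather than by fitting a motif
model. The input design is a *total* set of fixed-length promoters (one
per gene, positions −L..−1 relative to the TSS, default L = 1000) and a
*responsive* subset selected from an expression table by a fold-change
threshold. For each octamer $o$ the Relative Appearance Ratio is

$$\mathrm{RAR}(o) =
  \frac{c_{\mathrm{set}}(o) / n_{\mathrm{set}}}
       {c_{\mathrm{tot}}(o) / n_{\mathrm{tot}}},$$

where $c$ are occurrence counts over all 1-bp windows of a set and $n$
are promoter numbers. The ratio of per-promoter rates is insensitive to
set size and equals 1 in expectation for octamers unrelated to the
response (with equal-length, N-free promoters the count-weighted mean
of RAR over octamers is exactly $n_{\mathrm{tot}} W_{\mathrm{set}} /
(n_{\mathrm{set}} W_{\mathrm{tot}}) = 1$, an identity the test suite
asserts to 1e−9).

High RAR alone is not evidence: an octamer seen three times genome-wide
can reach RAR in the tens by landing once in the responsive set. Each
octamer therefore receives a one-sided Fisher exact test of enrichment,
and the P value is expressed as a LOD score $-\log_{10} P$. RAR values
with LOD < 1.3 (P > 0.05) are masked to zero; the masked statistic is
called RARf. Masking is per octamer, deliberately without
multiple-testing correction — the statistic is a *screen* whose output
feeds visual inspection and secondary selection, not a family-wise
inference (a Benjamini–Hochberg option exists in
`analysis_config(bh_correct = TRUE)` but is off by default).

### The Fisher 2×2 construction

The published ratio compares the responsive set against the *total*
set, which contains it. A contingency table needs disjoint classes, so
the test is built on responsive windows versus all *other* windows:

|              | octamer | not octamer |
|--------------|---------|-------------|
| responsive   | $c_s$   | $W_s - c_s$ |
| non-responsive | $c_t - c_s$ | $(W_t - W_s) - (c_t - c_s)$ |

with $W$ the valid-window totals. The one-sided enrichment P is the
hypergeometric upper tail $P(X \ge c_s)$, computed vectorized with
`phyper`; the test suite checks it against an independent exhaustive
tail summation on every 2×2 table with class margins up to 20+20
(agreement better than 1e−12) and against `fisher.test(alternative =
"greater")`. This construction and sidedness are recorded in the table
metadata, since other constructions are conceivable.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `table_fold_threshold` | 3.0 (ratio scale) | genes "more than 3-fold" up define the responsive set for table building; strictly-greater comparison |
| `scan_fold_threshold` | 5.0 | promoters individually scanned are the more stringent "over 5-fold" responders; the differential selection removes some false-positive octamers |
| `lod_threshold` | 1.3 | masking boundary, i.e. P = 0.05; LOD ≥ 1.3 keeps its RAR (the boundary itself passes, since "less than 1.3" is masked) |
| `rarf_peak_cutoff` | 3.0 | scan windows above this RARf become peak windows; a deliberately loose, sensitivity-first value |
| `crosstalk_max_distance` | 4 bp | inclusive distance between element starts from two treatment tables that counts as co-localized |
| `counting_mode` | `occurrence` | "count" read as total window occurrences; `promoter` (presence/absence) is available and recorded in metadata |
| `strand_mode` | `given` | `merged` pools each octamer with its reverse complement (palindromes once) and is the mode used for REG annotation |

All are plain arguments of `analysis_config()` and CLI flags, because
the appropriate RARf cutoff genuinely varies between experiments.

## Numerical and boundary conventions

* **Coordinates.** 1-based-negative TSS-relative positions; a window is
  addressed by its 5′-most base, so valid starts are −L..−8. String
  index $i$ maps to position $i - L - 1$.
* **N handling.** Windows containing N are excluded from counts *and*
  window totals (symmetric exclusion avoids composition bias); in scan
  profiles they carry `NA`, never 0, and therefore break peak merges.
* **Degenerate octamers.** `count_total = 0` gives RAR 0 (an absent
  sequence cannot be an element) and P = 1.
* **Threshold comparisons.** Fold-change selection and peak calling
  are strictly-greater; LOD masking and REG annotation are
  at-or-above. These follow the wording of the respective rules
  ("more than 3.0 fold", "less than 1.3 filtered out", "RARf ≥ 3").
* **Peak merging.** Above-cutoff windows cover 8-nt intervals; the
  merge joins intervals that overlap *or abut* (configurable
  `max_gap`, default 0). Two adjacent triggering windows give a 9-nt
  element, seven give 14 nt — matching the 8–14 nt size range of
  reported predicted elements, which motivated reading "peaks" as
  merged regions rather than single windows. Raising the cutoff can
  only shrink or remove elements (anti-monotonicity, tested).
* **Element position.** Reported at the element's 5′-most base, the
  convention used for published per-element positions.
* **Crosstalk distance.** Measured between element start positions
  (the reported coordinate); an interval-gap alternative is available
  (`anchor = "gap"`). Distance 4 is in, 5 is out. Records are
  restricted to distinct treatments and stored with the pair in
  lexicographic order.
* **Serialization.** Stat tables are written with 17 significant
  digits so a TSV round-trip is bit-exact (asserted in tests).

## REG annotation and motif matching

REG annotation uses the direction-insensitive (strand-merged) table:
a REG is annotated with every treatment whose RARf for its octamer is
≥ 3, ordered by decreasing RARf. Motif matching expands the restricted
pattern syntax (`N`, `(X/Y)`) to explicit strings and checks both
strands by default — necessary because, e.g., the DRE core CCGAC lies
on the complementary strand of the REG octamer AGTCGGTC. An octamer
matching several motifs counts toward each; the published figures do
not state a tie-break, and counting under every match keeps the
classification self-consistent under reverse complementation. The
position-frequency matrix (`build_pfm()`) replaces external
alignment-plus-logo tooling with anchor-based registration on the motif
core, weighted by appearance counts: ungapped 8-mers need no general
aligner, and the anchor reproduces the registration a logo would show.

## What the synthetic generator emulates — and what it does not

`generate_promoters()` draws i.i.d. letters (default composition
AT-rich, A = T = 0.335, C = G = 0.165, a realistic GC content for
plant promoter regions); `plant_motif()` overwrites (never inserts) one
octamer copy per selected promoter at a drawn position, preserving
length and the window-count identities; `generate_expression()` draws
fold changes from disjoint high/low ranges so threshold selection
recovers the designed subset exactly. Every stage takes an explicit
seed and restores the global RNG state.

The generator does *not* emulate promoter architecture (TATA/CpG
structure, positional composition gradients), linked occurrences of
cooperating motifs, or expression noise that misclassifies genes.
Passing the recovery benchmarks therefore shows the statistics behave
as designed under their own assumptions — not that real microarray
experiments will yield comparable signal-to-noise.

### Benchmark designs and their compositions

Two standing benchmarks exercise the statistics at desk scale (sizes
chosen to keep the full 65,536-row table builds in seconds on one CPU):

* **Parameter recovery** — 5,000 promoters of 1 kb, 300 responsive,
  one octamer planted at probability 0.5 (responsive) vs 0.05
  (background), *uniform* base composition. The planted octamer must
  exceed RARf 3, rank in the top 10 by RARf, and recover the analytic
  enrichment ratio within ±25%. Uniform composition is the study
  condition here: at ~5M windows it leaves no octamer rare, so rank is
  a meaningful recovery measure. Under skewed composition the rare
  GC-rich tail produces a few dozen all-in-set flukes that legitimately
  pass P < 0.05 with RAR ≈ 17 — the very false-positive class the
  masking narrows but cannot eliminate — and rank stops measuring
  recovery.
* **Null calibration** — 2,000 promoters of 500 nt, 100 "responsive"
  chosen with no planting, *AT-rich* composition. The per-octamer
  type-I fraction (P < 0.05 among octamers present in the total set)
  must stay at or below 6%, and masking must remove a larger share of
  high-RAR (> 3) octamers among rare octamers (total count ≤ 5) than
  among common ones (count ≥ 100). The skewed composition is essential
  here: it populates both count strata. Under a pure null the common
  stratum contains essentially no high-RAR octamers at all, so its
  removal fraction is taken as 0 (empty-stratum convention) and the
  rare stratum is additionally required to be strictly positive —
  which is precisely the observation that motivated the mask: chance
  high-RAR octamers concentrate among rare sequences.

## Known limitations

* Exact 8-mers only: no mismatches, no PWM scoring, no gapped motifs;
  degenerate binding sites spread their signal over several octamers.
* The loose RARf > 3 cutoff is sensitivity-first; predicted element
  lists contain chance peaks by design (see the worked example in the
  README) and need secondary selection.
* Enrichment confounds direct and indirect targets: two motifs that
  co-occur in the same promoters drag each other into the high-RARf
  set (the bystander effect); the co-localization analysis quantifies,
  but cannot remove, this.
* The shipped REG catalog is the 53-entry annotated subset, not the
  full 308-octamer catalog.
* Promoter sets are fixed-length and TSS-anchored; determining TSSs
  and extracting upstream regions from a genome is upstream of this
  package.
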