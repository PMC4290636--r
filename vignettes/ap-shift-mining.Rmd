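---
title: "Mining phosphopeptide signals from alkaline-phosphatase-paired LC-MS runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining phosphopeptide signals from alkaline-phosphatase-paired LC-MS runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosmine)
```

## The problem

Phosphopeptides are hard to pick out of a complex tryptic digest: they are
substoichiometric, often poorly ionized, and data-dependent acquisition (DDA)
tends to fragment whatever is most intense instead. One effective remedy is
enzymatic: split an enriched sample (TiO2 or anti-phosphotyrosine
immunoprecipitation), dephosphorylate one half with alkaline phosphatase
(AP), and run both halves by LC-MS. A genuine phosphopeptide then betrays
itself as a pair of features whose **neutral monoisotopic masses differ by a
multiple of the phosphate-group mass**,

$$ M_{\text{untreated}} - M_{\text{treated}} \approx n \cdot 79.966
   \ \text{Da}, \qquad n = 1, \dots, n_{\max}, $$

while eluting at nearly the same retention time. `phosmine` implements the
informatics around this idea as three pipeline stages plus a synthetic-data
generator:

1. **Mining** (`mine_pair()`, `merge_replicates()`): find candidate pairs in
   filtered peak lists from up to six replicate run pairs.
2. **Inclusion lists** (`deduplicate()`, `build_inclusion_list()`): convert
   candidates into deduplicated, retention-time-windowed m/z targets that an
   instrument will fragment in a follow-up targeted LC-MS/MS run.
3. **Linking** (`link()`, `summarize_linked()`, `md_score()`): join the
   resulting search-engine identifications to label-free quantification
   features, compute abundance ratios and ANOVA p-values, and summarize
   phosphosite-localization confidence via Mascot delta scores.

Neutral mass is computed as \(M = z\,(m/z) - z\,m_p\) with the proton mass
\(m_p = 1.00728\) Da, which reproduces the reference arithmetic to three
decimals: an ion at m/z 812.858 (2+) has \(M = 1623.701\) Da, its
AP-treated partner at 772.870 (2+) has \(M = 1543.725\) Da, and their
difference of 79.976 Da sits 0.010 Da from one phosphate loss — inside the
default 0.05 Da tolerance.

## Mining parameters and what they mean

`miner_params()` defaults match a published pTyr cell-lysate configuration:

| parameter | default | unit | meaning |
|---|---|---|---|
| `delta_mass` | 79.966 | Da | mass lost per dephosphorylation (HPO3); settable so other PTM losses can be mined |
| `mass_tol` | 0.05 | Da | tolerance on the observed shift vs. `n * delta_mass` |
| `rt_tol` | 5 | min | maximum elution-time difference between partners |
| `max_mods` | 5 | — | largest phosphate count considered |
| `min_charge` | 2 | — | peaks below this charge are discarded before matching |
| `top_n` | 3000 | — | intensity-rank truncation per run (`"auto"` uses the knee) |

Matching is performed on **neutral mass**, not raw m/z, so partners may be
observed at different charge states; `same_charge = TRUE` restores the
stricter behaviour. For each untreated peak and each `n`, only the treated
peak with the smallest absolute mass error (ties: smallest RT difference) is
kept — this prevents combinatorial inflation in dense peak lists while a
peak can still appear once per distinct `n` (multiply phosphorylated forms
are real). The scan itself sorts treated masses once and walks tolerance
windows with binary search; its contract, enforced by tests, is exact
equality with the quadratic all-pairs enumeration.

The `top_n` "knee" heuristic (`intensity_knee()`) is defined here as the
rank immediately before the largest drop of the descending intensity series,
ties resolved toward the smaller cut; a flat series keeps everything. Any
smarter definition of "greatest slope change" is deliberately avoided — the
chart data (`intensity_chart_data()`) is exposed so the cut can be chosen by
inspection, and `top_n` remains an explicit parameter.

Replicate merging (`merge_replicates()`) is greedy single-linkage clustering
of candidates by untreated (m/z, RT), seeded in descending intensity, with
defaults of 0.01 Th and 2 min; `min_support` (default 1) discards clusters
seen in fewer replicates. The merging rule is this package's own design:
multi-replicate experiments need *some* intersection rule, and
intensity-seeded single linkage is deterministic and order-independent.

## Inclusion lists

`deduplicate()` rounds the untreated m/z of every candidate to
`round_decimals` (default 2) digits and merges collisions — including
collisions across biological conditions combined with
`combine_conditions()`. Rounding is **half away from zero** (the spreadsheet
convention; 812.8579 becomes 812.86), with a relative-epsilon guard so that
decimal literals stored just below a half boundary in binary floating point
(1.005 is stored as 1.00499…96) still round up; banker's rounding is
available as an option since both conventions agree on the reference
example.

`build_inclusion_list()` splits the elution range (default 10–60 min) into
`n_segments` (default 10) equal segments, half-open `[start, end)` with the
last segment closed so boundary assignment is unambiguous. A merged
precursor is placed by the **median** of its member retention times
(robust to an outlier replicate). Two window modes are provided because a
6.92-min worked window (21.51–28.43 min) cannot arise from 5-min segments
padded by 1.5 min (which are always 8 min wide):

* `candidate_extent` (default): window = observed RT extent of the members
  ± `extra_rt_tol`. A candidate observed at 23.01 and 26.93 min with the
  default 1.5 min padding gets exactly the 21.51–28.43 min window.
* `segment`: window = assigned segment ± `extra_rt_tol` (always
  `width + 2 * extra_rt_tol` wide; 8.0 min under the defaults).

Which of the two a given published list used cannot be inferred from its
description, so neither is asserted as "the" behaviour; both satisfy the
partition and containment invariants in the test suite. An optional
`max_per_segment` cap respects instrument inclusion-list size limits.

## Linking identifications to quantification

`link()` filters identifications (ion score ≥ 25, at least one phosphosite
of a requested type — default pTyr) and assigns each survivor the feature
with the smallest |Δm/z| (ties: |ΔRT|) within 0.2 Th, 2 min, and equal
charge. One-to-one best matching is the default because a many-to-many join
multiplies quantification rows without evidence; `keep_all_matches = TRUE`
is the escape hatch. Per record the control/treatment ratio uses group
means, with an infinite ratio when the treatment mean is zero (a peptide
seen only in controls), and the p-value is a one-way ANOVA across condition
groups via `stats::aov` — undefined (NA, row retained unflagged) with fewer
than two values per group. `md_score()` implements the Mascot delta score —
top minus second ion score among alternative site placements of one
sequence; a single placement returns its own score, the conventional
"nothing to confuse it with" case.

Modification strings are parsed in a compact dialect (`pY10`,
`Phospho (Y10)`, other modifications ignored); a token whose residue or
position contradicts the sequence invalidates the row rather than silently
mislocating a site.

## What the synthetic generator emulates — and what it does not

`synth_config()` plants `n_phospho` (default 20) phosphopeptides among
`n_decoys` (default 200) non-shifting background peaks per run, with:

* neutral masses uniform in 800–3500 Da (tryptic peptides within a
  300–2000 m/z survey scan at charges 1–3), **rejection-sampled** so that no
  cross-pair mass difference lands within `decoy_margin` (default 0.1 Da,
  i.e. twice the default mass tolerance) of any multiple of 79.966 Da —
  background can therefore never masquerade as a dephosphorylation pair,
  which is what makes planted recall/precision exact oracles;
* phosphate counts from `mods_distribution` (mostly singly phosphorylated);
* Gaussian m/z noise (default sd 0.005 Th, scaling with charge on the mass
  scale) and RT jitter (sd 0.5 min); note the tails are unbounded, so a 3+
  peptide occasionally drifts past the 0.05 Da tolerance — recall near, not
  always exactly, 100% is the honest expectation at this noise level;
* charge states drawn from `charge_distribution`, default `(0, 0.7, 0.3)`
  over 1+/2+/3+ — multiply charged only, as tryptic phosphopeptides in this
  mass range essentially always are, and as the `min_charge = 2` filter
  presumes;
* all phosphosites on tyrosine by default (`residue_probs`), emulating an
  anti-phosphotyrosine-enriched sample;
* `dephospho_efficiency` (default 1.0) for incomplete AP digestion;
* log-normal intensities and per-run quantification noise
  (`quant_noise_sdlog`, default 0.05) around per-peptide fold changes
  (`effect`).

All randomness flows through the single `seed`; the generator saves and
restores the global RNG state so it never perturbs a caller's random
stream. Identification scores are normal around 40 (sd 5), comfortably
above the default score threshold of 25.

Deliberately **not** modelled: isotope envelopes, fragment (MS/MS) spectra,
chromatographic peak shape, charge-state coexistence of one peptide,
missed-cleavage mass relationships, and the correlation between sequence
and mass (planted sequences are random strings carrying the right
phosphosite letters). Passing tests therefore demonstrate the correctness
of the *matching, windowing and linking logic* under controlled noise — not
performance on real instrument data, where peak detection quality and
alignment dominate.

## Numerical choices and degenerate inputs

* Proton mass fixed at 1.00728 Da (`PROTON_MASS`), phosphate at 79.966 Da
  (`PHOSPHO_MASS`); both exported.
* Retention time is canonically minutes; msInspect-style `time` columns in
  seconds are converted on read (`rt_units = "seconds"` in the default
  mapping).
* Equal-intensity ties in `filter_peaks()` break by ascending m/z so
  truncation is deterministic; malformed rows are skipped and counted, not
  fatal, because instrument exports routinely contain footer junk.
* Peaks lacking a charge are dropped when `min_charge > 1`, and can only
  participate in matching if the file supplied a mass column.
* Empty inputs propagate as empty outputs everywhere (empty peak list →
  empty candidate set → empty inclusion list → all identifications
  unlinked); `min_support` above the replicate count empties the merged set
  with a warning rather than erroring.
* Precursors eluting outside the configured time range are clamped into the
  nearest segment and logged, since discarding a real candidate for a
  configuration mismatch would be worse.

## Problem sizes used in the test suite

The shipped tests validate the fast mining scan against the brute-force
enumeration on 55 random instances up to 200 untreated × 200 treated peaks
(and linking up to 500 × 500), planted recovery on ten seeds of 20 planted +
200 decoy peptides, inclusion-list invariants on 1000 random precursors, and
a full simulate → mine → inclusion → link round trip with a planted
8.57-fold abundance change recovered within 5%. These sizes exercise every
code path at full statistical fidelity while keeping the suite quick to run;
the algorithms are `O(n log n)` in the peak count and have been run on
full-scale (~19,000-peak) simulated lists without difficulty.

## Known limitations

* No FDR model on candidate pairs and no isotope-pattern verification; a
  candidate is any pair satisfying the tolerances, and specificity comes
  from replicate support and the follow-up targeted MS/MS identification.
* Mascot scoring, PhosphoRS probabilities, and pattern-based quantification
  are consumed as tables, never recomputed.
* The knee heuristic is advisory; on multimodal intensity distributions the
  largest single drop can sit far from what a human would call the knee.
* Linking trusts the upstream RT alignment of the quantification software;
  systematic RT shifts larger than `rt_tol` between the targeted runs and
  the quantification runs will unlink everything.
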