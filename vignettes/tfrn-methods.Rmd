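---
title: "Methods: signed TF regulatory network inference in tfrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed TF regulatory network inference in tfrnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfrnet)
```

## The model

`tfrnet` infers which transcription factors (TFs) drive a transcriptional
response, and how they regulate one another, from two kinds of evidence:
*where each TF can bind* (a peak set per TF, typically DAP-seq, which
profiles intrinsic binding preference on naked or native genomic DNA) and
*what changed* (up- and downregulated DEG lists after the stimulus).

The central assumptions are:

* **Promoter-proximal regulation.** A TF regulates a gene when it binds
  within a fixed window upstream of the gene's TSS. Distal enhancers,
  introns and downstream elements are ignored.
* **Enrichment implies regulation.** If a TF's peaks are over-represented
  among the promoters of one DEG direction, the TF is taken to act on that
  direction as a group. Individual peak/DEG coincidences are treated as
  regulation only for TF-coding targets, and only after the TF has passed
  the enrichment gate.
* **The TF's own transcription reports its phase and mode.** A TF whose
  coding gene is itself up- or downregulated is active after or before the
  stimulus respectively; combined with the direction of its enriched
  targets this yields activator/suppressor calls without literature input
  (UA, DS, US, DA — see `?classify_tf`). TFs enriched in both directions
  (UR/DR) or not differentially expressed (NTR) cannot be phased this way
  and are excluded; they may well matter biologically (post-transcriptional
  activation, cell-type-specific action) but the data at hand cannot sign
  them.
* **Sign consistency.** A regulator → target link is only interpretable if
  the target's observed direction agrees with the regulator's mode:
  activators explain co-directional targets, suppressors opposite-direction
  targets. Over the four classes this admits 8 of the 16 ordered pairs
  (UA–UA, UA–US, DS–UA, DS–US, US–DA, US–DS, DA–DA, DA–DS); the package
  derives the set from the rule and its tests cross-check the enumeration.

The classified nodes split into a stimulus-**R**epressed subnetwork
(DA + DS: active before the stimulus, switched off by it) and a
stimulus-**A**ctivated one (UA + US). Within the DA–DA core, tiers order
the hierarchy: tier 1 nodes have only outgoing core arcs (self-loops do
not count as input), tier 2 nodes are triggered by tier 1, tier 3 collects
the rest.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `upstream_len` | 1000 bp | promoter window 5′ of the TSS; the scale at which plant promoter elements concentrate, and the standard window for this kind of peak-set screen |
| `alpha` | 0.001 | BH-FDR level for the enriched flag; strict because hundreds of peak sets × 2 directions are tested and classification consumes the *calls*, not the p-values |
| `min_overlap_bp` | 1 | any overlap binds; peaks "in" a promoter is the natural reading, and peak boundaries are caller-dependent anyway |
| `bh_pool` | `"run"` | BH pool = all tests of the run (every peak set × both directions). Pooling per direction is available (`"per-direction"`); the run-wide pool is the more conservative interpretable choice |
| `tier2_rule` | `"any-parent"` | "triggered by tier 1" read inclusively: one tier-1 parent suffices. `"all-parents"` gives the strict reading (all non-self parents in tier 1) |
| `tss_rule` | `"most-upstream"` | representative TSS of multi-isoform genes = the most upstream start, maximizing promoter coverage; `"first-listed"` keeps annotation order |

Library labels (e.g. `"col"` native vs `"colamp"` demethylated DAP-seq
libraries) are processed in separate runs — the binding landscapes differ
too much to pool — and `compare_link_sets()` quantifies their agreement.

## Coordinate conventions and degenerate inputs

Internally every interval is 0-based half-open (BED-native); GFF3 is
converted on read. `tss` denotes the first transcribed base, and the
promoter never includes it: `[max(0, tss − L), tss)` on `+`,
`[tss + 1, tss + 1 + L)` on `−`. A peak starting exactly at a promoter's
`end` therefore does not overlap it. Reflecting all coordinates and
flipping strands maps `+` promoters exactly onto `−` promoters — a
symmetry the test suite exercises.

Degenerate cases are defined, not fatal: promoters clipped to zero length
(TSS at a contig edge) are dropped from the universe with a report; an
all-zero `a` cell gives p = 1; an empty DEG direction gives p = 1 for all
its tests; an empty classified set yields a valid empty graph; a DA–DA
core made only of cycles has no tier-1 seed, so all its nodes are assigned
tier 3 with a warning rather than an error. The gene universe defaults to
every annotated gene with a mappable promoter; an explicit universe can be
supplied. Genes appearing in both DEG lists are a hard error, since every
downstream rule conditions on a unique direction.

The one-sided Fisher p-value is computed as the hypergeometric upper tail
(`phyper(a − 1, a + c, b + d, a + b, lower.tail = FALSE)`); the test suite
pins it to an exact rational tail sum for every 2×2 table with `N ≤ 30`
(relative error below 1e−12) and to `fisher.test(alternative = "greater")`
on random tables. BH adjustment wraps `p.adjust(method = "BH")` and is
checked against a naive step-up reimplementation.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` plants a known network and emits exactly the files
the readers consume. Its design goal is *provable* ground truth:

* Genes occupy 3 kb slots (shuffled order, random strands) on one
  synthetic chromosome, so promoters can never overlap and every peak
  supports exactly one gene.
* Every planted edge becomes a peak inside the target's promoter. Because
  a meaningful edge's target always shares the regulator's enrichment
  direction, edge peaks double as enrichment evidence.
* Each TF's peak set is salted with additional background-DEG promoters
  until the planted test passes: the smallest bound count `a` with
  `p(a) × n_tests ≤ α` is found from the hypergeometric tail (a
  Bonferroni-style margin that implies the BH q-value passes as well).
  For TFs enriched in both directions the two demands couple — genes bound
  for one direction occupy cell `c` of the other — and are solved by
  fixed-point iteration. The generator re-verifies every planted test with
  `fisher_pvalue()` before writing a single file, and an infeasible demand
  fails with the approximate universe size that would be needed.
* Salt and noise never touch TF-coding promoters, so no spurious link can
  arise; promoter noise lands in neutral-gene promoters, which only
  weakens the planted tests (the salt calculation compensates), and
  intergenic noise lands in a promoter-free zone.
* `generate_fc_strata()` adds |log2FC| values by stratum. TF genes take
  their own stratum; a background DEG inherits the strongest stratum among
  the TFs it supports, so refiltering at a high threshold never starves a
  strong TF of its evidence mid-sweep.

The default scale — 200 genes, 10 TFs (4 DA, 1 DS, 2 US, 2 UA, 1 NTR
decoy), 11 edges, one chromosome — runs the full pipeline in about a
second, and the planted class ratios echo the repressed-heavy structure
typical of stimulus-response networks. Fixtures deliberately do **not**
emulate read-level signal, peak-width or score distributions, overlapping
promoters, multi-isoform TSS ambiguity, correlated binding between related
TFs, or enhancer-range regulation. Passing the recovery tests therefore
shows the *inference logic* is correct under its own assumptions, not that
those assumptions hold in any particular organism or dataset.

## Design choices where the procedure was genuinely open

* **Minus-strand promoter.** Defined as the kilobase genomically right of
  the TSS, excluding the TSS base itself: `[tss + 1, tss + 1 + L)`. Stated
  prominently because off-by-one conventions differ between tools.
* **Gene vs peak counting.** The 2×2 table counts *genes*, binarized on
  any overlap; counting peaks would let one promoter with many peaks
  dominate the margin and break the hypergeometric model.
* **Merging multiple peak sets per TF.** Each set is tested separately; a
  TF counts as enriched in a direction if *any* of its sets is, and all
  supporting sets are recorded. Aggregation precedes classification, so a
  TF with one set enriched up and another down takes the DR/UR path.
* **Self-regulation.** Self-links are emitted (only DA–DA and UA–UA can
  be meaningful), excluded from tier in-degree, and included in support
  counts.
* **Background universe.** All annotated genes with a mappable promoter,
  not just DEGs — the contingency table asks whether binding concentrates
  among DEGs relative to the genome the peaks could have landed in.

## Problem sizes used by the test and acceptance runs

The invariant checks enumerate all 46,376 2×2 tables with `N ≤ 30` and
1,000 random p-vectors of length 1–500; recovery, noise-robustness and
sweep checks use the default 200-gene/10-TF fixture with seeds fixed per
test. The whole suite completes in under a minute on one CPU.

## Known limitations

Promoter-window regulation misses distal and intragenic binding; the
classification trusts the DEG calls and inherits their thresholds (hence
`robustness_sweep()`); binding-competent is not binding-occupied, so links
are hypotheses ranked by evidence, not demonstrated regulation; and TFs
absent from the peak-set collection are invisible to the method. The
activator/suppressor calls are condition-specific summaries — a TF
classified here as a suppressor may act as an activator elsewhere, and
apparent suppression can arise from competition between activators for
shared sites rather than from a repression domain.
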