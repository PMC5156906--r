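---
title: "Methods: motif definitions, the substrate funnel, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif definitions, the substrate funnel, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimfunnel)
```

## The motif model

Calcineurin engages substrates through two docking SLiMs rather than
through phosphosite consensus. `slimfunnel` encodes both as
**position-class patterns**: an ordered list of allowed-residue sets, one
per position, with `x` a wildcard. Matching is exact set membership — there
is no scoring, no position weighting, and no mismatch tolerance. This is
deliberate: the definitions themselves were derived from structures and
confirmed binding sites, and the question each scan answers is "is this
window inside the motif's language?", not "how motif-like is it?".

The three LxVP-family definitions are nested by construction:

| name | pattern | language size |
|---|---|---|
| `canonical_pilxvp` | `[NQDESRTH]-[YTDFILV]-L-x-V-P` | 8·7·20 = 1 120 |
| `expanded_pilxvp` | `[NQDESRTH]-[YTDFILV]-L-x-[VPL]-[PK]` | 6 720 |
| `structural_pilxvp` | `[NQDESRTH]-[YTDFILV]-L-x-[VPLIH]-x` | 112 000 |

since {V} ⊂ {V,P,L} ⊂ {V,P,L,I,H} and {P} ⊂ {P,K} ⊂ anything. Dividing by
20⁶ gives exact per-window match probabilities under a uniform iid
background (1.75×10⁻⁵, 1.05×10⁻⁴, 1.75×10⁻³), which the test suite checks
empirically. `classify_hexamer()` exploits the nesting to assign each
6-mer a unique label (`canonical` > `expanded_only` > `structural_only` >
`no_match`); ties are impossible.

Conventions that matter for comparing printed sites:

* **Coordinates are 1-based and inclusive**, matching the superscript
  residue-numbering convention used for published docking sites.
* **All overlapping matches are reported.** PROSITE-style scanning does not
  consume residues; per-protein motif counts can therefore exceed protein
  counts (the "n hits in m sequences" pattern).
* **Case is ignored** — lowercase letters in motif notation conventionally
  mark wildcard positions, never sequence case.
* **Ambiguity codes** (X, B, Z, U, O) fail every constrained position and
  satisfy wildcards: a match is never claimed on unknown residues.
* The structural definition's fifth position is the set {V,P,L,I,H}
  regardless of the order it is written in.

Two PxIxIT dialects are scanned: `P-x-x-x-[IV]-[TDH]` (NFAT/PVIVIT-like)
and `P-x-x-x-x-[IV]-[TDH]` (AKAP79-like, one extra spacer). Their union is
deduplicated by (start, dialect), because a 7-mer window can legitimately
satisfy both dialects at different offsets.

## The funnel

A raw proteome scan for a 6-residue class pattern is dominated by chance
matches. The funnel keeps a match only if it looks like a real docking
site:

1. **Disorder (IDR) filter.** SLiMs function in intrinsically disordered
   regions. A match survives if the aggregation of per-residue disorder
   scores over its own window reaches the threshold (default 0.4, the
   conventional disorder cutoff). Scores are *consumed*, never computed:
   any per-residue predictor in [0,1] (either IUPRED mode, or the
   synthetic generator) satisfies the input contract, which is why the
   threshold — not the predictor — is part of the configuration.
2. **Phosphosite filter.** A substrate must have something to
   dephosphorylate: the protein needs ≥ 1 annotated pSer/pThr anywhere in
   its sequence. Presence is annotation-based; unannotated serines do not
   count.
3. **PxIxIT co-occurrence.** Docking is bivalent; the protein must also
   carry a PxIxIT site, itself subject to the same disorder criterion
   (toggle `require_pxixit_in_idr` to relax this).

Filters 2 and 3 branch **in parallel** from the IDR-stage protein set and
are then intersected. This is not equivalent to applying them sequentially
only in what it lets you report: the cross-tabs (both / PxIxIT-only /
phospho-only / neither) are the scientifically interesting margins —
PxIxIT-only proteins, for instance, are candidate CN *regulators* rather
than substrates, or substrates whose phosphosites are simply not yet
annotated.

Design choices that were genuinely open:

* **Window aggregation.** "The motif lies in a region with disorder
  ≥ 0.4" underdetermines the rule: whether every residue, the mean, or
  any residue of the 6-mer window must pass is open; the default is
  the **mean** (robust to a single-residue dip inside an otherwise
  disordered window), with `all` and `any` provided so the ambiguity is
  explorable rather than hidden.
* **Membership vs provenance.** A protein's funnel membership is decided
  by its surviving matches, but per-match provenance is kept, so motif
  counts and protein counts can differ at every stage.
* **Multi-motif proteins** are counted at the IDR stage (proteins with ≥ 2
  disordered motif instances), the stage at which that quantity is
  biologically quoted.
* `validate_conserved()` deliberately applies **no filters**: recovering
  known interactors is a raw sequence-presence question, and its match
  lists feed the logo/PPM builder.

## Distance and logo analytics

Phosphosite distances are anchored at the motif's **nearest edge**:
`position − end` for C-terminal sites, `start − position` for N-terminal
ones; sites inside the motif are ignored. A site qualifies when its
distance is at least 9 residues (C-terminal) or 20 residues (N-terminal) —
the separations needed to span the ~30 Å between the docking pocket and
the active site. Because the word "cutoff" also admits a maximum-distance
reading, both behaviours sit behind `cutoff_mode = "min"/"max"`, with
"min" the default per the mechanistic rationale. Each match's orientation
is that of its nearest qualifying site (nearest in sequence, not smallest
index); equidistant ties resolve **C-terminal**, the dominant orientation,
deterministically. The `near_window` parameter (default 50 residues) only
affects the "first phosphosite nearby" fraction, not qualification.

The PPM is plain column frequencies over aligned instances — no
pseudocounts, no small-sample correction — with per-column information
content `IC_j = log2(20) − H_j` bits, bounded by [0, log₂20 ≈ 4.32]. Two
instances differing in one position give `IC = log2(20) − 1 ≈ 3.32` bits
in that column, the worked example frozen in the tests. Export formats are
MEME minimal-motif and TSV; graphical rendering is out of scope — the
numbers are the test surface.

Localization uses a fixed eight-term vocabulary (`nucleus`, `membrane`,
`intracellular_transport`, `cytoplasm`, `mitochondrion`, `secreted`,
`cytoskeleton`, `other`); unmapped labels and unannotated proteins
collapse to `other` so fractions always sum to 1 over the queried set.

## The synthetic benchmark

`generate_dataset()` emulates the statistical structure of an annotated
proteome, not its biology:

* **Sequences** are iid draws; the default background is uniform over the
  20 residues so the analytic per-window match rates above are exact, and
  a human-like composition preset (`background = "human"`) exists for
  realism checks.
* **Disorder** is a block model: high-scoring blocks ([0.5, 1.0], safely
  above threshold) on a low baseline ([0, 0.3], safely below), roughly 3
  blocks per protein of 30–80 residues. Real disorder scores are
  autocorrelated and hover near the threshold; the funnel, however, only
  ever sees thresholded windows, so block structure is the minimal
  sufficient statistic. Planted windows never straddle a block boundary,
  making `in_idr` flags unambiguous under every aggregation mode.
* **Plants** are sampled uniformly from the requested class's language
  (for `expanded_only`, uniformly from expanded-minus-canonical by
  rejection), one per protein, placed ≥ 50 residues from either terminus
  so planted phosphosite distances are never truncated. Defective plants
  omit exactly one qualification — ordered placement, no phosphosite
  annotation, or no PxIxIT — and, for the PxIxIT case, chance PxIxIT
  matches are scrubbed from the host (one constrained position per match
  mutated to G, which can only destroy matches), so each defective plant
  is lost at exactly its designed stage.
* **Phosphosites** on host proteins are placed C-terminal with probability
  0.8 at 9–50 residues (N-terminal at 20–50 otherwise), mirroring the
  80/20 orientation preference and the within-50-residues tendency of
  curated candidates; background proteins get 1–3 sites at random
  positions with probability 0.8. **Localization** is drawn with nucleus
  0.33, membrane 0.18, intracellular transport 0.13, other 0.36.
* Every emitted truth entry is re-verified against the emitted data before
  the generator returns, and protein ids embed the seed so a truth
  manifest cannot be scored against the wrong dataset.

What passing tests on this generator do **not** show: recovery on real
proteomes, where disorder predictions are noisy near the threshold,
phosphosite annotation is biased toward well-studied proteins, and motif
occurrence correlates with composition. The generator is a correctness and
calibration instrument, not a realism claim; in particular the published
proteome-scale hit counts depend on a specific sequence database release
and disorder-predictor build and are not reproduction targets here.

## Numerical and scale choices

Scanning is exact set membership, so there are no tolerances in the match
path. PPM column sums are asserted to 1e-9; information content is exact
arithmetic. Statistical tests (background rates, orientation and
localization calibration) use fixed seeds and 4-standard-deviation
binomial/Poisson bands, a ~6×10⁻⁵ false-alarm rate per check. The test and
acceptance runs use proteomes of 20–400 proteins (up to 200 × 10 000
residues ≈ 2×10⁶ windows for background-rate checks, giving ≈ 35 expected
canonical matches), and 24–80 plants per recovery or calibration run —
sizes chosen so binomial error bands are a few percent wide while a full
suite completes in well under a minute.

## Known limitations

* Exact class matching cannot rank candidates; borderline sequences (for
  example a slightly suboptimal π residue) are invisible by design.
* The disorder contract trusts the provided scores; profiles from
  different predictors are not harmonized.
* One localization category per protein; multi-compartment proteins must
  be reduced upstream.
* The funnel treats annotation absence as evidence (no pSer/pThr → not a
  substrate candidate); on sparsely annotated proteomes the phospho filter
  is the dominant, and most biased, loss stage.
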