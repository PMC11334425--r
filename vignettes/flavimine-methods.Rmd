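---
title: "Methods: mining flavinylation-based electron transfer systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining flavinylation-based electron transfer systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavimine)
```

## The discovery procedure

ApbE covalently attaches FMN to a degenerate [S/T]GA[S/T] motif, modifying
the final Ser/Thr. Because flavinylation substrates are typically encoded
near the `apbE` gene that modifies them, `flavimine` infers candidate
substrates from three independent lines of evidence, conjoined:

1. **Neighborhood**: the protein's gene lies within the ±`window_k` genes
   flanking an anchor-family (`apbE`-like) gene on the same contig.
   Neighborhoods are counted in genes (0-based ordinals along the contig),
   not base pairs, and are clipped at contig edges, so a window holds
   `min(a, k) + min(n-1-a, k) + 1` genes for an anchor at ordinal `a` on an
   `n`-gene contig. Strand is recorded but plays no role in windowing, and
   non-coding rows count toward the window. Overlapping windows around
   distinct anchors are reported separately, never merged.
2. **Family**: the protein's best-match domain family — the lowest
   full-sequence E-value at or below `evalue_cutoff`, ties broken by higher
   bit score then lexicographic accession — is one of the configured target
   families. Annotation comes either from `hmmsearch --tblout` files (the
   fidelity path) or from the built-in ungapped PSSM scanner.
3. **Motif**: the protein carries at least one motif site. All matches at
   step 1 are reported, overlaps included; `X` never matches. Proteins with
   more than two sites are flagged *multi-flavinylated*.

The anchor family is a parameter rather than hard-coded: mining can anchor
on `apbE` and look for substrate families, or anchor on a candidate family
and measure how often `apbE` co-occurs — both orientations use the same
window machinery, and `colocalization_frequency()` reports the fraction of
anchor windows containing a target, overall and per phylum.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_k` | 5 | genes | the standard five-genes-up/five-down neighborhood for functional association |
| `evalue_cutoff` | 0.001 | E-value | conventional stringency for best-match Pfam annotation |
| motif | `[ST]GA[ST]` | residues | the canonical ApbE recognition motif; relaxed variants are expressible via `motif_pattern()` but off by default because the accepted deviations are not standardized |
| `tm_window` / `tm_threshold` | 19 / 1.6 | residues / KD units | classic Kyte–Doolittle settings for membrane-spanning helices |
| `heme_max_dist` | 6.0 | Å | bis-His axial NE2–NE2 across a heme iron sits near 4.2 Å; 6.0 leaves room for model error |
| `heme_min_seq_sep` | 10 | residues | excludes trivially adjacent His pairs that cannot flank a heme; cross-chain pairs are exempt, supporting homodimer sites |
| `min_ic` | 3.0 | bits | a column must concentrate most of its probability mass on one residue (max is log2(20) ≈ 4.32) |
| `proximal_cutoff` | 15 | Å | generous reach for a motif hydroxyl to engage a flavin pocket in a predicted model |

## Numerical and representational choices

- **Coordinates** are 1-based inclusive (GFF3 convention); gene ordinals are
  0-based and dense per contig after indexing, so window arithmetic is pure
  integer arithmetic and never depends on input row order.
- **Transmembrane segments** use the center-residue convention: each
  window's mean hydropathy is assigned to the window's central residue, and
  a segment is a maximal run of qualifying centers. This keeps a single
  hydrophobic stretch from absorbing its polar flanks — a 19-Ile core
  flanked by Asp yields one segment whose residues are all Ile (mean
  hydropathy exactly 4.5) — and two planted stretches separated by at least
  the window length are never merged.
- **Information content** is `log2(20) − H(p)` over non-gap frequencies;
  gaps are excluded from frequencies rather than treated as a 21st symbol,
  and low-occupancy columns (< 0.5 by default) are flagged, not dropped —
  standard sequence-logo practice. No small-sample correction is applied by
  default; at the row counts used here the positive bias of finite sampling
  is far below the 3.0-bit selection floor.
- **PSSM scanning** is ungapped: the best window is the maximum sum of
  per-column log-odds (leftmost on ties), and significance is an empirical
  p-value from seeded residue shuffles of the query re-scanned with the same
  profile. Such p-values are bounded below by `1/(n_shuffles+1)`, so the
  scanner path needs a cutoff above that floor (e.g. 0.02 at 60 shuffles);
  full profile-HMM alignment and E-value calibration are out of scope —
  ingesting real `hmmsearch` output is the high-fidelity path.
- **Superposition** is the Kabsch algorithm via SVD of the cross-covariance
  matrix with a determinant correction enforcing a proper rotation; fewer
  than 3 pairs or collinear point sets are rejected as underdetermined.
  Correspondence is an explicit input — sequence-independent structural
  alignment is a non-goal.
- **Heme sites** use NE2 as the coordinating atom with ND1 as fallback when
  NE2 is absent from the model.
- **Determinism**: all tabular output is tab-delimited UTF-8 with
  `.`-decimal formatting independent of locale; manifests carry versions,
  seeds, parameters and input checksums but no timestamps, so identical
  configurations produce byte-identical outputs. Outputs are staged and
  renamed into place only on success.

## What the synthetic generator emulates — and what it does not

`simulate_genomes()` produces single-contig genomes of ordered genes with a
planted anchor+target pair (probability `p_cluster`, uniform nonzero offset
within the window), targets carrying an exact number of motif sites, and
GTDB-style lineages cycling over four phyla. Background proteins are
**rejection-sampled to be motif-free**, a deliberate bias relative to
nature: it makes planted site counts exact ground truth, so recovery tests
are sharp. Consequently, perfect precision/recall on these fixtures
demonstrates the correctness of the window/annotation/motif machinery — not
the real-data false-positive rate, where chance [S/T]GA[S/T] matches are
common and the motif criterion is intentionally weak evidence on its own.
Real mining should lean on the hmmsearch annotation path and treat motif
counts as supporting evidence. Similarly, `simulate_structure()` emits
minimal models (ideal-helix CA traces plus exact planted NE2/OG
pseudo-atoms), sufficient for the geometric detectors but not physically
realistic side-chain geometry, and `simulate_msa()` draws columns i.i.d. —
no phylogenetic correlation between rows, so conservation estimates on real
alignments (where sequences are related) will be more optimistic than the
i.i.d. case.

Validation problem sizes were chosen to keep the whole suite fast while
leaving no statistical ambiguity: 200 genomes × 40 genes for end-to-end
recovery, 1,000 sequences against the brute-force motif oracle, 200
profile/sequence pairs for the PSSM oracle, 100 exact and 20 noisy
superposition trials, 10,000 rows for the information-content bias check.

## Known limitations

- One best family per protein; Pfam clan resolution and per-domain E-values
  are not modeled.
- The "frequently co-localized" notion is reported as a frequency, never
  thresholded — the cutoff is left to the analyst.
- No signal-peptide or cell-surface localization filter is applied to
  candidates.
- Pseudogenes and genes without protein products count toward windows; the
  treatment of such rows in genome-scale annotation pipelines varies.
- The motif-to-pocket measure is a static distance; a tethered flavin's
  conformational reach is not modeled.
- Transmembrane calls are sequence-hydropathy-based, not membrane-plane
  fitting in 3D.
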