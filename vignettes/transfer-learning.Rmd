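---
title: "Knowledge-transfer learning for MMP cleavage-site prediction: methods and design"
author: "CleaveTransfer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-transfer learning for MMP cleavage-site prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Matrix metalloproteases (MMPs) hydrolyse specific peptide bonds of their
substrate proteins. For several family members only a few dozen substrates
with experimentally mapped cleavage sites are known, which is too little to
train a conventional per-protease classifier well. The observation this
package builds on is that MMP substrate-cleavage sites share strong
family-wide sequence regularities — glycine enrichment at P7, P4, P1, P3'
and P6', proline at P3 and P5', leucine at P1' (Schechter–Berger numbering
around the scissile P1|P1' bond) — on top of protease-specific preferences.
A model for a data-poor *target* protease can therefore borrow statistical
strength from the data-richer *source* proteases.

## The procedure

1. **Data preparation** (`readSubstrates`, `reduceRedundancy`,
   `extractWindows`, `sampleNegatives`). Substrates are clustered at 70%
   global sequence identity and one representative kept per cluster, so that
   homologous substrates cannot straddle cross-validation folds. Every
   peptide bond yields a 16-residue window (P8–P8'); windows that overrun a
   terminus are padded with `X`. All annotated sites are positives; a 1:3
   positive:negative ratio is enforced by down-sampling the negative
   candidates, preferring (weight 3:1) candidates whose P1 residue is
   predicted buried — buried bonds are the most reliable negatives since
   proteases cannot reach them.
2. **Encoding** (`encodeWindows`). Eight schemes produce 4461 named
   features per window: AAindex physicochemistry (16 positions x 64
   indices = 1024), amino-acid composition (20), one-hot Binary
   (16 x 21 = 336), BLOSUM62 rows (336), charge/hydrophobicity summaries
   (3 properties x 3 segments = 9), k-spaced residue-pair composition
   CKSAAP for k = 0..5 (2400), per-residue disorder probability (16), and
   logistic-squashed PSSM scores (320).
3. **Common knowledge** (`extractCommonKnowledge`). The labelled windows of
   all source proteases are pooled and the top 50 features selected with
   greedy mRMR (MID objective, plug-in mutual information on
   mean-plus/minus-sd ternary discretisation). These 50 features are the
   knowledge transferred to the target.
4. **Target modelling** (`mrmrRank`, `buildCandidateList`,
   `forwardSelect`). The target's own top-100 mRMR features are appended
   (deduplicated, common features first). Walking that candidate list, one
   feature is added at a time; each prefix trains an epsilon-SVR (RBF
   kernel) and is scored by mean five-fold stratified cross-validated AUC
   on fixed seeded folds. The AUC-maximising prefix wins (ties go to the
   shorter prefix) and is refitted on all target rows.
5. **Baseline** (`trainBaseline`). The non-transfer reference merges all
   proteases, takes the plain mRMR top-100, and evaluates an SVR on the
   target by the same cross-validation — no source/target distinction.
6. **Evaluation and profiling** (`computeMetrics`, `rocAUC`,
   `crossValidate`, `cleavageEntropy`). Confusion metrics, Mann–Whitney
   AUC, and per-position Shannon entropies of cleaved windows, the standard
   quantitative readout of positional substrate specificity.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| window length | 16 | P8–P8'; the recognition-relevant neighbourhood |
| identity threshold | 0.70 | redundancy clustering cut-off |
| negative ratio | 3 | negatives per positive after resampling |
| buried weight | 3:1 | preference for buried-P1 negative candidates |
| `mCommon` | 50 | features transferred from the source pool |
| `mTarget` | 100 | target-ranked candidates |
| SVR cost/gamma grid | 2^-5..2^15 / 2^-15..2^3, x4 steps | libsvm-convention search ranges |
| epsilon | 0.1 | epsilon-SVR loss width |
| CV folds | 5 | stratified, seeded |
| cutoff | 0 | classification threshold on the +1/-1 regression score |

## Numerical and design choices

* **Padding.** Terminal pads are `X`: zero in the 20 standard Binary slots
  with the 21st (non-standard) slot set, the BLOSUM62 `X` row, the
  per-index mean in AAindex, excluded from composition and CKSAAP counts
  (CKSAAP's `N_Total` shrinks accordingly, from 15..10 on full windows),
  and the uninformative constant 0.5 in the disorder and PSSM blocks.
* **AAindex table.** The 64-index default is built from the AAindex
  distribution shipped with `seqinr`: the first 64 accessions, in accession
  order, complete for all 20 residues. Any 64 x 20 (or other-sized, with a
  warning) table can be substituted; downstream code only relies on the
  dimension contract.
* **CHARGE-Hyd structure.** The nine features are three properties (mean
  net charge with K/R = +1, D/E = −1, H = +0.1; aromatic content over
  F/W/Y/H; |mean charge| / (mean Kyte–Doolittle + 5.0)) over three segments
  (full window, P8–P1, P1'–P8'). A property-by-segment grid is the
  conventional reading of a 3 x 3 layout; per-property min/mean/max was
  considered and rejected as less standard.
* **mRMR variant.** MID (difference) rather than MIQ (quotient) — the
  canonical default — with ties broken by column order so rankings are
  exactly reproducible; mutual information uses base-2 logs, so relevance
  is in bits. The greedy trace is tested against an exhaustive
  recomputation of the objective at every step.
* **F-score.** Two variants are computed: the standard
  F1 = 2TP/(2TP+FP+FN) (headline) and an "as printed" variant
  2TP/(2TP+FP+TN) that some benchmark tables use; reporting both avoids
  silently reinterpreting published numbers.
* **Undefined metrics** (zero denominators) are `NA`, never silently 0.
* **Cleavage entropy.** Per-position Shannon entropy in bits with plug-in
  frequencies over the 20 standard residues; maximum log2(20) ≈ 4.32.
  Because published heatmaps are sometimes drawn in the inverted
  convention (high colour = high specificity), the profile carries both the
  raw entropy and the inverted score log2(20) − entropy; a normalised
  (divide by log2(20)) variant is available by flag.
* **Grid search once per candidate list.** Re-optimising (cost, gamma) at
  every forward-selection prefix multiplies cost by the grid size for
  little measured benefit on the synthetic scenario; the stricter protocol
  remains available via `perPrefixGrid = TRUE`.
* **Baseline corpus.** The baseline's top-100 features are selected on the
  merged data of all proteases (the merged-model reading); selection on the
  target alone is available via `targetOnlySelection = TRUE`.
* **Reported CV folds.** Forward selection and reported cross-validation
  use seeded stratified folds; reporting uses the fold seed supplied by the
  caller, so selection folds and reporting folds can be decoupled by
  passing different seeds.

## The synthetic generator

`defaultMMPLikeSpec()` emulates the structure of curated MMP substrate
sets: six domains (five source, one target) of 23–44 substrates and 85–290
cleavage sites each, substrate lengths 160–400 aa drawn from a uniform
background over the 20 residues. Every planted site's 16-mer is overwritten
position-wise from a mixture `strength * motif + (1 - strength) *
background`, with the shared motif above plus two private preferred
positions per domain; `strength = 0.6` is the package's reference
condition, chosen so that planted per-position residue frequencies
(0.6 + 0.4/20 = 0.62 for the preferred residue) sit in the range seen in
real cleavage-site logos for strongly enriched positions. Site placement
enforces 16-residue separation so planted windows never overlap.

What the generator does **not** emulate: realistic amino-acid background
composition (available via the `background` argument), homology between
substrates, evolutionary profiles (PSSM/disorder encoders fall back to
constants on synthetic data), and annotation noise (real databases contain
missed cleavage sites among the "negatives"). Passing the synthetic
recovery tests therefore demonstrates that the pipeline's machinery —
encoding, ranking, transfer, selection, evaluation — is correct and that
transfer recovers genuinely shared signal; it does not certify real-data
accuracy, which additionally depends on profile quality and database
completeness.

## Problem sizes used by the test-suite and acceptance runs

The recovery experiments run the full default scenario scale (about 3,800
windows across six domains, 2,756 features from the AAPair + Binary +
CKSAAP subset — the schemes that need no external profiles) with a compact
(cost, gamma) grid of {1, 32} x {0.001, 0.01}; medians are taken over 10
seeds in the test-suite and 5 seeds in the acceptance script. These sizes
are the package's reference experiment; the full 4461-feature space and the
full libsvm grid behave identically mechanically and remain the defaults
for real analyses.

## Known limitations

* The internal greedy identity clustering is a reproducible stand-in for
  CD-HIT's word-filtered heuristic; on large substrate sets CD-HIT should
  be run externally and its `.clstr` file passed through.
* Plug-in mutual information on ternary bins is biased upward for tiny
  samples; with fewer than ~30 windows per class, mRMR rankings become
  noisy (the generator's smallest domain has 85 sites, i.e. 340 windows).
* The protocol ranks the target's candidate features on the full target
  dataset before cross-validating, so the reported AUC trace carries
  feature-selection optimism whenever the feature space is much larger than
  the number of target windows — on null data (no planted signal, ~700
  windows, ~2,800 candidate features) this floor sits well above chance
  even though features selected without target rows score at chance.
  `transferLearnCV()` provides the unbiased alternative: a nested outer CV
  in which the target mRMR ranking, candidate list and forward selection
  are all redone inside each outer training fold, at roughly five times
  the cost. Its held-out estimates are at chance on null data and should
  be preferred whenever an honest generalisation estimate matters.
* The SVR score is an uncalibrated margin, not a probability.
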