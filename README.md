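# CleaveTransfer

Knowledge-transfer learning for matrix-metalloprotease (MMP) substrate
cleavage-site prediction.

MMPs cleave their protein substrates at specific peptide bonds, but for
several family members only a handful of experimentally verified cleavage
sites exist — too few to train a reliable per-protease predictor. MMP
cleavage sites nevertheless share family-wide sequence preferences around
the scissile P1|P1' bond (glycine at P7/P4/P1/P3'/P6', proline at P3/P5',
leucine at P1'). CleaveTransfer exploits this: it distills *common
knowledge* from data-richer source proteases and transfers it to a
data-poor target protease.

For a target protease `t` with labelled P8–P8' windows, the model is

1. encode every 16-residue window into 4461 named features over eight
   schemes (AAindex, AAC, Binary one-hot, BLOSUM62, charge/hydrophobicity,
   CKSAAP, disorder, PSSM);
2. rank features on the pooled source proteases by mRMR
   (maximise I(f; y) − mean over selected s of I(f; s), in bits) and keep the
   top 50 as common knowledge;
3. append the target's own mRMR top-100 (deduplicated, common first) and
   forward-select: for each prefix of the candidate list, train an
   epsilon-SVR (RBF kernel, c and gamma grid-searched) and score it by mean
   5-fold stratified cross-validated AUC; keep the AUC-maximising prefix;
4. compare against a merged-data baseline (plain mRMR top-100 on all
   proteases pooled, no transfer), with sensitivity, specificity, accuracy,
   F-score, MCC and ROC/AUC reporting, plus per-position cleavage-entropy
   profiling S_i = −Σ_a p_a(i) log2 p_a(i) of substrate specificity.

A seeded synthetic substrate generator (`defaultMMPLikeSpec()`,
`generateScenario()`) emulates the source/target structure of curated MMP
substrate sets and makes the whole pipeline testable end to end without
external databases.

## Worked example

```r
library(CleaveTransfer)

spec <- defaultMMPLikeSpec(strength = 0.6, seed = 42)
scenario <- generateScenario(spec)           # 5 source domains + 1 target
fms <- lapply(scenario$datasets, encodeWindows,
              schemes = c("AAPair", "Binary", "CKSAAP"))
cfg <- svrConfig(costGrid = c(1, 32), gammaGrid = c(0.001, 0.01),
                 cvFolds = 5L, seed = 42L)
result <- transferLearn(fms, "target", mCommon = 50, mTarget = 100,
                        config = cfg)
result
#> TransferResult: 122 candidates (50 common, 72 target-novel)
#>   best prefix: 118 features, CV AUC 0.993

head(selectedFeatures(result), 8)
#> [1] "Binary.P5p.P" "Binary.P1p.L" "Binary.P3.P"  "Binary.P1.G"
#> [5] "Binary.P6p.G" "Binary.P7.G"  "Binary.P4.G"  "Binary.P3p.G"

cleavageEntropy(scenario$datasets$target)
#> EntropyProfile for target - 178 windows
#>   average entropy 3.196 bits (max 4.322)
```

The selected model's leading features are exactly the planted shared-motif
one-hot columns (P' -side proline, P1' leucine, the glycine positions) —
the common knowledge recovered from the source domains — and the target's
cross-validated AUC of 0.993 reflects the strong planted signal at motif
strength 0.6. The entropy profile averages 3.2 bits against the 4.32-bit
maximum: cleavage positions are constrained, the rest of the window is
near-random background.

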