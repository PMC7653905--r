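# trimorf

Per-residue prediction of **molecular recognition features (MoRFs)** —
short (5–25 residue) regions of intrinsically disordered proteins that
fold upon binding a structured partner — by **trisecting** each sequence
into two terminal zones and a middle zone and scoring them with separate
models.

Who it is for: bioinformaticians who have disordered protein sequences
plus per-residue structural-attribute predictions (secondary-structure
probabilities, ASA, backbone angles, half-sphere exposure, contact
number, e.g. SPIDER2 output) and want per-residue MoRF propensity
tracks, or who want to fuse such tracks with other MoRF predictors'
scores.

## Method

For a sequence of length *L*, residue *j* is represented by the window
`[max(1, j−20), min(L, j+20)]` (width 41 in the interior, truncated at
the termini). The window's *l* × *u* slice of the structural trace *M*
is reduced to a fixed-length descriptor by the lagged second moment

    AC(k, j) = (1/l) · Σ_{i=1..l−k} M(i,j) · M(i+k,j),   k = 1..DF, j = 1..u

(DF = 10; default channel: HSE-α upper-sphere count, so 10 features).
Note the divisor *l* and the absence of mean-centring — the descriptor
is implemented exactly as the method defines it.

Residues with `j ≤ 20` or `j > L − 20` are **terminal**, the rest
**middle**. One RBF-kernel SVM (`C = 1000`, `gamma = 0.0038`, z-scored
features) is trained per zone, on balanced positive/negative segments:
each MoRF run plus 20 residues of flank is a positive segment, and an
equally long negative segment is placed at random, disjoint from every
MoRF's flanked extent and touching the same zone. Decision values are
min–max normalized to [0, 1] over the training set.

Raw tracks are smoothed with the windowed rule
`score_j = (max(W_j) + median(W_j)) / 2` over a score window `W_j` of
half-width 12 (4/15 for MoRFpred-plus/MoRFchibi-style external tracks),
and multiple predictors' tracks can be fused by plain averaging, with an
optional re-smoothing at half-width 8. Evaluation pools all residues of
all sequences into one global ROC curve; AUC equals the Mann–Whitney
statistic with half credit for ties, and FPR-at-TPR summaries use the
smallest FPR among curve points reaching the target TPR.

A synthetic-data module generates annotated sequences plus structural
traces with a planted HSE signal (mean shift of 2 background standard
deviations inside each MoRF, autocorrelated noise), so the entire
train → predict → evaluate pipeline runs with no external data. See the
methods vignette (`vignettes/trimorf-methods.Rmd`) for the design
rationale and what the generator does and does not emulate.

## Worked example

```r
library(trimorf)

train  <- simulate_dataset(sim_config(n_sequences = 120, seed = 2024))
held   <- simulate_dataset(sim_config(n_sequences = 40,  seed = 2025))
bundle <- train_bundle(train, seed = 1)
bundle
#> <morf_bundle v1> flank 20, terminal + middle models
#>      model n_pos n_neg
#> 1 terminal    32    30
#> 2   middle   114   102

d      <- held[[1]]
smooth <- process_track(score_sequence(bundle, d$sequence, d$trace), 12)
smooth
#> <score_track> sim0001 [processed]: 519 residues, range [0.000, 0.453]

tracks <- lapply(held, function(h)
  process_track(score_sequence(bundle, h$sequence, h$trace), 12))
ev <- evaluate_tracks(tracks, lapply(held, `[[`, "sequence"))
ev$auc
#> [1] 0.8384…   # pooled over 549 MoRF and 12500 non-MoRF residues
round(ev$fpr_at_tpr, 4)
#> tpr_0.2 tpr_0.3 tpr_0.4 tpr_0.5 tpr_0.6 tpr_0.7 tpr_0.8 tpr_0.9
#>  0.0346  0.0406  0.0457  0.0551  0.0853  0.1151  0.2944  0.5213
```

The manifest shows the balanced per-zone sample counts (small imbalances
are sequences too short to place a negative segment). For the first
held-out sequence the true MoRF spans residues 299–303; the smoothed
track averages 0.300 inside it versus 0.183 outside, and the pooled AUC
says a random MoRF residue outscores a random background residue 84% of
the time. The FPR-at-TPR row reads, e.g.: to recover 70% of MoRF
residues you accept an 11.5% false-positive rate.

## Command line

```sh
trimorf simulate --out data/ --n 100 --seed 7       # FASTA + annotations + traces
trimorf train    --fasta data/sequences.fasta --annotations data/annotations.tsv \
                 --traces data/traces --out bundle.rds --seed 7
trimorf predict  --bundle bundle.rds --fasta data/sequences.fasta \
                 --traces data/traces --out scores.tsv
trimorf combine  --tracks scores.tsv,other.tsv --flanks none,4 --out combined.tsv
trimorf evaluate --scores scores.tsv --fasta data/sequences.fasta \
                 --annotations data/annotations.tsv --out report.json
```

(`trimorf` is the Rscript wrapper installed under `exec/`; equivalently
call `trimorf::morf_cli(c("simulate", "--out", "data"))`.) Formats:
FASTA sequences; TSV interval annotations (`seq_id`, `start`, `end`,
1-based inclusive); native structural TSV (`seq_id`, `pos`, `residue`,
channel columns) with a best-effort reader for SPIDER2-style output
(`read_structural_table(..., dialect = "spider2")`); score-track TSV
(`seq_id`, `position`, `residue`, `score`, `stage`).

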