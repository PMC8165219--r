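# peprank

Allele-specific prioritization of peptide–MHC class I binding by learning to
rank.

Identifying which 8–15-residue peptides bind a given MHC class I allele is a
key step in peptide vaccine design: bound peptides are what cytotoxic T cells
can see. Curated affinity databases mix quantitative IC50 measurements (nM,
smaller = stronger) with qualitative five-tier binding calls, and repeated
measurements often conflict. For selecting candidates, the *ordering* of
peptides matters more than exact IC50 values, so `peprank` trains an
allele-specific scoring function S(p) with pairwise ranking objectives
instead of regression. It is aimed at immunoinformatics users who want a
self-contained, inspectable implementation of ranking-based binding
prediction — from raw affinity tables to trained models, ranking metrics and
binding-motif analysis — with every component testable against synthetic
data with known ground truth.

## What is inside

* **Affinity preprocessing** — IC50 normalization
  `b = clamp(1 − log₅₀₀₀₀ x, 0, 1)`, five-level banding (level 5:
  IC50 ≤ 100 nM … level 1: > 5000 nM), and majority-vote consolidation of
  duplicated measurements (conflicting pairs are removed and logged).
* **Peptide encodings** — BLOSUM62 rows, one-hot, and a learned 20-dim
  embedding, concatenable; dual-end learnable position embeddings indexed by
  the offset from each end, so variable-length peptides share positional
  structure; middle padding to 15 ("GGFVPNMLSV" → "GGFVXXPNXXXMLSV").
* **Two scoring architectures** — `convm`: 1-D convolution over k-mers,
  batch norm, ReLU, self-attention pooling
  (`wᵢ = softmax(v tanh(W rᵢ + b))`, `c = Σ wᵢ rᵢ`) and a fully-connected
  head; `spconvm` additionally applies global kernels to the padded 15-mer
  and concatenates their output with the pooled local embedding. Forward and
  backward passes are hand-written matrix code, gradient-checked in the test
  suite.
* **Four objectives** — value-based hinge `max(0, c + (bᵢ−bⱼ) − (Sᵢ−Sⱼ))`,
  level-based hinge `max(0, r(lᵢ−lⱼ) − (Sᵢ−Sⱼ))`, a constrained variant that
  also ties same-level scores together, and a piecewise mean-square loss with
  one-sided penalties for qualitative entries (sigmoid-normalized scores).
* **Training** — SGD from lr 0.05, ×0.9 decay after 5 stale validation
  epochs, early stop after 20, best-epoch parameters returned; peptide-level
  5-fold cross-validated grid search selected by a hybrid regret score over
  AR100/HR100/AR500/HR500/AUC/ROC5/ROC10.
* **Ranking metrics** — average rank and hit rate of the promising set
  (IC50 < h nM), strict-indicator AUC, and truncated ROC_t against the top-t
  negatives.
* **Attention → motifs** — per-residue attention weights (k = 1), their
  accumulation into a position × amino-acid matrix, and correlation with
  external scoring matrices (stabilized-matrix sign convention: preferred
  residues score low, so recovered motifs correlate negatively).
* **Synthetic benchmark** — per-allele tables with a planted two-anchor
  scoring profile (offset 2 + terminal), mixed quantitative/qualitative
  entries, injected measurement conflicts, and exact ground truth.

## Worked example

Simulate an allele, preprocess, train a ranking model, evaluate, and inspect
the learned motif:

```r
library(peprank)
library(dplyr)

allele <- synthetic_allele(seed = 1)                 # anchors: position 2 + terminal
gen  <- generate_dataset(allele, n_peptides = 800, seed = 42)
cons <- preprocess_affinities(gen$data)
nrow(cons)                    # 760  (40 conflicting peptides removed)
head(cons, 3)
#>   allele      peptide       kind           ic50      b level
#> 1 SYN-A*01:01 AACTKFFIVTAHR quantitative  5181. 0.210      1
#> 2 SYN-A*01:01 ACFPKLLAG     quantitative 20813. 0.0810     1
#> 3 SYN-A*01:01 ACKAWYKNADI   quantitative  1265. 0.340      2

test_pep <- withr::with_seed(42, sample(cons$peptide, 160))
fit <- train_model(filter(cons, !peptide %in% test_pep),
                   model_config("convm", k = 1, loss_id = "hv"),
                   train_control(max_epochs = 100), seed = 42)
glance(fit)
#>   architecture loss  epochs best_epoch best_val_loss final_lr early_stopped
#> 1 convm        hv       100         93         0.348   0.0215 FALSE

preds <- score_peptides(test_pep, fit)
preds$ic50 <- gen$truth$ic50[match(test_pep, gen$truth$peptide)]
evaluate_ranking(preds)
#>   ar100 hr100 ar500 hr500   auc  roc5 roc10
#> 1  34.5 0.703  47.2 0.684 0.823 0.246 0.374

att <- collect_attention(test_pep, fit)
head(att, 4)
#>   peptide  position weight
#> 1 RPLEFGIA        1 0.0167
#> 2 RPLEFGIA        2 0.738     # the planted anchor draws the attention
#> 3 RPLEFGIA        3 0.0647
#> 4 RPLEFGIA        4 0.0849

promising <- gen$truth$peptide[gen$truth$ic50 < 500]
sm <- smm_like_matrix(collect_attention(promising, fit), frame = "padded")
motif_correlation(sm, -allele$profile, columns = allele$anchors)
#> -0.523
```

The held-out AUC of 0.82 says the model orders binders above non-binders on
unseen peptides at this small training size (larger runs reach ≥ 0.99); the
attention column shows the weight concentrating on the planted anchor at
position 2; and the negative motif correlation says the attention-derived
position × amino-acid matrix recovers the planted preference pattern under
the scoring-matrix sign convention. `autoplot(att)` and
`plot_motif_matrix(sm)` draw the corresponding heatmaps, and `tidy(fit)`
returns the per-epoch training log.

A thin command-line wrapper over the same functions ships in
`inst/cli/peprank.R` (`simulate`, `preprocess`, `train`, `gridsearch`,
`predict`, `evaluate`, `attention`, `motif`).

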