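# lncloc

Multi-label prediction of lncRNA subcellular localization from sequence,
with an interpretable, compartment-specific attention mechanism.

## What problem this solves

Long non-coding RNAs act where they are located — nucleus, cytoplasm,
chromatin, or the insoluble cytoplasmic fraction — and many occupy several
compartments at once. `lncloc` is for computational biologists who want
(i) calibrated per-compartment probabilities for lncRNA sequences and
(ii) a per-compartment map of *which sequence regions* drove each call, so
candidate localization elements (e.g. the AGCCC nuclear signal or repeated
RCCTCCC elements) can be read off the model rather than guessed.

## The model

A sequence (U read as T, capped at 8196 nt) is split into up to
`n_max = 512` consecutive bins; each bin is the mean of its overlapping
k-mer skip-gram vectors (k = 3, d = 128 at full scale). The bin matrix
passes through 8 Transformer blocks whose heads compute residual
pre-softmax attention with a learnable clipped relative positional
encoding:

    S_ij = alpha[b(i,j)] * (q_i . k_j) / sqrt(d_head) + beta[b(i,j)] + Prev_ij
    b(i,j) = clamp(i - j, -25, 25)

where `Prev` is the previous block's raw score matrix. A
localization-specific attention head then learns one softmax distribution
over positions per compartment j:

    alpha_j = softmax(V w_a^j + b_a^j),   s_j = sigmoid(alpha_j' V w_s + b_s)

trained with binary cross-entropy (Adam 3e-4, 4-epoch warm-up, linear
decay, batch 64). Positions whose attention weight exceeds `1/n_eff` (the
uniform expectation) are flagged, mapped back to nucleotide intervals,
scanned for IUPAC motifs, and exported as MEME-ready FASTA. The network,
including full backpropagation, is implemented in base R and verified
against finite differences and nested-loop oracles; the skip-gram embedder
is a small seeded C++ routine.

## Worked example

Generate a planted-motif dataset, fit a small model, and interpret it:

```r
library(lncloc)

train <- lncloc_simulate(synthetic_config(n_samples = 500, seed = 101))
test  <- lncloc_simulate(synthetic_config(n_samples = 100, seed = 202))

cfg <- lncloc_config(n_blocks = 2, n_heads = 4, hidden = 32, head_dim = 16,
                     ffn_dim = 128, n_max = 64, k = 5)
ctl <- lncloc_control(lr_peak = 3e-3, batch_size = 32, max_epochs = 120,
                      val_fraction = 0.2, patience = 25, seed = 5)
fit <- lncloc(train$records, train$labels, cfg, ctl)   # ~10 min on one CPU

pred <- predict(fit, test$records)
multilabel_metrics(test$labels, pred$probabilities)
```

```
Multi-label evaluation on 100 samples
  Ave-F1 0.864  (AvgPre 0.882, AvgRec 0.847)
  MiP 0.864  MiR 0.816  MiF 0.839
  P@1 0.930   average AUC 0.872
  per-label AUC: nucleus 0.835  cytoplasm 0.975  chromatin 0.865  insoluble_cytoplasm 0.811
```

`Ave-F1` is the harmonic mean of sample-averaged precision (over samples
with at least one call) and sample-averaged recall; `MiP/MiR/MiF` pool
true/false positives over all sample x compartment entries; `P@1` is the
fraction of sequences whose top-ranked compartment is correct; AUC is the
rank probability that a positive outranks a negative, per compartment.
Here the model ranks the right compartment first for 93% of held-out
sequences and calls compartments with micro-F1 0.84 — learned purely from
the planted sequence motifs.

Interpretation maps each compartment's attention back to sequence:

```r
out <- interpret_predictions(pred$results, test$records)
head(out$hits[, c("id", "label", "pattern", "start", "end", "match")])
```

```
          id   label pattern start  end match
1 synth_0001 nucleus   AGCCC    63   68 AGCCC
2 synth_0001 nucleus   AGCCC   219  224 AGCCC
3 synth_0001 nucleus   AGCCC   241  246 AGCCC
4 synth_0002 nucleus   AGCCC   707  712 AGCCC
5 synth_0002 nucleus   AGCCC  1147 1152 AGCCC
6 synth_0002 nucleus   AGCCC  1969 1974 AGCCC
```

Against the generator's ground truth, attention-flagged positions hit
planted-motif nucleotides far above the background rate:

```r
attention_enrichment(pred, test)$enrichment
#> [1] 3.09
```

A thin command-line front end wraps the same functions
(`inst/cli/lncloc`): `simulate`, `train` (with
`--no-localization-attention` / `--no-positional-encoding` ablation
flags and YAML configs), `predict`, `evaluate`, `interpret`.

## Data recipe for real corpora

The package is corpus-agnostic: any FASTA plus a label TSV
(`id<TAB>nucleus<TAB>cytoplasm<TAB>chromatin<TAB>insoluble_cytoplasm`, or
`id<TAB>labels` with comma-separated names) will train. A curated corpus
in the style the model targets is built by: retrieving
lncRNA-to-compartment annotations from a localization database (e.g.
RNALocate), merging entries by gene symbol, attaching sequences from
NCBI, reducing redundancy with `cd-hit-est` at an 80% identity cutoff,
keeping compartments with enough entries, and writing the result in the
two formats above. Those external services and tools are deliberately not
wrapped here.

## Truth JSON schema (synthetic fixtures)

`write_fixture()` emits `sequences.fasta`, `labels.tsv`, and
`truth.json`; the latter maps each record id to a map from label name to
a list of `[start, end)` 0-based nucleotide intervals of planted motifs:

```json
{"synth_0001": {"nucleus": [[104, 109], [871, 876], [1240, 1245]]}}
```
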