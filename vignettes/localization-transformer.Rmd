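---
title: "A localization Transformer for multi-label lncRNA compartment prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A localization Transformer for multi-label lncRNA compartment prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Long non-coding RNAs function where they reside: a chromatin-tethered
transcript regulates transcription differently from one exported to the
cytoplasm, and many lncRNAs occupy several compartments at once.
`lncloc` treats subcellular localization as a **multi-label** sequence
classification problem over four compartments — nucleus, cytoplasm,
chromatin, and insoluble cytoplasm — and predicts, for each input
sequence, four independent probabilities together with a per-compartment
attention profile over the sequence. The attention profiles are the
interpretability device: short localization elements (e.g. the AGCCC
nuclear-retention signal, or repeated RCCTCCC elements) should attract
the attention mass of the matching compartment.

## Model

### Sequence encoding

A sequence of length $L$ (capped at 8196 nt; `U` read as `T`, other
ambiguity codes as `N`) is split into
$n_{\mathrm{eff}} = \min(n_{\max}, \lfloor L/k \rfloor)$ consecutive,
non-overlapping bins whose lengths differ by at most one nucleotide
(longer bins first); $n_{\max} = 512$ positions at full scale. Each bin
is represented by the arithmetic mean of the embedding vectors of its
overlapping k-mers ($k = 3$, dimension $d = 128$ by default); k-mers
containing `N` contribute a frozen zero vector but stay in the
denominator, so ambiguous stretches shrink toward zero rather than
vanish. The k-mer vectors are pre-trained on the input corpus with
skip-gram and negative sampling (window 5, 5 negatives, 10 epochs,
seeded single-worker training, so tables are bitwise reproducible), then
loaded as a trainable lookup and fine-tuned during supervised training
(`finetune_embedding = FALSE` freezes them). Layouts shorter than
$n_{\max}$ are padded with masked positions that are provably inert:
padded rows are zero, attention never reads them, and the label head
renormalizes over real positions only.

### Residual-attention Transformer blocks

The bin matrix $X \in \mathbb{R}^{n\times d}$ passes through
`n_blocks = 8` identical blocks. Each head $h$ of block $t$ computes
pre-softmax scores

$$S^{(t,h)}_{ij} \;=\; \alpha^{(t,h)}_{b(i,j)}\,
  \frac{q_i \cdot k_j}{\sqrt{d_{\mathrm{head}}}}
  \;+\; \beta^{(t,h)}_{b(i,j)} \;+\; S^{(t-1,h)}_{ij},$$

where $b(i,j) = \mathrm{clamp}(i-j, -25, 25)$ is the clipped signed
relative distance, $\alpha$ (initialized at 1) is a learnable
multiplicative positional scale, $\beta$ (initialized at 0) an additive
positional bias, and $S^{(t-1,h)}$ the previous block's raw scores — the
residual pre-softmax attention idiom, with $S^{(0,h)} = 0$. Setting
$\alpha \equiv 1,\ \beta \equiv 0$ recovers plain scaled dot-product
attention, which is why the untrained network starts in that regime.
Queries, keys and values are widened to $d_{\mathrm{head}} = 64$ per
head by dedicated dense maps (eight heads; the widening avoids the
low-rank bottleneck of $d/H = 16$), and the concatenated heads are
projected back to $d$ by $W_O$. The block finishes with the classic
post-norm arrangement: add & layer-norm, a position-wise
ReLU feed-forward network of inner width $4d = 512$, add & layer-norm.

Three choices here are deliberately resolved design points rather than
consequences of the formulas:

* **Where $\alpha$ attaches.** Whether the positional scale multiplies
  the scaled or the unscaled dot product is not determined by the
  defining equations; we multiply the *scaled* product (keeping
  $\alpha$ dimensionless) and expose `scale_alpha = FALSE` for the
  alternative reading.
* **What `Prev` carries.** The residual score matrix excludes the
  masking penalty and is re-masked at every layer; letting $-\infty$
  penalties accumulate across eight blocks would freeze padded columns
  into every layer's softmax input. Heads are aligned by index across
  blocks.
* **Post-norm, ReLU, $4d$ feed-forward.** The block skeleton follows
  the original Transformer defaults wherever the architecture is
  otherwise unspecified.

### Localization-specific attention head

After the last block, each compartment $j$ owns an attention
distribution over positions,
$\boldsymbol\alpha_j = \mathrm{softmax}(V w_\alpha^j + b_\alpha^j)$
(masked positions excluded), pools the representation as
$c_j = \boldsymbol\alpha_j^\top V$, and the *shared* output projection
yields $\hat s_j = \sigma(c_j w_s + b_s)$. Sharing $w_s, b_s$ across
labels follows the output formula as written; a per-label projection is
available behind `per_label_output = TRUE`. Binary calls use the strict
rule $\hat y_j = 1 \iff \hat s_j > 0.5$. Two ablations are config
flags: `use_localization_attention = FALSE` replaces the head with
masked mean-pooling plus a dense layer (per-label attention is then
*unavailable*, and the interpretation API says so loudly), and
`use_positional_encoding = FALSE` removes the $\alpha/\beta$ terms.
For single-compartment corpora, `output_mode = "softmax"` turns the four
sigmoids into a softmax with categorical cross-entropy.

### Training

The loss is binary cross-entropy averaged over all sample x label
entries (probabilities clipped at $10^{-7}$) — the only reading of
"cross-entropy" consistent with a sigmoid multi-label head. Adam with a
peak learning rate of 3e-4, linear warm-up over the first 4 epochs and
linear decay to zero afterwards, batch size 64, dropout 0.2 on the
embedded rows and 0.1 elsewhere. Epoch budget and stopping are not
pinned by the architecture; the package defaults to 100 epochs with
early stopping on validation micro-F1 (patience 10) over an 80/20
train/validation split. All randomness — initialization, the split,
per-epoch shuffling, dropout — derives from one master seed, and
training is single-threaded, so runs are bitwise reproducible. The
entire network, including backpropagation through the residual score
chain (block $t$'s scores receive gradient from every later block),
the layer norms, the label-wise attention head, and the embedding
scatter, is implemented in base R and verified against central finite
differences and naive nested-loop oracles in the test suite.

## The synthetic benchmark

Curated localization corpora are small, noisy, and externally hosted;
the package instead ships a generator whose ground truth is known by
construction. Each synthetic transcript draws a length uniformly from
300–3000 nt, an i.i.d. uniform background, and an active-label set from
independent marginals (0.60, 0.50, 0.20, 0.15 for nucleus, cytoplasm,
chromatin, insoluble cytoplasm; redrawn until at least one label is
active, matching the training invariant that every sample has a
compartment). Each active label plants three non-overlapping copies of
its motif at uniform positions: AGCCC (nucleus) and RCCTCCC (cytoplasm)
are literature localization elements, while TGGAAT (chromatin) and
CACGTG (insoluble cytoplasm) are arbitrary, mutually non-matching
fixture 6-mers — the generator documents them as fixtures, not biology.
Planted coordinates are recorded per record and label, so attention
profiles can be scored against exact motif positions.

What the generator emulates: label-specific recurring sequence
determinants, multi-label structure, length heterogeneity, background
occurrences of the same motifs (a 5-mer appears by chance about
$L/4^5$ times in uniform sequence, so the nucleus signal is genuinely
noisy at the long end). What it does not emulate: realistic nucleotide
composition, transcript structure, splicing, secondary structure, or
correlated labels (an optional co-occurrence knob exists but defaults
off). Passing the end-to-end tests therefore demonstrates that the
architecture can discover planted sequence determinants and surface
them through label-wise attention — not that it reaches any particular
accuracy on curated corpora.

## Attention-threshold interpretation

For a sequence with $n_{\mathrm{eff}}$ real positions, a position is
flagged for compartment $j$ when its attention weight strictly exceeds
$1/n_{\mathrm{eff}}$ — the expectation of a uniform distribution over
the real positions, so uniform attention flags nothing. "Input length"
is deliberately read as the number of *attention positions*, not
nucleotides: the weights are a softmax over positions, so only
$1/n_{\mathrm{eff}}$ equals their expectation. Flagged positions map
back to nucleotide intervals through the bin layout; touching intervals
merge (gap tolerance 0 by default); regions are scanned for IUPAC
motifs (R = A/G etc.; an `N` in the sequence matches only an `N` in the
pattern) and exported as MEME-ready FASTA with a sidecar recording the
conventional width-9 / E-value 0.05 analysis settings. The package does
not run MEME, render logos, or define a quantitative motif-similarity
score; none is defined for this procedure.

## Scaled-down study configuration

The full-scale model (8 blocks, hidden 128, 512 positions) exists for
real corpora. All shipped end-to-end experiments use a scaled-down
configuration chosen once as the package's reference setup: 2 blocks,
4 heads of width 16, hidden 32, feed-forward 128, 64 positions, k = 5,
trained with peak learning rate 3e-3, batch 32, at most 120 epochs
(patience 25 on validation micro-F1) on 500 generated sequences with a
100-sequence held-out test set, and an overfit-sanity run (32
sequences, dropout off, peak 3e-3, batch 8, 200 epochs). k = 5 is the
length of the shortest planted motif, so every motif determines at
least one full k-mer; the raised peak learning rate compensates for the
short schedule of a small model. These sizes keep a full train /
evaluate / interpret cycle within a desktop-R footprint while leaving
the architecture's every component exercised.

## Numerical conventions

* Coordinates are 0-based, half-open everywhere.
* Layer-norm uses population variance with $\varepsilon = 10^{-5}$;
  softmaxes subtract the row maximum before exponentiation.
* Ties in precision-at-k and multi-class argmax break toward the lowest
  label index.
* Undefined quantities (no predicted labels anywhere; single-class AUC
  columns) are reported as `NA` and excluded from averages; a harmonic
  mean with a zero numerator is 0 by convention.
* Per-label AUC is the Mann–Whitney statistic with midranks for ties.
* Uneven bin division puts the longer bins first; every bin holds at
  least one k-mer, so bin means are always defined.
* K-mers absent from the training corpus receive small seeded Gaussian
  fallback vectors; the null (`N`) vector is frozen at zero through
  training.

## Limitations

The implementation is CPU-oriented base R: practical for the scaled
configuration and for inference, slow for full-scale training on
thousands of sequences. The synthetic benchmark certifies mechanism,
not biological accuracy; on real corpora the labels, redundancy
filtering, and class imbalance dominate difficulty in ways the
generator deliberately does not model. The attention threshold flags
positions, not nucleotides: a flagged bin may span tens of nucleotides
at long input lengths, so motif hits are localized only to bin
resolution before the IUPAC scan narrows them.
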