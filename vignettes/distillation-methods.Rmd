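---
title: "Multi-teacher distillation for protein embedding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-teacher distillation for protein embedding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Protein language models map amino-acid sequences to per-residue vector
representations that feed essentially every modern protein annotation
pipeline — subcellular localization, gene-ontology prediction, stability
regression, interaction prediction. The best such models are very large
(hundreds of millions to billions of parameters), which makes embedding a
large sequence collection expensive. Knowledge distillation addresses this
by training a small *student* encoder to reproduce the outputs of one or
more fixed, pre-trained *teacher* models. Because different teachers excel
on different proteins, a *multi-teacher* scheme with a learned per-instance
teacher selector can outperform any fixed choice of teacher.

`protdistill` implements this training scheme end to end at desk scale: the
student encoder, the joint masked-language-modeling + distillation
objective, the offline teacher store, the adaptive selection policy, and
the embed-and-fine-tune downstream pipeline — plus a synthetic-data module
that stands in for both the pre-training corpus and the teachers, so the
whole framework is testable on one CPU with no downloads.

## The student encoder

The student is an encoder-only transformer in the T5 style:

* pre-norm blocks with RMSNorm (`x / sqrt(mean(x^2) + 1e-6) * g`) and no
  bias vectors anywhere;
* multi-head self-attention with a learned relative-position bias table
  shared across layers: the score between positions `i` and `j` receives a
  per-head bias indexed by `clip(j - i, -w, w)` with window `w = 8`;
* a position-wise ReLU feed-forward block;
* input and output embeddings tied, so per-position vocabulary
  distributions are `softmax(h_i %*% t(E))`.

The vocabulary has 23 symbols: the 20 canonical amino acids in alphabetical
one-letter order, an unknown symbol (ambiguity codes B, J, O, U, X, Z map
here), a mask symbol, and a pad symbol. Sequences are truncated to their
first 1000 residues, the convention used by protein embedding models to
bound memory; the pre-truncation length is kept as metadata. The reference
depth is six layers — the depth reported as most cost-effective for a
T5-style student — while test-scale configurations use two layers and a
hidden size of 32, which train in minutes on one CPU. The relative-bias
choice follows from the one architectural trait that distinguishes T5-style
encoders; an encoder-only stack suffices because the model is used for
embeddings and masked prediction, never for generation.

Forward and backward passes are written directly in base R matrix algebra
(the linear algebra itself runs in BLAS). The backward pass is verified
against central finite differences in the test suite at a relative
tolerance of 1e-4.

## The objective

Pre-training corrupts each batch by masking: every non-special position is
selected independently with probability 0.15 and replaced by the mask token
(the minimal faithful reading of a mask-and-predict objective; the
BERT-style 80/10/10 variant and a span-corruption scheme with geometric
mean span length 3 are available behind options). Two losses are computed:

* **Masked-LM loss** `L_MLM`: the negative log-likelihood of the original
  residues under the student's output distributions, averaged over the
  masked positions.
* **Distillation loss** `L_Distill`: the Kullback–Leibler divergence
  `KL(p_T || p_S)` between the teacher's and the student's per-position
  output distributions, averaged over all positions, with the `0·ln 0 = 0`
  convention. The direction is teacher-to-student, penalizing the student
  wherever it fails to cover teacher mass.

The combined objective is `L = alpha * L_MLM + (1 - alpha) * L_Distill`
with `alpha = 0.2` by default — the mixing weight reported to work best,
giving the softened teacher signal the larger share. Both terms are
*means* over their scored positions rather than raw sums: unreduced sums
would make the balance set by `alpha` drift with sequence length and batch
size. The masked-LM term scores masked positions only (standard MLM); the
distillation term scores all positions, which is what makes offline
distillation informative — the teacher ran on the *clean* sequence, so at
masked positions its distribution leaks the identity of the hidden residue.

The prose description of distillation sometimes refers to comparing
embedded vectors rather than output distributions. The package implements
the distribution-space KL as the default and also provides an
embedding-space mean-squared-error alternative (student hidden states
through a learned linear projection against stored teacher embeddings),
selectable via `loss_config(distill_space = "embedding")`.

No distillation temperature is used (fixed at 1).

## Offline teachers

Teachers never run during training. A `teacher_store` is a directory
container with a JSON manifest (teacher ids, vocabulary, precision) and one
validated record per `(teacher, sequence)` key holding the `N x V`
row-stochastic output matrix and, optionally, an `N x d_T` embedding
matrix. Records are written once and read many times; a preflight check
before training guarantees no mid-run misses.

Synthetic teachers make the framework testable without any pre-trained
model:

* `oracle` / `noisy_oracle`: probability `q` on the true token, remainder
  uniform — teachers of controllable quality;
* `uniform`: completely uninformative;
* `motif`: oracle-like only inside occurrences of its declared motifs —
  a teacher knowledgeable about part of sequence space, used to study
  complementary multi-teacher settings.

## Adaptive teacher selection

Each teacher `k` owns a logistic unit over an instance feature vector:
`s_k = logistic(w_k' f_k + b_k)`. Features combine the three ingredient
families the selector conditions on: the pooled student representation
(mean hidden state), summaries of the teacher's predictions (mean entropy,
mean maximum probability), and the teacher's current distillation loss on
the instance — both raw and relative to the mean over teachers, the
relative form being the cleanest instance-level routing signal when
teachers are knowledgeable about complementary parts of sequence space. The raw weights are normalized to a categorical distribution
— the minimal construction that turns independent logistic outputs into a
valid sampling distribution — and one teacher is sampled per instance
("hard" selection; a `mixture` mode that averages distillation losses under
the current weights exists behind a flag). During training, sampling
probabilities are floored at 0.02 so no teacher is starved before the
policy has evidence.

The policy is trained by REINFORCE. The reward is the improvement in the
instance's combined loss across the optimizer step (loss before minus loss
after), which directly operationalizes "select the teacher that most
improves the student". A teacher-independent alternative — the decrease of
masked-LM loss on a fixed validation batch — is implemented as
`reward = "validation"`; in desk-scale experiments it carries almost no
per-teacher signal early in training, because near-uniform prediction is
itself near-optimal at masked background positions, so even an
uninformative teacher's gradient steps look rewarding. The instance reward
shows a clear differential and is the default.

Two stabilizers, both standard policy-gradient practice, matter at this
scale:

* **Advantage normalization.** Rewards are centered by an exponential
  moving-average baseline (decay 0.9) and scaled by a running estimate of
  advantage magnitude, making update sizes invariant to the numerical
  scale of the reward (which is otherwise ~1e-3 and would leave the
  logistic parameters frozen).
* **Scheduled policy learning rate.** The policy learning rate follows the
  same warm-up/decay shape as the optimizer. Late in training per-step
  rewards vanish for every teacher; without decay, the normalized noise
  makes the selector random-walk between extremes.
* **Batch-averaged updates.** All instances of a batch share one parameter
  update, so their per-instance REINFORCE contributions are averaged
  (scaled by `1/batch_size`), keeping the per-step policy movement
  independent of batch size. Without this, large batches multiply the
  update count and a rich-get-richer dynamic can collapse the selector
  onto one teacher before the routing features are learned.

The default policy learning rate (0.03) is chosen so that, with duplicated
identical teachers, the selector stays near uniform over a training run
(no spurious symmetry breaking) while still committing to a clearly better
teacher within a few hundred steps.

## Optimization schedule

AdamW (betas 0.9/0.999, decoupled weight decay 0.01 — ecosystem defaults,
as only the optimizer name and learning rate are prescribed) at a base
learning rate of 3e-4, ten epochs, batch size 16, with linear warm-up over
the first 10% of steps. The schedule after warm-up is not prescribed;
linear decay to zero is used as the most common companion of linear
warm-up. Batches are processed one sequence at a time with gradients
accumulated and averaged — mathematically identical to padded batching for
per-position mean losses, and pad positions can never contaminate a loss.
Training is full precision and single-threaded, so identical seeds give
bitwise-identical checkpoints; checkpoints carry the optimizer, policy and
RNG state, and resuming a run reproduces the straight-through result
exactly.

Degenerate cases: a sequence drawing zero masked positions contributes no
masked-LM term for that instance (the distillation term still trains it);
a non-finite loss or parameter aborts the run with an error rather than
continuing silently.

## Downstream pipeline

Per-protein embeddings are the global average pool (mean over positions)
of the final hidden states on clean sequences. A two-layer perceptron head
(one ReLU hidden layer, width 256 by default) is trained on frozen
embeddings with full-batch AdamW until the training loss plateaus
(relative improvement below 1e-5 for 25 epochs) or 500 epochs. Inputs are
standardized with training-set statistics. Losses per task family: softmax
cross-entropy (binary, multiclass), independent per-label binary
cross-entropy (multilabel — the only consistent multilabel reading of
"cross-entropy"), mean squared error (regression). Metrics, configurable
but defaulting to field standards for these benchmark families: accuracy,
micro-averaged F1, Spearman correlation. Evaluation uses 10-fold
cross-validation with seeded shuffling, fold sizes differing by at most
one, and an assertion on every run that no held-out id reaches its fold's
training set.

## The synthetic-data module

The generator emulates the *shape* of the real setting — variable-length
sequences over the 20-letter alphabet, class-defining motifs, teachers of
controllably different quality — not its biology. Defaults, chosen once
and used by the test suite:

* 200 sequences, lengths uniform on 60–100, i.i.d. background (uniform by
  default; a frequency-table option provides skewed, compressible
  backgrounds for studying the masked-LM term in isolation, since a
  uniform background is incompressible and leaves masked positions
  unpredictable by construction);
* two classes, each defined by a length-8 motif planted with probability 1
  at a random position (motifs overwrite a background window and never
  overlap one another, so lengths stay as drawn);
* the default motifs `DKLIVEQR` and `ILDKWFYH` share half of their residue
  composition in different order. This places the task where the framework
  is actually informative: a bag-of-residues shortcut separates the
  classes only weakly (real benchmark classes differ partly, not only, in
  composition), an exact-motif detector separates them fully, and a
  bag-of-3-mers logistic baseline confirms solvability before any
  embedding model is judged. Fully distinct motifs make the task solvable
  by raw composition; fully composition-matched (anagram) motifs make it
  *unsolvable for any mean-pooled encoder*, because pooling sums
  near-identical per-token contributions over the motif window — an
  instructive degenerate corner, available by configuration, but wrong as
  a default benchmark;
* regression targets are planted-motif counts plus Gaussian noise
  (sd 0.1) — the simplest controllable noise model; multilabel labels are
  exact planted-presence indicators.

What passing tests on this corpus do **not** show: performance on real
proteins. The synthetic teachers are far simpler than real protein
language models (their outputs depend only on the true token and motif
membership), the background has no homology, domain structure, or natural
length distribution, and the motif signal is exact rather than
degenerate. The tests establish that the machinery — losses, gradients,
selection, schedules, pooling, cross-validation — does what it claims
under conditions where the right answer is known by construction.

## Numerical choices

* Softmax rows subtract the row maximum before exponentiation; RMSNorm
  uses epsilon 1e-6; ties in argmax resolve to the first index.
* Weight matrices initialize i.i.d. Normal(0, 0.02²); norm gains at 1;
  relative biases at 0.
* `KL` returns `+Inf` (flagged, not an error) if the student assigns zero
  mass where the teacher has mass — unreachable through softmax outputs
  but honored for hand-built inputs.
* The span-corruption start rate is `-log(1 - rate) / mean_len`, so the
  stationary *union* coverage of overlapping spans equals the target
  masking rate.
* Test-scale studies in the suite use corpora of 100–240 sequences,
  lengths 30–100, students with 2 layers and hidden size 32 (about 23k
  parameters), and at most 2000 optimizer steps; these sizes are the
  package's desk-scale reference conditions.

## Known limitations

* No GPU path, no mixed precision, no attention optimizations: the encoder
  is written for correctness and small-scale determinism, not throughput.
* The REINFORCE selector is a concrete instantiation (logistic weights,
  EMA baseline, instance reward); the literature it abstracts offers
  richer schedulers, and no regret guarantees are claimed.
* Adapters that wrap real pre-trained protein models to fill a teacher
  store are out of scope here; the store format is the integration point.
* The default six-layer configuration is a reference architecture; no
  claim is made that it reproduces any released model's parameter count or
  weights.
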