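# protdistill

Multi-teacher knowledge distillation for protein sequence embedding, as a
self-contained, desk-scale R package.

## The problem

Protein language models turn amino-acid sequences into numerical vectors
that drive most modern protein annotation tasks — subcellular localization,
gene-ontology prediction, stability regression. The strongest models have
hundreds of millions of parameters and are expensive to run over large
sequence collections. Knowledge distillation trains a small **student**
encoder to mimic one or more fixed, pre-trained **teacher** models; because
different teachers excel on different proteins, a **multi-teacher** scheme
with a learned per-instance teacher selector can outperform any single
fixed teacher.

`protdistill` implements that training framework end to end for people who
want to study, test, or extend it without GPUs or external model weights:

* a T5-style encoder-only student (RMSNorm pre-norm blocks, learned
  relative-position biases, tied embeddings) with hand-verified
  backpropagation in base R;
* the joint objective
  `L = α · L_MLM + (1 − α) · L_Distill`, where `L_MLM` is the
  masked-language-modeling loss (masking probability 0.15) and `L_Distill`
  is the per-position Kullback–Leibler divergence `KL(p_T ‖ p_S)` between
  teacher and student output distributions, with `α = 0.2` by default;
* an **offline teacher store**: teachers run once, their per-position
  outputs are persisted, and training never invokes them again;
* **adaptive teacher selection**: per-teacher logistic weights over
  instance features (pooled representation, teacher prediction summaries,
  per-teacher losses), normalized, sampled, and trained by REINFORCE with
  a moving-average baseline;
* AdamW with linear warm-up (ratio 0.1) and decay, batch size 16, base
  learning rate 3e-4, ten epochs — with bitwise-reproducible runs and
  resumable checkpoints;
* a downstream pipeline: global-average-pooled per-protein embeddings, a
  two-layer MLP head, and 10-fold cross-validation for binary, multiclass,
  multi-label, and regression tasks;
* a synthetic-data module (planted-motif corpora and synthetic teachers of
  controllable quality) that makes every component testable offline.

## A worked example

Distill a tiny two-layer student from two complementary synthetic teachers
— each knowledgeable only about one class's sequence motif — then classify
the held-out motif classes from mean-pooled embeddings:

```r
library(protdistill)

# 1. a small planted-motif corpus (two classes, default motifs)
spec <- synthetic_spec(n_sequences = 80, length_range = c(40L, 70L), seed = 7)
corpus <- generate_corpus(spec)
tokens <- tokenize_sequences(corpus$records)

# 2. an offline store with two complementary synthetic teachers
store <- build_test_store(tokens, list(
  teacher_A = list(kind = "motif", params = list(q = 0.9, motifs = "DKLIVEQR")),
  teacher_B = list(kind = "motif", params = list(q = 0.9, motifs = "ILDKWFYH"))),
  file.path(tempdir(), "teacher-store"))

# 3. multi-teacher distillation pre-training of a tiny student
model <- pretrain(
  tokens, store,
  student = student_config(num_layers = 2, hidden_dim = 32,
                           num_heads = 4, feedforward_dim = 64),
  config = pretrain_config(epochs = 25, batch_size = 16, base_lr = 1e-3,
                           seed = 1))
model
#> <mtdp_model> 17348 parameters, 25 epochs, 125 steps
#>   teachers: teacher_A, teacher_B
#>   final losses: mlm 3.0434  distill 0.1268  total 0.7101

# 4. per-protein embeddings and 5-fold cross-validated classification
emb <- embed_sequences(model, tokens)
cv <- cross_validate(emb, corpus$labels, "binary", k = 5, seed = 1,
                     hidden = 64, max_epochs = 300)
glance(cv)
#> # A tibble: 1 × 6
#>   metric       k  mean    sd   min   max
#>   <chr>    <int> <dbl> <dbl> <dbl> <dbl>
#> 1 accuracy     5 0.812 0.117 0.688 0.938
```

Reading the output: the student has ~17k parameters; after 125 optimizer
steps its mean per-position KL to the sampled teachers has fallen to 0.13
nats, while the masked-LM term sits near the entropy of the uniform
background (~3 nats — random backgrounds are incompressible, so the
distillation term carries the learnable signal here). The pooled
embeddings of even this very short demo run already separate the two motif
classes well above the 0.5 chance level; the test suite's full-length runs
reach ≥ 0.9 mean cross-validated accuracy. `autoplot(model)` draws the
loss curves, `autoplot(cv)` the cross-validation box plot, and
`tidy()`/`glance()` return the underlying tibbles.

The same pipeline is available from a shell:

```sh
inst/cli/protdistill simulate --spec spec.yaml --out sim/ --seed 4
inst/cli/protdistill pretrain --fasta sim/corpus.fasta --store sim/store \
    --config train.yaml --out run/ --seed 4
inst/cli/protdistill embed --fasta sim/corpus.fasta \
    --checkpoint run/checkpoint.rds --out emb.tsv
inst/cli/protdistill evaluate --embeddings emb.tsv --labels sim/labels.tsv \
    --task binary --k 10 --out metrics.tsv
```

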