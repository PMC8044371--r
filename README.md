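# methylMT

Multi-task prediction of DNA modification sites (4mC and 6mA) across
species with a shared bidirectional-GRU encoder.

## What this is for

DNA N4-methylcytosine (4mC) and N6-methyladenine (6mA) are epigenetic
marks mapped experimentally as short labeled sequence windows, one
benchmark per species and modification type. Species differ wildly in how
much labeled data exists, and single-species classifiers generalize
poorly. `methylMT` is for researchers who want to train one model over
several species at once: a shared encoder learns sequence features common
to all tasks, and small per-species heads specialize them, so data-poor
species borrow strength from data-rich ones (hard parameter sharing).

The model: windows are split into overlapping n-gram words (default
dinucleotides) and embedded; two GRUs read the embedded sequence in
opposite directions with the recurrence

    r_t = sigmoid(W_r x_t + U_r h_{t-1})
    z_t = sigmoid(W_z x_t + U_z h_{t-1})
    h'_t = tanh(W x_t + r_t ⊙ U h_{t-1})
    h_t = z_t ⊙ h_{t-1} + (1 − z_t) ⊙ h'_t

(the update gate multiplies the previous state); per-position states are
concatenated and max-pooled over time into one vector y of length 2H;
per-task fully connected stacks (affine → batch-norm → ReLU, then softmax)
turn y into a site probability. Training interleaves tasks stochastically
and minimizes the weighted binary cross-entropy sum over tasks with Adam.
Evaluation reports SN, SP, ACC, MCC and rank-based AUC per task. A
synthetic motif-benchmark generator makes every stage — and the
multi-task-vs-single-task ablation — testable without any downloads.

## Worked example

```r
library(methylMT)

# 2 species-like tasks, balanced classes: positives carry a shared motif
# (90% of the time) and a task motif (50%), mutated at 5% per position
spec <- synthetic_spec(n_tasks = 2, n_train = 100, n_test = 50, seed = 1)
ds <- generate_dataset(spec)
ds$registry
#> Multi-task registry: 2 task(s)
#>   task1                    train   200 (100+/100-)  test   100 (50+/50-)
#>   task2                    train   200 (100+/100-)  test   100 (50+/50-)

res <- fit(ds$registry, training_config(steps = 400, seed = 1), hidden_dim = 32)
ev <- evaluate_model(res$model, ds$registry, split = "test")
ev[, c("task", "SN", "SP", "ACC", "MCC", "AUC")]
#>    task   SN   SP  ACC       MCC    AUC
#> 1 task1 0.78 0.94 0.86 0.7293968 0.9164
#> 2 task2 0.72 0.88 0.80 0.6078307 0.8792
```

Each row is one task's held-out performance: `SN`/`SP` are the fractions
of true sites and non-sites called correctly at threshold 0.5, `ACC` their
balanced overall rate, `MCC` the chance-corrected correlation between
calls and labels (1 = perfect, 0 = chance), and `AUC` the probability a
random positive outscores a random negative. Values near 0.9 reflect the
generator's deliberately imperfect motif signal — positives lack the
shared motif 10% of the time, so perfect separation is impossible.

Models are checkpointable (`save_checkpoint()` / `load_checkpoint()`,
bit-identical round trip) and single-task baselines for ablation come from
`fit_single_task()`.

### Command line

The same workflows are scriptable via the installed `exec/methylMT`
Rscript: `simulate`, `train`, `predict`, `evaluate` subcommands, e.g.

```sh
Rscript exec/methylMT simulate --tasks 4 --n-train 200 --seed 7 --out data/
Rscript exec/methylMT train --manifest data/manifest.tsv --steps 2000 --seed 7 --out run/
```

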