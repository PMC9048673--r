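---
title: "Methods: simulated sequence grammars as ground truth for model and attribution benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated sequence grammars as ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grammarbench)
```

## The generative model

An example is a triplet $(x, y, a)$: a sequence window $x$ over a
declared alphabet (DNA, RNA, or the 20 amino acids), a condition $y$
(a mutually exclusive class or a set of independent labels), and an
annotation string $a$ of the same length as $x$ whose characters mark
each position as *grammar* (`G`) or *background* (`_`). Background
positions are i.i.d. draws from a categorical background distribution;
for DNA the default is the natural nucleotide composition of the human
genome (A 29.565%, C 20.435%, G 20.435%, T 29.565%), and
condition-specific backgrounds may override the default per condition.

Condition information enters $x$ only through probabilistic rules. A
rule belongs to one condition and, with its firing probability, writes
an ordered list of sequence elements into the window. Elements are
either position weight matrices — independent per-position symbol
distributions, sampled column by column — or k-mer sets, from which
one k-mer is drawn by its probability. Every written position is
flagged `G` in $a$; everything else remains `_`. Because the learner
never sees $a$, the annotation is pure evaluation ground truth.

### Placement semantics

These conventions are this package's own choices where the general
framework leaves them open; they are stated here because tests depend
on them.

* Coordinates are 0-based with half-open `[start, end)` intervals in
  the `placements` table.
* A rule's position spec is `center` (start $\lfloor (L - w)/2
  \rfloor$ for span $w$ in window $L$), a 0-based fixed index, or
  `random` (uniform over feasible starts).
* Elements joined by spacing constraints form a chain; each
  constrained gap is drawn uniformly from $[\text{min\_gap},
  \text{max\_gap}]$. `order_fixed = TRUE` pins the pair's order;
  otherwise it is flipped with probability 1/2 per example.
* A rule with several elements, no constraints and `random` position
  places each element independently and uniformly (used by the
  "combination of PWMs" archetype); with `center`/fixed position the
  elements form a gap-0 chain.
* Placements never overlap previously placed grammar positions.
  Placement is rejection-sampled up to 1000 times, then errors — an
  overlap would corrupt the annotation semantics.
* Rule probabilities below 1 deliberately produce examples that carry
  a condition's label without its sequence signal, emulating the label
  noise of functional-genomics assays. For multilabel tasks every
  condition's rules fire independently and $y$ is the set of
  conditions that fired.
* Adjacent elements at gap 0 merge their `G` runs in $a$; the
  conservation invariant (number of `G` positions = total placed
  element width) always holds, and exact per-element intervals are
  available from the `placements` table.
* Variable window lengths are drawn uniformly from the declared
  (min, max) range.
* Duplicate sequences across subsets are possible (sampling is
  independent); they are documented, not deduplicated.

Datasets are pure functions of the data definition, including its
seed; the simulation RNG stream is separate from the training stream,
so changing the model never changes the data.

## The model harness

No deep-learning framework for R is assumed: the harness implements
its layer vocabulary (1D valid convolution via im2col, dense, max
pool, global max pool, batch normalization, dropout, ReLU, and
residual skip blocks) with exact reverse-mode gradients in base R,
verified against central finite differences at relative tolerance
1e-4. Sequences are one-hot encoded to a (batch, length, alphabet)
array; variable-length batches are right-padded with all-zero channel
vectors, which receive zero attribution by construction.

Defaults (all overridable in the model definition): Adam with
learning rate 1e-3, batch size 64, early stopping on validation loss
with patience 10 and best-weights restoration. Multiclass models end
in a softmax with categorical cross-entropy; multilabel models in
element-wise sigmoids with binary cross-entropy.

**Initialization.** Hidden convolutional and dense layers use
He-scaled Gaussian weights with a small positive bias (0.1); the
output layer is initialized to exactly zero (weights and bias). The
zero head is load-bearing: architectures that flatten a wide
all-positive ReLU activation map into a narrow dense bottleneck (e.g.
1300 inputs into 5 units) otherwise die irrecoverably in a
substantial fraction of seeds, because Adam's early near-sign updates
move whole weight rows coherently and can push every bottleneck unit
negative for every input. With a zero head, hidden layers receive
gradient only after the output layer has learned informative
directions, which removed the collapse in all tested seeds without
changing converged behavior.

Training reads only $(x, y)$ — the interface does not expose $a$ to
the learner — and fixed (data seed, model seed) pairs reproduce the
training trajectory exactly on a single-threaded BLAS.

## Feature importance evaluators

All FIEs return a length-$n$ vector for a length-$n$ example:
feature-level $n \times |\mathcal{A}|$ values are collapsed per
position. The default collapse is the signed sum over channels;
saliency uses the sum of absolute values; both are switchable
(`collapse = "sum" | "abs_sum" | "max"`). For one-hot inputs the
signed sum of an input-multiplied attribution equals the observed
symbol's value, which is why it is the default.

* **Raw gradient** $\nabla f_y(x)$, **saliency** $|\nabla f_y(x)|$,
  **gradient×input** $x \odot \nabla f_y(x)$. $f_y$ is the activated
  output (probability) by default; `on = "logit"` differentiates the
  pre-activation instead.
* **Integrated gradients** with the zero vector as baseline and a
  right-endpoint Riemann sum over $k/K$, $k = 1..K$ (default $K =
  100$). The default multiplies the averaged gradient by the input,
  the form that satisfies completeness ($\sum_i z_i \approx f_y(x) -
  f_y(0)$, exact for linear models); the bare mean-gradient variant is
  available via `multiply_by_input = FALSE`. Both are provided because
  the two forms circulate in the literature and differ for nonlinear
  models.
* **Modified backpropagation** replaces the ReLU backward rule only:
  guided backpropagation passes gradient where forward activation and
  incoming signal are both positive; deconvolution where the incoming
  signal is positive; DeepLIFT uses the rescale rule with
  zero-baseline reference activations and returns multiplier × input.
  DeepLIFT's summation-to-delta identity is exact through
  conv/ReLU/dense stacks and a sigmoid head (the rescale rule is also
  applied to the output sigmoid); max-pooling layers and the softmax
  head are handled gradient-style, which voids the identity — the
  tests therefore check completeness only on pooling-free sigmoid
  networks. RevealCancel and non-ReLU nonlinearities are out of scope.
* **Sufficient input subsets** (SIS), model-agnostic: repeatedly (i)
  backward-select — greedily mask the position whose removal decreases
  $f_y$ least until $f_y \le \tau$ — then (ii) re-grow the minimal
  retained set from the most recently masked positions until $f_y >
  \tau$; that set is one SIS, removed from the available pool before
  the next round. Masked positions carry the all-zero vector,
  consistent with the integrated-gradients baseline. Default $\tau =
  0.5$ suits sigmoid/binary outputs; multiclass users should set
  $\tau$ explicitly. Every returned subset is disjoint from the others
  and verified sufficient by direct re-evaluation.

## Grammar recovery and test-set metrics

The per-example grammar-agreement (vocabulary-recovery) score is the
absolute-attribution mass fraction on grammar positions, 0/0 defined
as 0; for SIS it is the precision of the union of masks against `G`
positions. This mass-fraction statistic is **this package's
definition** — the quantity is shown but not printed as a formula in
the literature this design follows — and it has the properties the
tests rely on: it is 1/0 for attribution concentrated on/off grammar
positions and invariant under positive rescaling.

ROC AUC uses the trapezoidal rule; PR AUC uses step-wise
(average-precision) summation, avoiding the optimism of linear PR
interpolation; a constant classifier's PR AUC equals the prevalence.
Micro-averaging pools all (class, example) score–target pairs before
thresholding; macro ("per-class") averages per-class AUCs. Agreement
plots normalize $|z|$ per example to $[0, 1]$ (luminosity; constant
rows map to 0) and order examples by descending agreement.

Dataset-size sweeps iterate grammars × architectures × training sizes
× simulation seeds, record micro ROC/PR AUC (and optionally mean IG
agreement), continue past individual cell failures, and resume from
their output file.

## What the synthetic world does and does not establish

The generator reproduces the features that matter for benchmarking
interpretability — known informative positions, controllable grammar
complexity (the six archetypes), class-dependent backgrounds, label
noise via rule probabilities, spacing/order interactions — but not
read-level sequencing error, assay bias, or chromatin context. A green
test therefore certifies that an architecture/FIE pair can recover a
stated rule family under clean conditions; it does not certify
performance on experimental data, where both noise and rule mismatch
intervene. Fixture PWMs are information-content-targeted random
motifs (columns tempered in log space to a target IC, bisection to
within 1e-3 bits) and make no claim of biological fidelity.

## Numerical choices and degenerate inputs

* Probability-vector validation tolerance 1e-9; imported motif rows
  are renormalized only when off by ≤ 1e-3, larger deviations error.
* Cross-entropy clamps probabilities at 1e-12; training aborts with an
  error on non-finite loss.
* The DeepLIFT rescale denominator falls back to the plain gradient
  rule when $|\Delta|$ < 1e-7.
* Ties in global max pooling resolve to the first position; SIS
  greedy steps break ties by first index — both make attribution
  deterministic.
* Zero-length backgrounds, empty batches, zero training epochs and
  below-threshold SIS calls return well-defined empty results rather
  than erroring.
* Batch normalization uses momentum 0.99 and $\epsilon$ = 1e-5, with
  running statistics in inference mode (so attribution is
  deterministic and batch-independent).

## Known limitations

* One backend; the build/train/predict/gradient interface is kept
  thin so a second backend could be swapped in.
* DeepLIFT completeness is not preserved through max-pooling or
  softmax (see above); guided backprop and deconvolution are defined
  by their backward rules only, as usual.
* SIS is $O(n^2)$ model evaluations per subset; it is batched but
  intended for windows of a few hundred positions, not thousands.
* The spacing between unconstrained chain neighbors is 0; expressing
  "anywhere apart" requires either independent placement (no
  constraints, random position) or a wide explicit gap range.
* No architecture search, no pretrained weights, no automatic grammar
  inference from experimental data: definitions are inputs.
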