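---
title: "Latent generative modelling of protein families with tvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent generative modelling of protein families with tvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Homologous protein families carry, in their alignment statistics, the
co-evolutionary constraints that keep their members folded and functional.
`tvae` learns those statistics with a variational autoencoder (VAE) whose
encoder is a temporal convolutional network (TCN), regresses a measured
fitness — the motivating application is T50 thermostability of cytochrome
P450 chimeras, the temperature at which half the protein irreversibly
inactivates — on the learned latent space with a Gaussian process (GP), and
then proposes new variants by sampling the latent neighbourhood of the best
known sequence, decoding, and keeping candidates whose predicted fitness
falls in a desired window just above the natural maximum.

## Model

### Encoder

An aligned sequence is one-hot encoded as a 21 x L binary matrix (gap plus
the 20 amino acids in alphabetical one-letter order; each alignment column
sums to one). The alignment-column axis is treated as the temporal axis of a
stack of dilated causal convolutional residual blocks: the output at column
t depends only on columns <= t, and tap i of a kernel of size k with
dilation d reads the input delayed by d(k - i) columns. Each residual block
applies [dilated causal convolution, weight normalisation, ReLU, dropout]
twice, adds the block input through an identity skip (a 1 x 1 convolution
when the channel counts differ), and applies a final ReLU. Per-block
dilations double (1, 2, 4, ...), so the receptive field grows geometrically
with depth:

RF_i = RF_{i-1} + (k_i - 1) * d_i * S_i,  S_i = prod_{j<i} s_j.

A dilation-blind variant of this recursion (`receptive_field()`) is also
exposed; the network itself obeys the dilation-aware form, and the test
suite validates it against a brute-force perturbation probe: the predicted
field equals the widest input span that can influence one output column,
for stacks of 1-4 blocks with dilations 1, 2, 4, 8.

The final block's channels (100 by default) are averaged over alignment
columns (global average pooling — the interface between the convolutional
stack and the dense head is a design choice here; pooling keeps the
parameter count independent of L), passed through one fully connected tanh
layer, and mapped by two linear heads to the mean and log-variance of a
diagonal Gaussian over the latent space (dim 3 by default; 2 for
visualisation).

### Objective and decoder

Training maximises the evidence lower bound

ELBO = E_q[log p(s|z)] - KL(q(z|s) || p(z)),

with a standard-normal prior, the closed-form diagonal-Gaussian KL, one
reparameterised sample of z per evaluation (z = mu + sigma * eps), and a
decoder z -> tanh hidden layer -> linear logits -> per-column softmax over
the 21 symbols, scored by categorical cross-entropy. Per-sequence
position-based weights multiply the whole per-sequence loss (reconstruction
and KL jointly): the weights re-balance the effective data distribution, so
they scale the entire per-datum ELBO rather than only its reconstruction
term. Optimisation is Adam (learning rate 1e-3 by default) with L2 weight
decay 1e-4, the optimum of a sweep over {1e-2, 1e-3, 1e-4, 1e-5}.

The whole network and its gradients are written in vectorised base-R linear
algebra; correctness of every gradient path (convolutions, weight norm,
skip projections, heads) is pinned by a finite-difference check in the test
suite.

### Sequence weighting and cleaning

Cleaning an aligned family drops sequences whose gap fraction exceeds 20%
and removes exact duplicates (first occurrence kept). The gap fraction is
computed on the aligned rows, where gaps are still visible; stripping gaps
first would make the rule vacuous, so `strip_gap_sites()` exists as a
separate, explicitly destructive operation whose output generally needs
external realignment. Position-based weights follow Henikoff & Henikoff
(1994): in a column with r distinct symbols a sequence carrying a symbol of
multiplicity m contributes 1/(rm); sequence weights are column means,
normalised to sum to N. Gaps count as a 21st symbol type.

### Fitness regression

Latent means (not posterior samples) are the GP features. The kernel is RBF,
k(z1, z2) = sig_g^2 exp(-||z1 - z2||^2 / (2 lambda^2)), with a constant mean
fixed at the training mean of y and an observation-noise variance sig_n^2
on top of the noise-free RBF formulation; exact interpolation of noisy T50
measurements is ill-conditioned, so sig_n^2 is fitted alongside the other
two hyperparameters with a floor of 1e-8. Fitting maximises the log marginal
likelihood in log-parameter space with L-BFGS-B from a moment-matched start
(variance of y; median pairwise latent distance) plus five seeded random
restarts — the marginal likelihood is multi-modal. Quality is reported as
Pearson correlation and mean absolute deviation on a seeded, unstratified
hold-out split; with 278 labelled items and test fraction 0.2 the split is
222 train / 56 test.

### Variant generation and screening

Around the encoder posterior of the highest-fitness sequence,
`sample_around()` draws z = mu + scale * sigma * eps; scale 1 reproduces the
posterior, 0 collapses to the mean. Decoded argmax sequences are scored for
global (Needleman-Wunsch) and local (Smith-Waterman) identity against the
reference under match = 1, mismatch = 0, gap open/extend = 0, with ties
broken by preferring matches, then diagonal moves, then the up move — fixed
so identities are bit-reproducible. Identity is 100 * matched pairs /
alignment length; the local denominator is the best local alignment's
length, and an alignment with no matching residue reports 0 by convention.
Because both identity conventions appear in the literature, reports carry
the two side by side. Screening keeps predictions strictly inside
(lower, upper); the canonical window for the cytochrome application is
(69.7, 72) degrees C — above the best natural T50, but close enough to
remain plausible.

## The synthetic generator

`simulate_family()` provides the fully self-contained study system: a Yule
(pure-birth) tree with exponential waiting times, a root sequence uniform
over the 20 amino acids, and per-branch site substitution with probability
1 - exp(-rate * t), the replacement drawn uniformly from the other 19
residues (a Jukes-Cantor-style 20-state chain). Clade labels cut the tree
at a fixed distance from the root, mirroring the grouping-by-evolutionary-
distance construction; for an ultrametric tree `clade_cut_for_groups()`
derives the cut giving an exact clade count from the branching depths.
Optional fitness values are a per-clade effect (drawn once), a linear term
in root depth, and Gaussian noise, on a T50-like scale (baseline 55,
clade SD 5, noise SD 0.5); the noiseless components are recorded for
recovery tests.

What the simulator reproduces: equal-length gap-free homologs whose pairwise
identity decays with patristic distance, clade structure that a faithful
embedding should separate, and a smooth latent-linked fitness with small
measurement noise. What it does not reproduce: indels and alignment errors,
non-uniform amino-acid composition and realistic substitution matrices
(WAG/LG), rate heterogeneity across sites, and database-scale redundancy.
Tests passing on this generator therefore certify the machinery — causality,
bounds, recovery, ranking — not performance on any real family.

## Problem sizes and defaults

Full-scale settings are recorded as defaults where they are
architecture constants (kernel 2, stride 1, dilation base 2, dropout 0.2,
TCN output width 100, 3 blocks, dim_z 3, hidden layer 100, weight decay
1e-4, seed 42, pretrain/fine-tune epochs 20000/8000). The package's own
benchmarks run at desk scale, chosen once: memorisation uses 30 sequences of
L = 40 for 2000 epochs with a 2-block (24/48-channel) encoder; the clade
study uses 300 leaves, L = 60, 4 clades, dim_z 2 and 400 epochs; GP studies
use n = 200-250; the end-to-end demo (and the acceptance script, which
drives it) runs the same 300-leaf family with 600 training epochs and 600
generated variants. These sizes make each benchmark a few minutes of CPU while
leaving the measured properties (>= 95% memorisation identity, positive
clade silhouette beating label permutations, held-out Pearson >= 0.9 on the
smooth landscape, length-scale recovery within a factor 1.5) comfortably
attainable by a correct implementation and clearly diagnostic of a broken
one.

## Numerical choices

- Weight-norm row norms are floored at 1e-12 so zero-initialised filters
  stay differentiable-in-practice.
- Decoder probabilities are floored at 1e-300 inside logs.
- The ELBO <= log p(x) bound is asserted against a 1000-sample importance
  estimate; the ELBO side averages its reconstruction term over 100
  posterior draws, because the one-draw estimator's Monte-Carlo noise
  (fractions of a nat) occasionally exceeds the bound gap even though its
  expectation never does.
- The GP keeps a Cholesky factorisation; predictions in the tests are
  cross-checked against an independent dense `solve()`.
- `train()` aborts with a diagnostic on a non-finite loss rather than
  continuing from a poisoned state.
- All randomness (initialisation, shuffling, dropout, latent draws,
  restarts) flows from explicit integer seeds; two same-seed runs agree
  bitwise on one BLAS thread.

## Known limitations

- Training is CPU-bound R linear algebra: fine at desk scale, not a
  replacement for GPU training of a 57k x 426 family at 20000 epochs.
- The decoder treats alignment columns as conditionally independent given
  z; generated sequences inherit no explicit pairwise covariation beyond
  what the latent bottleneck carries.
- Gap stripping leaves unaligned sequences; realignment is out of scope.
- The GP assumes a stationary RBF landscape over the latent space; strongly
  non-stationary fitness surfaces would need a different kernel.
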