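---
title: "Methods: a machine-learning-directed design loop for thermotolerant Rubisco activase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a machine-learning-directed design loop for thermotolerant Rubisco activase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RcaDesign)
```

## The problem

Rubisco activase (Rca) is the AAA+ chaperone that spends ATP to strip
inhibitory sugar phosphates off Rubisco's catalytic sites. It is famously
heat-labile: a one-hour shock in the low forties (degrees C) is enough to
kill the ATPase activity of the cassava enzyme, which makes Rca a prime
engineering target for keeping photosynthesis running in a warming climate.
`RcaDesign` implements, end to end and fully in software, an iterative
engineering loop for this problem:

1. **Curation** — refine a candidate ortholog set against the cassava
   reference (identity and length filters, chloroplast transit peptide
   stripping, gap-fraction trimming of the alignment).
2. **Modeling** — train a variational autoencoder (VAE) on the one-hot
   encoded alignment; optionally attach a semi-supervised property head
   that predicts each sequence's measured thermal tolerance.
3. **Generation** — sample latent space around the wildtype and decode,
   keeping only variants within a Hamming budget (default 20 substitutions)
   of the wildtype.
4. **Screening analytics** — turn coupled ATPase assay traces (NADH
   oxidation read as A340 decay) into activity calls, a per-sequence
   maximum tolerated shock temperature ("tmax"), residual-activity
   percentages, and per-round tallies.
5. **Loop** — feed the screen results back as labels, retrain, and design
   the next round.

Because the physical loop closes in a laboratory, the package ships a
synthetic study system (the `generateMsa`/`groundTruth`/`simulateTrace`
family) in which the genotype-to-phenotype map is planted and known, so
every stage — and the loop as a whole — is testable against ground truth.

## The synthetic study system

The generator is not a throwaway fixture; it defines the conditions under
which the package's claims are tested, so its defaults are fixed and
documented here.

**Alignment.** `generateMsa()` draws an alignment around a random consensus
with *subfamily structure*: each ortholog belongs to one of `n_clades = 6`
clades; every clade except the wildtype's own carries its own preferred
alternate residue at a fraction (`clade_divergence = 0.6`, scaled by
`1 - conservation`) of the variable columns, and residual column-independent
noise is layered on top. The default conservation profile alternates
strongly conserved columns (consensus probability 0.95) with variable ones
(0.6). Two properties motivated this design. First, real ortholog sets are
not column-independent — subfamily structure is exactly the low-dimensional
signal a VAE's latent space exists to capture, and a column-independent
simulator would leave the model nothing to learn beyond the consensus.
Second, the wildtype's own subfamily sits at the consensus, so the
reference occupies a populated region of sequence space — as a query
sequence inside its own ortholog neighborhood does — and the latent
neighborhood of the wildtype decodes to near-wildtype sequences.

**Planted phenotype.** A `groundTruth()` names a small set of key alignment
columns (default: one, column 25) at which a stabilizing residue (default:
glycine replacing the wildtype proline, echoing the campaign's
single-mutation top performer) adds `delta_tmax = 8` degrees C of tolerance
to the wildtype baseline of `base_tmax = 38` degrees C. Those two values
are the study conditions: the wildtype survives a 38-degree shock and dies
at 42, and one substitution moves tolerance to 46 — inside the
38/42/46/50-degree challenge ladder. Each stabilizing substitution also
multiplies catalytic activity by `activity_scale = 0.7`, planting the
stability–activity trade-off the screening analytics must resolve (the
trade-off magnitude is not reported anywhere we know of; 0.7 keeps the
variant's rate clearly measurable yet clearly below wildtype). Epistasis
between key positions is deliberately out of scope: effects are additive.

**Traces.** `simulateTrace()` models the permissive coupled assay as a
linear A340 decay, `A(t) = max(floor, A0 - r t)`, with `A0 = 1` and
`floor = 0.1` in arbitrary absorbance units (the campaign's absolute
amplitudes are unpublished, so amplitudes are arbitrary-unit by design),
wildtype rate `r = 0.01` AU/min, and Gaussian observation noise
(`trace_noise_sd = 0.01` AU). Heat-shock damage is a step function: full
activity at or below the sequence's true tolerance, none above — matching
the binary active/inactive readout of the screen; graded damage is not
modeled. The linear-then-plateau shape encodes the two facts the assay
design relies on: the initial slope is proportional to ATP hydrolysis rate,
and over a long (~16 h) incubation any residual activity runs the reaction
to completion, which is what makes the endpoint screen permissive.

**What passing tests do and do not show.** The simulator has planted,
additive, single-column genetics, clade-structured variation, and
homoscedastic Gaussian noise. Success here demonstrates that the machinery
is correct — encodings invert, the ELBO is the ELBO, the sampler respects
its constraints, calls and tallies are exact — and that the loop can find a
planted signal. It does not demonstrate that a real ortholog set carries a
learnable tolerance signal, nor calibrate expected effect sizes on real
data.

## The model

The VAE is a multilayer perceptron pair on the flattened one-hot input
(21 symbols per column: 20 amino acids plus the gap, which is a
first-class symbol everywhere so that Hamming distances and encodings are
gap-convention-free). Defaults: encoder widths 256/64, a 4-dimensional
latent (the campaign visualized "two out of four" latent dimensions, which
fixes the dimensionality), decoder mirrored, per-position softmax output.
The training objective is the standard evidence lower bound

$$\mathcal{L} = \mathbb{E}_{q(z|x)}\!\left[\log p(x|z)\right]
  - \beta\, \mathrm{KL}\!\left(q(z|x)\,\|\,\mathcal{N}(0, I)\right),$$

with the KL term in closed form for the diagonal-Gaussian posterior,
$\tfrac12\sum_j (\mu_j^2 + \sigma_j^2 - 1 - \log\sigma_j^2)$, which is
nonnegative term by term. $\beta$ ramps linearly from 0 to `kl_weight`
(default 1) over the first 10% of epochs — a plain warm-up against
posterior collapse. $\beta$ is also the lever that trades reconstruction
sharpness for latent coverage: models intended to *generate* (the
10,000-variant sampling experiments) train at $\beta = 8$ with small
minibatches (size 32), where the posterior matches the prior, gradient
noise keeps the decoder surface rich in decision boundaries, and the
wildtype's neighborhood decodes to tens of thousands of distinct
sequences; models intended to *reconstruct* keep $\beta = 1$ full-batch —
a converged $\beta = 1$ posterior is so sharp ($\sigma \approx 0.13$)
that argmax decoding around it yields only a handful of distinct
variants. Optimization is full-batch Adam (learning rate `1e-3`,
`2e-3` in the examples below; everything about the original architecture
and schedule is unpublished, so these are this package's own choices,
sized to train a ~2,000 x ~300-column alignment in minutes on one CPU).

**Semi-supervision.** With labels attached, a small tanh head (16 hidden
units) reads the latent representation and predicts the measured tmax
(squared error on the standardized target) and the room-temperature
activity flag (cross-entropy), masked to labeled rows only — missing
labels are never imputed. Two regularization choices matter and were made
after observing that an unregularized head memorizes a 150-label training
set through the over-parameterized encoder instead of finding the planted
column: the head is trained on the *sampled* latent $z$ rather than the
posterior mean (posterior noise makes memorized point-placements
unprofitable; inference still reads the mean), and the optimizer applies
decoupled weight decay (`1e-4`) to weight matrices. The property weight
$\lambda$ defaults to 1; the loss structure — ELBO plus
$\lambda$-weighted prediction loss — is the claim, not any particular
weight, and the planted-signal experiments below use $\lambda = 50$, where
the supervised gradient is comparable to the reconstruction gradient for a
120-column alignment.

**Determinism.** One seed drives initialization, minibatch shuffling (when
minibatching; the default is full-batch) and the reparameterization draws.
The property head initializes from an independent stream derived from the
same seed, so a $\lambda = 0$ semi-supervised run reproduces the
unsupervised parameters bit for bit. Log-variances are clamped to
$[-8, 8]$; a non-finite loss aborts with the offending epoch.

## Generation

`proposeVariants()` samples a diagonal Gaussian centered on the wildtype's
posterior mean with standard deviation `sigma_scale` (default 1) times the
posterior standard deviation, decodes by per-position argmax (ties broken
by alphabet order, so one latent point maps to exactly one sequence), and
rejects any decoded sequence beyond the Hamming budget, any duplicate, the
wildtype itself, and anything previously screened. Rejection continues in
batches until the requested count is accepted or 100x that count of draws
has been spent, at which point the sampler reports starvation with its
acceptance rate. Whether the original campaign enforced its 20-substitution
budget by rejection or by sigma tuning is unstated; rejection makes the
constraint a hard guarantee, which is what the package asserts on every
run. `designRound()` oversamples the pool tenfold, ranks by predicted
tmax (ties: fewer mutations, then lexical id — a deterministic order), and
returns the top slice with a provenance label. In campaign experiments the
design rounds sample at `sigma_scale = 3`: a rare beneficial determinant
can sit several posterior standard deviations from the wildtype in a
supervised latent space, and the wide pool plus ranking — not the sampling
radius — controls design quality. The loop then ratchets: the first round
typically recovers only a handful of stabilized candidates (its mean true
tolerance can even trail the natural actives'), but once those labeled
near-wildtype variants enter retraining, the second round proposes
stabilized designs almost exclusively.

## Screening analytics

Initial rates are least-squares slopes over the first quarter of
timepoints (minimum 3). Two calling modes are provided because the
campaign reports no numeric threshold: *kinetic* (active iff the rate is
more than `k = 3` control standard deviations below the no-enzyme control
mean, strictly, with a `1e-12` guard so an exactly flat trace is never
called active) and *endpoint* (active iff the total drop exceeds 50% of
the positive-control drop — the natural reading of a ~16 h permissive
screen). tmax assignment is: inactive at RT, "RT-only", or the maximum
shock temperature with an active call; non-monotone patterns resolve to
the maximum with a logged warning. Tallies use exact integer arithmetic; a
sequence with tmax $T$ counts as "maintaining activity" at every ladder
temperature at or below $T$, which makes ladder counts non-increasing by
construction. "Active above 46" is counted as tmax >= 46 by default, with
the strict reading available (`above_mode = ">"`), because the deposited
wording is ambiguous. Concentration normalization to the 5 uM assay target
records an "undiluted" flag for wells below target rather than
extrapolating rates.

## The loop, and replaying a deposited table

`runCampaign()` chains the stages with stage-labeled error reporting and
derives every stage seed from one global seed, so a campaign is
reproducible bit for bit. The assay is an oracle function — simulator,
deposited-table lookup (`tableAssay`), or in principle a wet lab — and the
semi-supervised model is retrained after every round on all accumulated
labels. `replayDeposited()` recomputes round tallies, the tmax
distribution, per-variant Hamming distances to the wildtype, and the
best-versus-wildtype tolerance differential from an activity table alone.
The package cannot ship the campaign's deposited dataset, so
`syntheticDepositedTable()` constructs — in code, at call time — a table
with the same round structure as the published headline counts and random
synthetic sequences; it exists to exercise the replay path end to end and
is labelled synthetic everywhere.

## Problem sizes used in the tests

The test suite and the acceptance script run the loop at desk scale, the
package's own choice of fixture sizes: a 200-sequence, 120-column planted
alignment for sampler and recovery experiments (10,000 proposed variants;
3 seeds for the recovery and progression checks), a 60-sequence,
40-column alignment for unit-level model tests, and campaign presets of
30-100 natural sequences with design rounds of 8-50. The full-scale
defaults (1,997 natural / 704 / 704) remain available through
configuration.

## Known limitations

- Additive, single-column genetics and binary heat damage are idealized;
  the simulator cannot surface epistasis or graded denaturation.
- The identity filter's denominator (global alignment length, gaps
  counted) is one of several reasonable conventions; the original
  campaign's is unpublished, so it is configurable and the curation report
  records the values used.
- cTP prediction is an adapter plus a deterministic anchor-motif
  heuristic, not a trained predictor; externally predicted lengths should
  be supplied for real data.
- The VAE is CPU-sized; alignments beyond a few thousand rows or a few
  hundred columns will train slowly.
- Unsupervised `designRound()` ranking is arbitrary (no property head);
  it exists as a baseline, not a recommendation.
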