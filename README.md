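# RcaDesign

Machine-learning-directed design of thermotolerant Rubisco activase (Rca)
variants, implemented as a fully testable R package.

## The problem

Rubisco activase is the AAA+ chaperone that hydrolyzes ATP to strip
inhibitory sugar phosphates from Rubisco's catalytic sites — and it is one
of the most heat-labile links in the photosynthetic chain. The cassava
enzyme loses ATPase activity after a one-hour heat shock at 42 °C. Raising
its tolerance by even a few degrees, with as few substitutions as
possible, is a realistic route to protecting yields of a staple crop under
climate warming.

`RcaDesign` is for computational protein engineers and plant-biology
groups who want to run (or audit) the design-build-test loop behind such a
campaign: curate an ortholog alignment, train a generative sequence model,
propose mutation-budgeted synthetic variants, convert high-throughput
ATPase screen readouts into thermal-tolerance calls, feed those labels
back into the model, and iterate.

## The model

The core is a variational autoencoder over the one-hot encoded multiple
sequence alignment (21 symbols per column: 20 amino acids + gap). An MLP
encoder maps a sequence *x* to a diagonal-Gaussian posterior
*q(z|x) = N(μ(x), diag σ²(x))* over a 4-dimensional latent *z*; an MLP
decoder maps *z* back to per-column categorical distributions *p(x|z)*.
Training maximizes the evidence lower bound

    ELBO = E_q [ log p(x|z) ] − β · KL( q(z|x) ‖ N(0, I) )

with the KL term in closed form, ½ Σ (μ² + σ² − 1 − log σ²). A
semi-supervised property head on the latent representation predicts each
sequence's measured maximum tolerated heat-shock temperature (squared
error, standardized) and activity flag (cross-entropy), over labeled rows
only, weighted by λ.

Design rounds sample a Gaussian around the wildtype's posterior, decode by
per-position argmax, and **reject any variant more than 20 substitutions
from the wildtype** (gap counted as a symbol), any duplicate, and anything
already screened — then rank by predicted tolerance.

Screen analytics turn A340-versus-time traces of the coupled ATPase assay
(NADH oxidation, absorbance decay proportional to ATP hydrolysis) into
initial rates, activity calls (3-SD kinetic rule, or a permissive endpoint
rule against the positive-control depletion), a per-sequence maximum
tolerated temperature over the 38/42/46/50 °C challenge ladder, residual
activity percentages, and exact per-round tallies.

A synthetic study system (`groundTruth()`, `generateMsa()`,
`simulateTrace()`) plants a known genotype→tolerance map — by default one
proline→glycine key position worth +8 °C with a 0.7× activity trade-off —
so the whole loop can be tested against ground truth. See the methods
vignette (`vignettes/design-loop-methods.Rmd`) for every modeling choice
and its rationale.

## Worked example

Generate a small planted ortholog set, screen it in silico, train the
semi-supervised model, and design five candidates:

```r
library(RcaDesign)

truth <- groundTruth()                    # planted P→G determinant, +8 °C
msa   <- generateMsa(60, 40, truth = truth, seed = 42)
recs  <- screenSequences(alignedSequences(msa), truth, seed = 1)
tallyRound(recs)

labels <- data.frame(id = alignmentIds(msa),
                     tmax = trueTmax(alignedSequences(msa), truth),
                     active = 1)
model <- trainVae(msa, labels = labels,
                  config = vaeConfig(epochs = 200, learning_rate = 2e-3,
                                     property_weight = 50, seed = 5))
cand <- designRound(model, wildtypeSequence(msa), screen_history = recs,
                    constraints = designConstraints(n_candidates = 5,
                                                    sigma_scale = 3, seed = 8))
cand[, c("id", "hamming_to_wt", "predicted_tmax")]
mean(trueTmax(cand$sequence, truth))
```

Output (printed by the code above):

```
    round tested active_rt inactive pct_active_rt at_38 pct_at_38 at_42
1 natural     60        60        0           100    60       100    25
  pct_at_42 at_46 pct_at_46 at_50 pct_at_50
1  41.66667    25  41.66667     0         0

RcaVae: latent dim 4, semi-supervised, alignment width 40
  trained 200 epochs; final ELBO -21.498 (recon -12.990, KL 8.509)

             id hamming_to_wt predicted_tmax
1 design1_00001             7       44.77679
2 design1_00002             4       43.18980
3 design1_00003             9       41.79860
4 design1_00004             4       41.54557
5 design1_00005             6       41.40449

[1] 41.2
```

The tally row says how many of the 60 screened sequences were active at
room temperature and how many kept activity at each ladder temperature
(counts are non-increasing along the ladder by construction): 25 of 60
tolerate 42 °C or more — these carry the planted glycine. Each design
candidate stays within the 20-substitution budget (`hamming_to_wt`) and is
ranked by the property head's predicted tolerated temperature
(`predicted_tmax`, °C). The designed five average a true tolerance of
41.2 °C against the 38 °C wildtype — the loop is already enriching for the
stabilizing substitution after one round.

`replayDeposited()` recomputes round-level summaries (tallies,
active-above-46 °C counts, per-variant Hamming distances, the
best-versus-wildtype differential) from a deposited-style activity table;
`syntheticDepositedTable()` builds, in code, a stand-in table with the
published campaign's round structure for exercising that path.

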