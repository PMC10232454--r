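---
title: "Two-stage SMILES generation: language modeling then policy-gradient property optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SMILES generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

De novo molecular design asks for novel, chemically valid molecules that
score well on some property — drug-likeness (QED), predicted potency
(pIC50 against a target), or the output of an external activity
classifier. `smirl` treats the SMILES line notation as a language:
a molecule is a string, and generating one is a sequential
decision process that emits one token at a time.

The package implements this in two stages, sharing a single network:

1. **Language modeling.** A decoder-only (GPT-style) transformer is
   trained by teacher forcing to predict the next token of corpus SMILES
   strings framed as `[BOS] s [EOS]`. This stage teaches the grammar of
   SMILES and the local rules of chemistry — which strings parse at all.
2. **REINFORCE fine-tuning.** The same network is then read as a policy
   $\pi_\theta(a \mid s)$ over a Markov decision process whose states are
   string prefixes ($s_0$ = the empty string), whose actions are
   vocabulary tokens plus `[EOS]`, and whose transitions are
   deterministic appends. Reward is zero at every intermediate step; the
   terminal state — reached when `[EOS]` is drawn or the string hits the
   length cap — is scored by a molecular property function. Policy
   gradients ascend $\nabla_\theta J = \mathbb{E}[\,G_t \nabla_\theta
   \ln \pi_\theta(a_t \mid s_t)\,]$ with sampled returns
   $G_t = \sum_{k \ge 1} \gamma^{k-1} R_{t+k}$.

The two-stage order matters: direct RL from a random policy has
essentially zero probability of ever writing a parseable molecule, so
the reward signal (which is validity-gated to 0) never arrives. The
package enforces the order and exposes `allow_untrained = TRUE` only to
let users reproduce that degenerate behaviour deliberately.

## Model and parameters

The decoder follows the pre-norm GPT-2 layout: learned token and
position embeddings, `n_layers` blocks of

$$z = x + \mathrm{MHA}(\mathrm{LN}(x)), \qquad
  x' = z + \mathrm{MLP}(\mathrm{LN}(z)),$$

with causal masking inside the scaled dot-product attention
$\mathrm{softmax}(QK^\top/\sqrt d)\,V$, a final layer norm, and a linear
head to vocabulary logits. The reference configuration is 4 layers, 8
heads, model width 512, feed-forward width 1024, and a 150-token length
cap; `decoder_config()` defaults to it. Everything the reference recipe
leaves open is an explicit package default, chosen once:

* learned positional embeddings (matching the GPT family the
  architecture follows);
* Adam, learning rate `1e-4` for the LM stage and `1e-5` for the RL
  stage at reference scale (the smaller RL rate guards against policy
  collapse); neither rate is part of the reference recipe;
* `[BOS]`-prefixed, `[EOS]`-terminated training sequences with padding
  excluded from the loss;
* GELU activations, truncated-normal initialisation (sd 0.02), dropout
  0.1 during training only, a final pre-head layer norm;
* pure REINFORCE: no baseline is subtracted by default. A
  moving-average baseline is available behind `rl_config(baseline =
  TRUE)` as a non-default variance reduction.

The RL stage defaults mirror the reference protocol: discount
$\gamma = 0.99$, 100 steps of 500 episodes each. The phrase "averaging
500 episodes" is implemented as exactly 500 episodes per step, trading
the looser reading for determinism.

Two further policy choices deserve a note:

* `[PAD]` and `[BOS]` are not actions of the MDP, so the sampler masks
  them out of the next-token distribution (a $-10^{30}$ logit, which
  underflows to exactly zero probability — identical to renormalising
  over the permitted tokens). The same mask is applied inside the
  policy-gradient loss, so sampled log-probabilities and the gradient
  refer to the same distribution. The raw language-model surface
  (`decoder_forward()`) stays unmasked.
* The `[EOS]` draw is an action whose log-probability enters the
  gradient even though the token is never appended: termination is a
  decision of the policy. Episodes truncated at the length cap are
  ordinary terminal states; their strings are scored like any other
  (usually 0, being unfinished chemistry).

## Tokenization

"Character-level" is taken literally: every character of the SMILES
string is a token, including the letters of two-character atoms such as
`Cl`. Decoding is concatenation, which restores such atoms, so
round-tripping is exact. The alternative BPE scheme seeds the vocabulary
with the corpus characters and greedily merges the most frequent
adjacent pair (ties broken lexicographically; merges never cross line
boundaries; pairs must occur at least twice) until a target count — 500
non-special tokens in the reference ablation — is reached. The merge
list is stored with the vocabulary, so re-encoding is deterministic.
Specials sit at fixed ids (`[PAD]` 0, `[BOS]` 1, `[EOS]` 2) for
reproducible checkpoints.

## Rewards

All rewards are validity-gated: a terminal string RDKit cannot parse and
sanitise scores exactly 0. On valid molecules:

* `qed_reward`: $10 \times \mathrm{QED}$, range $[0, 10]$;
* `pic50_reward`: $\exp(\mathrm{pIC50}/3)$, with pIC50 supplied by a
  pluggable scorer; IC50 values are converted as
  $\mathrm{pIC50} = 9 - \log_{10}(\mathrm{IC50\ [nM]})$ (the nanomolar
  unit is this package's reading; it makes the formula produce
  conventional pIC50 values);
* `predictor_reward`: the raw probability of an external classifier-type
  predictor, range $[0, 1]$.

QED and SAS come from RDKit's reference implementations (reached through
a batched subprocess bridge with a session cache); they are consumed as
oracles, not re-derived. A scorer failing on a *valid* molecule raises
an error rather than silently scoring 0 — the zero branch belongs to
invalidity alone, and silent zeros would leak into the gradient.
`surrogate_scorer()` provides a deliberately simple ridge-regression
stand-in for an externally trained graph-network property predictor so
the pIC50/predictor paths are exercisable offline; it is labelled a
surrogate everywhere and makes no claim to chemistry.

## Evaluation metrics

Validity is the percentage of generated strings RDKit parses. Novelty
and diversity are computed on canonical SMILES — raw string comparison
would miscount rewrites like `OCC` vs `CCO` — and, like the QED/SAS
statistics, over valid molecules only; the exclusion rule stated for the
property statistics is applied uniformly, and the report records this in
a `denominators` field. Duplicates are retained when averaging QED/SAS
(diversity reports uniqueness separately). The reference protocol draws
25,000 molecules per evaluation; `evaluate()` records the intended and
actual counts. Percentages are reported to two decimals, rounded
half-up.

## The synthetic corpus

`generate_fixture_corpus()` makes the whole pipeline runnable offline:
it enumerates alkane chains, single branches, 3–6-membered carbocycles
with tails, and O/N heteroatom substitutions (single and double) within
a heavy-atom budget, canonicalises everything with RDKit, deduplicates,
and emits a seed-shuffled subset. The default budget of 11 heavy atoms
gives an enumerable space comfortably above five thousand unique
molecules — large enough to train on without repeating the pool — while
keeping strings under 14 characters so a small decoder learns the
grammar in minutes on one CPU.

What the synthetic corpus deliberately lacks: stereochemistry, charges,
fused and aromatic rings, sulfur/halogens, and the property
distributions of real screening libraries. Its QED values span roughly
0.26–0.65. Tests passing on this corpus therefore demonstrate the
*mechanics* — grammar learning, reward ascent, metric arithmetic — not
chemical coverage of Zinc-like corpora, which can be dropped in as
plain `.smi` files with identical code paths.

## Numerical choices

The decoder forward/backward passes are hand-written in C++
(RcppArmadillo) because no automatic-differentiation framework is part
of this package's dependency footprint; the backward pass is verified
against central finite differences to `1e-6` relative tolerance in the
test suite, and the REINFORCE gradient additionally against exact
enumeration of a toy MDP. Layer norm uses $\epsilon = 10^{-5}$;
softmaxes subtract the row maximum; log-probabilities are floored at
`1e-300` inside the loss. The equality between the expected REINFORCE
gradient and $\nabla_\theta \sum_s p_\theta(s) R(s)$ is exact only for
$\gamma = 1$ with terminal-only rewards, so the oracle tests run
undiscounted; discounted return arithmetic is tested separately against
a brute-force double sum.

Degenerate inputs have defined behaviour: an empty generated set
evaluates to 0% validity with a warning; `compute_returns(numeric(0))`
is `numeric(0)`; a zero-reward batch produces an exactly zero gradient
and (with fresh optimiser state) bit-identical parameters.

## Desk-scale protocol

The package's acceptance workflow (`scripts/acceptance.R`, mirrored by
the heaviest test) runs the full two-stage protocol at a size chosen for
a single CPU: the 5,000-molecule synthetic corpus, a 2-layer / 8-head /
width-64 / feed-forward-128 decoder with a 32-token cap, 3 training
epochs, then 30 REINFORCE steps of 128 episodes under the QED reward,
with 1,000-molecule evaluations before and after. Two desk-scale
settings differ from the reference-scale defaults, both chosen for the
statistics of small batches rather than for any particular outcome:

* *Learning rates.* The desk model is two orders of magnitude smaller
  than the reference configuration, so the LM stage uses Adam at `1e-3`
  (instead of `1e-4`); the RL stage uses `3e-4` (instead of `1e-5`),
  large enough that thirty steps traverse meaningful ground.
* *Baseline on.* At 128 episodes per step the Monte-Carlo gradient has
  roughly thirteen times fewer samples per step than the reference
  protocol's 500-episode steps over 100 steps. Pure REINFORCE with an
  all-positive reward then exhibits a rich-get-richer pathology: every
  sampled action is pushed up in proportion to its return, so
  high-probability short molecules with mediocre QED absorb the
  probability mass and the policy collapses onto a handful of strings.
  The desk protocol therefore enables the package's moving-average
  baseline, which centres the returns so that only above-average
  molecules are reinforced. The algorithm remains REINFORCE (with
  baseline); the reward, discount and step budget are unchanged; and
  the full-scale default remains pure REINFORCE.

The expected outcome is directional, matching the with/without-RL
comparison at reduced scale: mean QED of sampled molecules strictly
increases, validity stays high, and the mean terminal reward over the
last ten steps exceeds the first ten.

## Known limitations

* No KV-cache in the sampler: each emitted token re-runs the full
  prefix, which is fine at desk scale and wasteful at 150-token scale.
* Canonicalisation round-trips through a subprocess; throughput is
  batched but latency-bound, so per-molecule calls in tight loops should
  go through the vectorised functions.
* The BPE learner is quadratic-ish in merge count on large corpora; it
  is intended for the ablation-sized vocabularies it reproduces.
* Single-objective rewards only; composing properties is out of scope.
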