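# smirl — two-stage SMILES generation with policy-gradient property optimisation

`smirl` generates novel drug-like molecules for de novo molecular
design. It treats a molecule's SMILES string as a sentence: a
decoder-only (GPT-style) transformer is first trained as a language
model on a corpus of molecules, learning the grammar of SMILES and the
local rules of chemistry; the same network is then fine-tuned with
REINFORCE so that molecules sampled from it maximise a terminal property
reward. The package is aimed at computational chemists and method
developers who want a fully inspectable, CPU-scale implementation of
this two-stage recipe, with every stage runnable offline.

## The method in brief

Generation is a Markov decision process over string prefixes: the state
is the SMILES written so far (starting empty), the actions are the
vocabulary tokens plus `[EOS]`, transitions append deterministically,
and the only reward arrives at the terminal state — when `[EOS]` is
drawn or the length cap is hit. With $G_t = \sum_{k\ge1}\gamma^{k-1}R_{t+k}$
the policy follows the score-function gradient

$$\nabla_\theta J(\theta) \;=\; \mathbb{E}_\pi\!\left[\,G_t\,
\nabla_\theta \ln \pi_\theta(a_t \mid s_t)\,\right],$$

estimated over sampled episodes. Built-in validity-gated rewards (an
invalid SMILES scores exactly 0):

| reward | valid molecule scores | range |
|---|---|---|
| `qed` | $10\times\mathrm{QED}$ | $[0,10]$ |
| `pic50` | $\exp(\mathrm{pIC50}/3)$ | $\ge 0$ |
| `predictor` | external classifier probability | $[0,1]$ |

plus `pic50_from_ic50()` implementing
$\mathrm{pIC50} = 9-\log_{10}(\mathrm{IC50\,[nM]})$. Generated sets are
scored with the standard metric suite — validity, novelty and diversity
(on canonical SMILES, valid molecules only) and QED/SAS mean ± sd.
Parsing, canonicalisation, QED and SAS are delegated to RDKit through a
bundled batch bridge (`python` with `rdkit` must be on the PATH).

## Worked example

Everything below runs offline on one CPU in a couple of minutes, using
the package's deterministic synthetic corpus (small chains, branches,
rings and O/N-substituted molecules):

```r
library(smirl)

corpus <- generate_fixture_corpus(fixture_spec(5000, seed = 71))
vocab  <- build_char_vocab(corpus)

cfg <- decoder_config(length(vocab), n_layers = 2, n_heads = 8,
                      d_model = 64, d_ff = 128, max_len = 32)
lm  <- train_lm(corpus, cfg, epochs = 3, seed = 72, lr = 1e-3)
tidy(lm)
#> # A tibble: 3 × 2
#>   epoch  loss
#>   <int> <dbl>
#> 1     1 1.21
#> 2     2 0.883
#> 3     3 0.805

rl <- rl_finetune(lm, reward_spec("qed"),
                  rl_config(n_steps = 30, episodes_per_step = 128,
                            lr = 3e-4, baseline = TRUE, max_len = 32,
                            seed = 74))

pre  <- sample_batch(lm$params, vocab, n_samples = 1000, seed = 73)
post <- sample_batch(rl$params, vocab, n_samples = 1000, seed = 75)
evaluate(pre, corpus, n_expected = 1000)
#> <metrics_report>
#>   generated 1000 (expected 1000), valid 881
#>   validity 88.10%  diversity 92.51%  novelty 28.83%
#>   QED 0.518 +/- 0.075   SAS 2.58 +/- 0.45
evaluate(post, corpus, n_expected = 1000)
#> <metrics_report>
#>   generated 1000 (expected 1000), valid 950
#>   validity 95.00%  diversity 60.11%  novelty 30.11%
#>   QED 0.552 +/- 0.049   SAS 2.51 +/- 0.46
```

Reading those numbers: after three epochs the language model writes
parseable chemistry for ~88% of samples. Thirty baseline-centred
REINFORCE steps under the `10 * QED` reward lift validity to 95% and
shift the mean QED of sampled molecules from 0.518 to 0.552, at the
price of concentrating on fewer distinct molecules (diversity 93% →
60%) — the validity/diversity trade-off RL fine-tuning exhibits at
every scale. Novelty is modest here because the synthetic motif space
is small and partly memorised; real corpora (Zinc/Moses-style `.smi`
files drop in unchanged) behave differently.

A shell workbench wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","smirl.R",package="smirl"))') \
    fixtures --n 5000 --seed 7 --out fixtures.smi
# then: train-lm, rl, generate, evaluate, stats
```

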