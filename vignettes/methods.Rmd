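---
title: "Reward-driven text simplification: model, rewards and training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-driven text simplification: model, rewards and training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simplerl)
```

## The problem

Medical abstracts and systematic-review summaries are written at a reading
level far above what most of the public can comfortably follow. Automatic
text simplification rewrites such a paragraph — the *source* S — into a
*generation* G that preserves the meaning of a human-written *reference*
simple version T while reading at a lower grade level and using more common
words. `simplerl` implements the measurement and training machinery for this
task: the automatic metrics used to evaluate simplification systems, three
rewards that score a candidate simplification, and the reinforcement-learning
objective that trains a conditional generator against those rewards.

The package is deliberately runnable at desk scale. A full-scale system
would plug a large sequence-to-sequence model (a BART-class transformer) and
a biomedical sentence embedder into the same contracts; the package ships a
closed-form toy policy and a hashed bag-of-words embedder so that every
result here is reproducible in seconds on one CPU, with no downloads.

## Text statistics and metrics

All metrics share one canonical tokenizer: sentences split at `.`, `!`, `?`
followed by whitespace (with a small abbreviation guard list, e.g. "e.g.",
"et al."), words are maximal alphanumeric+apostrophe runs, lowercased.
Syllables are counted by the standard vowel-group heuristic (`aeiouy`
groups, trailing silent "e" dropped unless it is the only group, floor of
one, small exception table). Published readability numbers are sensitive to
these choices, which is why they are pinned and documented; reproduction of
external corpus-level values is therefore approximate by nature.

The Flesch-Kincaid Grade Level is

$$\mathrm{FKGL} = a \cdot \frac{\text{words}}{\text{sentences}} +
  b \cdot \frac{\text{syllables}}{\text{words}} - c.$$

Two coefficient presets are provided. `"standard"` is the widely used
triple $(0.39, 11.8, 15.59)$ and is the default for corpus reports.
`"paper"` is $(0.38, 1.8, 15.59)$, a variant printed in parts of the
medical-simplification literature; its second coefficient differs by an
order of magnitude from the standard formula, and published corpus values
are consistent with the standard triple, so the variant is kept only for
strict fidelity experiments. The Automated Readability Index uses the
standard constants $4.71 \cdot \text{chars/word} + 0.5 \cdot
\text{words/sentence} - 21.43$.

ROUGE-n is clipped-count multiset n-gram overlap (precision, recall, F1),
with no stemming or stopword removal. SARI averages, over n = 1..4 with
equal weight, the F1 of n-gram *additions* and *keeps* and the precision of
n-gram *deletions*, judged against the source and the reference. Operation
sets are unique n-grams. Published SARI implementations differ in their
handling of empty operation sets; here the convention is pinned: if the
candidate-side and reference-side sets are both empty the component scores
1 (the operation was not required and was not performed), if exactly one is
empty it scores 0. Under this convention a candidate identical to the sole
reference always scores 1, which we consider the defining identity of the
metric.

## The three rewards

Each reward scores a triple (S, T, G); all three are pure functions, which
the self-critical baseline below requires.

**Relevance** is the cosine similarity between embeddings of T and G,
clipped to [0, 1]. The embedding model is a contract (text to fixed-length
vector, deterministic); the packaged default is a hashed bag-of-words
embedder (64 signed hash buckets over word types) so the reward runs with
no pretrained weights. A biomedical sentence embedder raises the fidelity
of this reward but not its shape.

**Readability gap** compares grade levels: $r_F = \mathrm{clip}\!\left(
\frac{r(T) - r(G)}{\max(|r(T)|, 10^{-6})}, -1, 1\right)$, positive exactly
when G reads below the target's grade. The relative (rather than absolute)
difference keeps the reward scale-free across corpora whose references sit
at different grades; the clip bounds the gradient signal.

**Lexical simplicity** rests on the Zipf scale: a word's Zipf frequency is
$\log_{10}$ of its occurrences per billion words, roughly 7 for "the" and
1–2 for rare jargon. For the unique word types inserted by the
simplification (in G, not S) and deleted by it (in S, not G),
$\Delta Z = \bar{Z}(G - S) - \bar{Z}(S - G)$: positive when the words
brought in are commoner than the words removed. In paired medical
simplification corpora the typical shift is about 0.4, and roughly 87% of
pairs sit near that value, so the reward is a ramp saturating there:
$r_L = \mathrm{clip}(\Delta Z / 0.4,\, 0,\, 1)$. The saturation point is
configurable. Empty type sets contribute mean 0, so a verbatim copy earns
no lexical reward. Out-of-vocabulary words default to Zipf 0 ("below
measurable frequency"), treating unknown tokens as maximally rare.

The total reward is the weighted sum
$R = \alpha\,r_{\cos} + \beta\,r_F + d\,r_L$ with non-negative weights,
equal thirds by default (the fitted weights of the original study are not
public).

## Training objective

The generator is any conditional distribution $p_\theta(y_t \mid y_{<t}, x)$
exposing per-step log-probabilities. Two losses combine:

* the maximum-likelihood loss
  $L_{ml} = -\sum_t \log p_\theta(y_t \mid y_{<t}, x)$ on the reference, and
* the policy-gradient loss with a baseline $b$,
  $L_{pg} = -\frac{1}{n}\sum_t \log p_\theta(y^s_t \mid \cdot)\,(r(y^s) - b)$,
  where $y^s$ is a sequence sampled from the model.

Self-critical sequence training instantiates $b = r(y^*)$, the reward of
the model's own greedy decode: a sample is promoted exactly when it beats
what the current policy would deterministically produce. The mixed loss is
$L = \gamma L_{pg} + (1 - \gamma) L_{ml}$, and training follows a two-phase
schedule: MLE-only epochs first (so the policy speaks the corpus language),
then mixed-loss epochs.

Decoding: greedy takes the argmax at each step (ties broken toward the
lowest token id, for determinism), sampling draws at temperature 1 with no
truncation. Rollouts stop at the end token or at `max_decode_length` and
are scored as-is; an empty generation receives reward 0 in all components.
During training, G is the detokenized rollout, T the pair's reference and
S its source. Advantages are per-sample, as in standard self-critical
training; batch gradients are averaged and applied by plain stochastic
gradient descent, keeping the core auditable — external frameworks can
attach their own optimizer through the same contract.

## The toy policy

The packaged generator is intentionally the smallest model that makes the
objective non-trivial:

$$\mathrm{logits}_t = b + A\,(B\,\phi(x)) + U[\,\cdot, y_{t-1}] +
  Q[\,\cdot, \min(t, P)]$$

with $\phi(x)$ the L1-normalized bag-of-token counts of the source, a
rank-16 source map $A B$, a previous-token transition matrix $U$ whose
extra final column is used at the first step (so the model can learn that
sequences never open with the end token), and a per-position term $Q$
with $P = 12$ slots (later positions share the last). The position term
matters more than it looks: without it the policy cannot express "stop
after about k tokens", and the readability reward — which favors short
generations — is simply unreachable, so the reinforcement phase stalls.
All gradients are closed-form softmax gradients, verified in the test
suite against central finite differences at $10^{-5}$.

Two step sizes are used: `learning_rate` (default 0.5) for the MLE phase
and `rl_learning_rate` (default 10) for the mixed phase. The separation
reflects the objectives' scales, not tuning folklore: per-token MLE
gradients are O(1) probability differences, while policy-gradient
weights are an advantage (a fraction of a unit-scale reward) divided by
the rollout length — roughly an order of magnitude smaller.

The mixing scalar defaults to $\gamma = 0.98$. The choice is a genuine
trade-off that is easy to see empirically: at $\gamma = 1$ (no MLE
anchor) the policy climbs the combined reward fastest, but it does so by
collapsing onto short, very common, content-free output — high
readability and lexical rewards, relevance near zero. That degenerate
optimum is exactly the failure mode the mixed loss is meant to prevent;
a small MLE weight keeps the generations anchored to the references
while still letting the reward shape them.

## The synthetic corpus

The generator emulates exactly the two statistical axes the rewards and
metrics read, and nothing else:

* a **readability gap**: complex paragraphs of 3–6 sentences around 25
  words each, drawn from the rare end of the vocabulary; simple paragraphs
  of 2–4 sentences around 8 words (truncated normal lengths, floor 3);
* a **Zipf shift**: the simple side reuses a fraction (default 0.3) of the
  complex side's word types and fills the rest with insertions whose mean
  Zipf frequency is matched to (mean deleted Zipf + `target_delta_z`), so
  the corpus-mean shift approximates the target, 0.4 by default — the
  shift typical of paired medical simplification data.

The vocabulary is itself synthetic: pseudo-words built from
consonant-vowel syllables (no "e", so the silent-e rule never fires),
with Zipf values on a continuum from 0.5 to 7 and syllable counts
negatively correlated with frequency, as in natural language. Because the
complex text depletes insertion candidates just below the desired Zipf
value, the insertion draw is followed by a small swap correction that
recenters the drawn mean; without it the realized shift runs about 0.1
high. Generation is a pure function of (vocabulary spec, corpus spec),
both of which carry their seeds.

What the generator does *not* emulate: meaning, discourse structure,
medical terminology, or factuality. A passing test on this corpus shows
that the metrics, rewards and training objective behave as specified on
data with known statistical structure — it does not show that a trained
toy policy simplifies real medical text.

## Problem sizes and numerical choices

The standard desk-scale experiment (`toy_training_setup()`) uses a
60-word vocabulary, 200 training pairs at the training scale (1–2 complex
sentences around 12 words; one simple sentence around 6), 5 MLE epochs
followed by 100 RL epochs at batch size 8, and rollouts capped at 20
tokens. These sizes were chosen so a full two-phase run takes about a
minute and a multi-seed comparison a few minutes, while leaving the reward
landscape rich enough that the RL phase has something real to climb: at
initialization a random policy babbles to the length cap, the MLE phase
pulls it toward reference-like short outputs, and the RL phase then trades
off the three rewards (stopping earlier than the references helps the
readability reward; inserting common vocabulary helps the lexical reward;
overlapping the target's words helps relevance).

Numerical conventions worth knowing:

* greedy ties break toward the lowest token id; sampling records its seed
  in the rollout, and every internal seed is derived deterministically from
  the run seed, so whole training runs are bit-reproducible;
* a generation whose hashed embedding cancels to the zero vector scores
  relevance 0 during training (the strict API, `relevance_reward()`,
  raises an error instead — degenerate embeddings are a user mistake in
  analysis code but an expected transient during exploration);
* the trace's reward columns are the mean rewards of the sampled
  rollouts observed during each epoch's steps — the running estimate of
  the expected reward that the policy gradient maximizes — and the
  epoch-0 and final rows are seeded sampled evaluations of the fixed
  initial and final policies, so first and last entries use the same
  estimator; greedy (deployment) quality is available separately via
  `evaluate_policy(mode = "greedy")`. The greedy decode of the *random
  initial* policy is a degenerate babble loop whose reward is an
  artifact of the argmax, which is why the expected (sampled) reward is
  the honest ascent measure;
* `delta_z` "approximately 0.4" is operationalized as the band [0.3, 0.5]
  in corpus reports; the band is configurable.

## Known limitations

The toy policy is near-unigram (one-step transition memory) and cannot
model word order beyond adjacency; ROUGE-2 of its generations is
accordingly weak. The hashed embedder measures vocabulary overlap, not
meaning; relevance under it is a lexical proxy. The syllable heuristic is
wrong on a known tail of English words ("-le" endings, some loanwords);
the exception table covers only common cases, which is one reason
corpus-level readability of external data reproduces only to within about
half a grade. The reward set itself is known to admit degenerate optima
(very short, very common-worded output scores well on two of three
components); the relevance weight is what anchors generations to content,
and a stronger embedder sharpens that anchor.
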