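---
title: "Methods: automated Padua VTE risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated Padua VTE risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vterisk)
```

## The problem

The Padua prediction score estimates a hospitalized medical patient's
risk of venous thromboembolism from eleven risk factors with integer
weights summing to 20; patients with a total of at least 3 are treated
as high risk. Five factors are disease categories that require reading
the diagnosis in context; the other six are clinical facts (recent
surgery, reduced mobility, hormonal treatment, age, BMI, thrombophilia
labs) scattered through the narrative and structured parts of an EMR.
`vterisk` automates the whole scale with two branches whose outputs are
eleven boolean item flags, each with human-readable evidence, a total
score, and a risk level.

A score exactly equal to the cutoff is stratified as **high** risk —
the conservative clinical choice; the published phrasing ("below 3 …
low", "above 3 … high") leaves the boundary case open, so `cutoff` is a
parameter and the strict `> 3` reading is one configuration change away.
An optional three-level view separates totals of exactly 0, mirroring
the cohort stratum used for evaluation.

## Branch A: the disease-category classifier

Each diagnosis string, paired with the patient's extracted symptom list,
forms one classification unit mapped to one of six categories (the five
disease items plus "others").

**Symptom weight vector.** For category $k$ with symptom corpus $N_k$,
$\mathrm{TF}(t,k) = N_{k,t}/\mathrm{count}(N_k)$,
$\mathrm{IWF}(t) = \log(W_c / W_{c,t})$ over the pooled corpus, and
$\mathrm{TI} = \mathrm{TF}\times\mathrm{IWF}$. A unit's weight vector
starts at six zeros and, for every symptom and every category containing
it, adds $\mathrm{TI}_{k,t}/\max_{t'}\mathrm{TI}_{k,t'}$. Down-weighting
globally common symptoms is the point: a symptom shared by many
categories has a small IWF and contributes little anywhere.

Numerical choices: the logarithm base is immaterial (it cancels under
the max-normalization) and defaults to the natural log; a category whose
maximal TI is 0 contributes 0 rather than 0/0; duplicate symptoms are
deduplicated by default (patient-level symptom sets are sets), with a
switch for occurrence-counting.

**Embedding.** Diagnosis text maps to a fixed 20 × 768 matrix and the
symptom list to 50 × 768 (truncation at the tail, zero-row padding).
The default embedder is a deterministic hashed token projection: each
token seeds a Lehmer (Park–Miller) stream that emits its 768-vector, so
runs are bit-reproducible across platforms with no model downloads. The
vectorizer is a contract; a pretrained contextual embedder can be
plugged in behind it.

**Encoders.** Two stacked bidirectional LSTM layers per input role:
layer 1 returns per-position features of width 768 (384 per direction);
layer 2's final forward and backward states concatenate to the 768-wide
output. All-zero padding rows are masked, so their placement cannot
influence the result.

**Fusion and head.**
$h_\text{concat} = [h_\text{diagnosis}, h_\text{symptoms}]$ (1536);
inverted dropout (default rate 0.5) applies only in training; the
symptom weight vector is prepended to give the 1542-wide fused feature;
an affine map and softmax produce the six category scores, trained with
focal loss $-\alpha_y (1-p_y)^\gamma \log p_y$ (default $\gamma = 2$,
$\alpha$ = inverse class frequency) to counter the heavy class
imbalance. At the patient level each diagnosis forms a unit with the
shared extracted symptoms; an item is flagged if any unit's argmax is
its category, and per-category patient scores are unit maxima (used by
the ranking metrics).

**A deliberate deviation: fixed random encoders.** The encoder stacks
are initialized from a seeded RNG and then held fixed; gradient training
(Adam, lr 1e-3, batch 32) applies to the classification head only. Full
backpropagation through ~7M recurrent parameters at the mandated
geometry is not feasible in pure R within a one-CPU test budget, and
random recurrent networks are established feature maps (echo-state
networks). Every architectural contract — shapes, fusion order, dropout
placement, focal loss, early stopping, ablation wiring — is preserved
and tested; what changes is which parameters move during training. A
consequence worth knowing: the head is linear in the fused feature, so
tasks that need nonlinear interactions between the branches are out of
reach; the synthetic worlds used by the tests are solvable by a linear
head over these features, and the acceptance suite demonstrates that
they are solved.

**Training protocol.** Stratified, seeded 7:3 train/validation split
(the source protocol states only the ratio; stratification guards the
rare classes). Data amplification duplicates a seeded 10% of the
disease-category units with an appended uncertainty marker ("?",
"undecided") relabeled to "others", emulating uncertain diagnoses; an
ablation mode disables it. Training runs at most 100 epochs and stops
after 10 epochs without validation-F1 improvement (macro by default;
micro by switch). The returned checkpoint has the highest validation
F1; among F1 ties the later checkpoint with lower validation loss wins —
macro-F1 over an argmax is a step function, and without the tie-break
the loop would return a barely-trained epoch-1 head whenever F1
plateaus early.

## Branch B: the clinical-factor extractor

Sentences (split on CJK/ASCII terminators; a period between digits is a
decimal point, not a boundary) are segmented by greedy longest match
over the union of the loaded lexicons plus date patterns: lexicon terms
become `TERM` tokens, negation cues `NEG`, date expressions `TIME`, the
rest whitespace-split `OTHER`. Terms edged by ASCII alphanumerics match
only at word boundaries ("no" never fires inside "normal"); CJK terms
need no boundaries. Spans are 0-based, half-open, and reconstruct the
sentence.

**Negation.** A match is negated when a cue shares its
comma/semicolon-delimited clause, optionally within a token window
(default: the whole clause). Clause scope strictly contains both
published behaviors — filtering the sentence around the cue and
matching the cue's immediate context. Negated matches are kept for
provenance but excluded from flags. The default cue list ("no", "not
used", "not seen", "none", "not found", "denies", … plus common Chinese
cues) is extensible from file.

**Time.** Absolute dates ("On April 16, 2021", ISO-8601, CJK
year-month-day) and simple relative phrases ("3 days/weeks/months ago")
resolve against the record date; unresolvable expressions yield `NA`
and never crash. The recent-surgery flag fires only for a non-negated
surgery/trauma match anchored to a date within the window — 30 days by
default, calendar-month arithmetic by switch; both window boundaries
are inclusive. Undated mentions never fire the flag (the conservative
reading of an unstated behavior).

**Numeric rules.** Elderly ⇔ age ≥ 70; obesity ⇔ BMI = weight/height²
≥ 30; thrombophilia ⇔ any present lab crossing its bound. The lab
bounds (protein C < 70%, protein S < 60%, antithrombin III < 80%,
d-dimer > 0.5 mg/L) are package defaults, configurable and documented as
placeholders: the source cites its laboratory criteria without printing
values. Missing numerics yield `FALSE` with a "missing data" note.

## Evaluation indexes

Per-label Mann–Whitney AUC (ties half-credit), macro/micro F1, Hamming
distance, one-error, ranking loss (pairwise, ties half-credit) and
coverage (worst-relevant-rank − 1; a `normalized` flag divides by the
label count, since published coverage values below 1 imply a
normalization whose definition is not stated). Degenerate samples are
excluded with warnings. Every metric is checked against brute-force
enumeration to 1e-12.

## The synthetic world

The generator replaces private corpora and hospital records; all
randomness is Mersenne-Twister under a single seed and bit-reproducible.

* **Corpora/lexicons**: six per-category symptom vocabularies with
  Zipf-like counts; `*_overlap` fractions shared with a common pool;
  synthetic multi-word surgery/hormone/mobility terms. Vocabularies are
  fixed catalogs (diagnosis and symptom term spaces are closed coding
  systems in the emulated setting); the seeded draws live in the units
  and records.
* **Training units**: 2–4 diagnosis keywords and 3–8 count-weighted
  symptoms per unit, 100 units per category by default (the published
  class counts are three orders of magnitude larger and private; the
  desk-scale world keeps the structure, not the size). Off-category
  symptom noise is a rate parameter, 0 by default.
* **EMRs**: each record samples its 11 gold flags from per-item
  prevalences (defaults are the published per-item positive counts over
  the 7,690-record cohort, so most records score 0), then plants exactly
  the corresponding evidence: category-vocabulary diagnoses and
  symptoms, dated surgery sentences inside the window, lexicon terms
  for mobility/hormones, numerics across the rule thresholds — plus
  negated and out-of-window distractors that must not flip any flag.
* **The ablation preset** (`preset_symptom_informative`) emulates the
  regime that motivates the symptom weight vector: 80% of diagnosis
  tokens shared (diagnosis under-determines the category), 40% of
  symptom terms shared with the Zipf head (common symptoms inject noise
  into the raw encoding), 5% off-category noise. TF-IWF down-weights
  the shared terms, so the weight vector carries cleaner signal than
  the raw symptom encoding, and the expected ordering — full model ≥
  diagnosis+symptoms ≥ diagnosis-only — emerges on seed averages.

What a green test does and does not establish: the generated text is
keyword-bearing synthetic prose, so the suite validates the mechanics
(segmentation, negation scope, time windows, weighting arithmetic,
training protocol, aggregation) — not clinical NLP performance on real
narrative, which requires real corpora and the pretrained-embedder
adapter.

One structural property deserves emphasis: training units carry
per-diagnosis symptom sets, but deployment hands every unit the
patient-wide symptom union (Branch B extracts symptoms once per
record). On multi-disease records this shift misroutes a small fraction
of units no matter how the head is trained — the same shift exists in
the emulated system, whose disease-branch accuracy is far from perfect
on real data. The end-to-end soundness test therefore asserts exactness
where exactness is structural (the deterministic rule branch: planted
gold flags are recovered perfectly, and risk levels with them), and the
full two-branch pipeline is evaluated with reported, not asserted,
sensitivity/specificity.

## Known limitations

* No clinical NER, coreference or spelling correction; matching is
  lexicon-exact by design.
* The default embedder is context-free; homonyms and paraphrases need
  the pretrained adapter.
* Thrombophilia lab bounds are placeholders; deployments must supply
  local reference ranges.
* Sentence splitting is rule-based; prose with unusual punctuation can
  merge or split clauses and shift negation scope.
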