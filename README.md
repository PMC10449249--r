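# vterisk

Automated Padua risk assessment for venous thromboembolism (VTE) from
electronic medical record (EMR) text.

Hospitalized medical patients are screened for VTE risk with the Padua
prediction score: eleven risk factors, each worth 1–3 points, summed to a
total out of 20; a total of ≥ 3 marks a high-risk patient who should be
considered for prophylaxis. Scoring the scale by hand requires a clinician
to read the whole record, so in practice only a fraction of admissions are
assessed. `vterisk` implements a fully automated dual-branch pipeline:

- **Branch A — disease-category classifier.** Five Padua items are disease
  categories (prior VTE, active cancer, heart/respiratory failure, acute
  MI/ischemic stroke, acute infection/rheumatologic disorder). Each
  (diagnosis text, patient symptoms) pair forms a classification unit:
  the diagnosis embeds to a 20 × 768 matrix, the symptom list to 50 × 768;
  two stacked bidirectional LSTM encoders produce
  `h_diagnosis`, `h_symptoms` ∈ R⁷⁶⁸;
  `h_concatenated = [h_diagnosis, h_symptoms]` passes through dropout and
  is prepended with a length-6 **symptom weight vector** (SWM) built from
  TF-IWF statistics — `TF = N_{k,t}/count(N_k)`,
  `IWF = log(W_c / W_{c,t})`, `TI = TF × IWF`, max-normalized per category
  and summed over the unit's symptoms — giving a 1542-wide fused feature
  classified by a softmax head trained with focal loss
  `-α_y (1-p_y)^γ log p_y`. A Padua disease item is flagged when some
  unit's argmax lands in its category.
- **Branch B — clinical-factor extractor.** Greedy longest-match
  segmentation against surgery/trauma, hormonal-drug, reduced-mobility and
  symptom lexicons; clause-scoped negation filtering ("no", "not seen",
  "denies", …); date parsing and anchoring so that "recent (≤ 1 month)
  trauma/surgery" fires only for a dated, non-negated mention within the
  30-day window; numeric rules for age ≥ 70, BMI ≥ 30 kg/m², and
  thrombophilia labs (protein C/S, antithrombin III, d-dimer).

The package also ships the multi-label evaluation indexes (per-label AUC,
F1, Hamming distance, one-error, ranking loss, coverage, and the
sensitivity/specificity/precision panel for risk levels) and a seeded
synthetic-EMR generator with planted gold labels that stands in for
private hospital data.

## Worked example

```r
library(vterisk)

lex <- lexicon_set(
  surgery_trauma   = c("artificial joint replacement", "hip fracture repair"),
  hormone          = c("tamoxifen", "estrogen therapy"),
  reduced_mobility = c("deep coma", "bedridden"),
  symptom          = c("fever", "cough", "chest pain", "edema"))

rec <- emr_record(
  record_id   = "demo-001",
  record_date = "2021-04-30",
  diagnoses   = "community acquired pneumonia",
  sections    = list(
    past_history   = "On April 16, 2021, artificial joint replacement. no edema",
    complaints     = "fever and cough for three days",
    treatment_plan = "patient remains bedridden"),
  age_years = 74, height_m = 1.70, weight_kg = 66)

assess(rec, model = NULL, lex)   # rules-only assessment (no classifier)
#> Padua risk assessment: total = 6 | level = high
#>   + elderly : age 74 years
#>   + reduced_mobility : bedridden
#>   + recent_surgery_trauma : artificial joint replacement on 2021-04-16
```

The surgery mention is anchored to 2021-04-16 — 14 days before the record
date, inside the 30-day window — while the negated "no edema" is excluded
and the extracted symptoms (`fever`, `cough`) are what Branch A would
receive. Passing a trained model (below) adds the five disease items.

The SWM worked example: with category corpora
`{fever: 2, cough: 1}` and `{cough: 1}`, the symptom list `["cough"]`
yields

```r
corp <- symptom_corpora(list(c(fever = 2, cough = 1), c(cough = 1)))
build_swm("cough", corp)
#> prior_vte active_cancer heart_resp_failure mi_stroke infection_rheum others
#>       0.5           1.0                0.0       0.0             0.0    0.0
```

i.e. `cough` is maximally characteristic of category 2 (it is that
corpus's best term) and half-normalized in category 1, where `fever`
dominates.

## Training and the full pipeline

```r
spec   <- generator_spec(seed = 1)          # synthetic stand-in world
bundle <- gen_corpora(spec)
units  <- gen_training_units(spec, bundle)  # 600 labeled units
model  <- train_pdcm(units, bundle$corpora, train_config(seed = 1))
records <- gen_emr(spec, bundle)            # EMRs with planted gold flags
report  <- evaluate_batch(records, model, bundle$lexicons)
```

A command-line interface wraps the same steps
(`simulate`, `build-swm`, `train`, `assess`, `evaluate`), e.g.

```sh
Rscript exec/vterisk simulate --seed 7 --out-dir fixtures
Rscript exec/vterisk train --units fixtures/units.jsonl \
        --corpora fixtures/corpora.tsv --seed 7 --out model
Rscript exec/vterisk evaluate --emr fixtures/emr.jsonl \
        --model model --lexicons fixtures --out metrics.json
```

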