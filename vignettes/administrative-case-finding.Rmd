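---
title: "Tracer-based case finding and rate estimation for parkinsonism and dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer-based case finding and rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Neither parkinsonism nor dementia has a population registry in most Italian
regions, but both leave a durable trace in administrative data: reimbursed
prescriptions of disease-specific drugs, hospital discharge diagnoses, and
chronic-disease exemption codes. `ndtrace` adjudicates case status from
these traces, over four linked sources — population registry, outpatient
prescriptions (ATC), hospital discharge records (ICD-9-CM, up to six
diagnosis positions), and exemptions — and estimates the stratified,
standardized rates a surveillance report needs.

The core assumption is pharmacological: antiparkinsonian drugs and
anti-dementia drugs are prescribed almost exclusively to the target
populations, and — the sensitivity-enhancing step — antipsychotics,
trazodone and mirtazapine in an older person *without psychiatric illness*
are strong proxies of dementia, because they are the standard treatment of
its behavioural disturbances. The proxy criterion trades specificity for
sensitivity, which is why it is vetoed by any psychiatric discharge or
exemption when it is the only evidence.

## Adjudication rules

Parkinsonism: (i) repeated antiparkinsonian prescriptions, or (ii) the
Parkinson-specific exemption (038). Dementia: (i) repeated anti-dementia
prescriptions, (ii) a dementia ICD-9 code in any diagnosis position of a
discharge, (iii) a dementia exemption, or (iv) repeated proxy-drug use;
(iv)-only cases with psychiatric labels are excluded. The *both* group is
exactly the intersection of the two case sets — an identity the test suite
asserts rather than assumes.

Decisions the sources leave open, and what this package does:

* **"Repeated" prescriptions.** Undefined in surveillance protocols'
  public descriptions. Default: ≥ 2 matching prescriptions within 365 days
  (`repeat_min_count`, `repeat_window_days`), the weakest reading that
  still excludes single occasional use. The qualifying date is the first
  prescription of the earliest qualifying span, found by a sliding window
  over the person's date-sorted matches (tested against a combinatorial
  brute-force oracle). Two same-day prescriptions qualify; the window is
  closed on both ends.
* **Psychiatric veto scope.** The veto scans the *entire* available
  history, not only the look-back window: the source descriptions state no
  time bound, and a historical schizophrenia label makes the proxy
  interpretation doubtful at any later time.
* **Code lists.** The exact regional lists are not public; the defaults
  (`codebook()`, `inst/extdata/codebook.yaml`) are documented,
  clearly-editable stand-ins: dementia ICD-9 {290, 294.1, 294.2, 331.0,
  331.1, 331.82}, psychiatric ICD-9 {295, 296}, with prefix matching and
  dot-insensitive ICD-9 comparison. All results are conditional on the
  codebook supplied.
* **Membership.** Prevalent = case criteria met by, and alive and resident
  on, Dec 31 of the reference year ("alive" = no death date or death date
  ≥ Dec 31; point-prevalence convention). Age = completed years on Dec 31.
  Cases who died during the reference year are tabulated separately for
  mortality.

## Incidence and the look-back

A case is incident in year *t* if no qualifying record — including a
*single* matching prescription that would not by itself satisfy the
repeated rule, and including proxy prescriptions — exists in calendar
years [*t* − 5, *t* − 1]. The washout is person-level and
disease-agnostic ("no evidence of neurodegenerative disease of either
kind"), so a long-standing parkinsonism patient first showing dementia
evidence in *t* is not an incident case; group-specific new-case counts
are the incident persons restricted to each group. For reference years
close to the study start the look-back is truncated by the available
history, giving early years a shorter washout — their estimates should be
read with that caveat.

## Rate estimation

* Crude rates are 1000·n/P with Wilson score CIs (closed form; the test
  oracle is `prop.test(correct = FALSE)`). The published crude rows are
  reproduced exactly to two decimals from their printed counts.
* The annual-incidence and mortality denominators are the same Dec-31
  resident population as prevalence (not person-years), matching the
  published convention.
* Direct standardization uses the WHO 2000–2025 world standard or the
  Eurostat ESP 2013, shipped as editable CSVs and renormalized over the
  analysis range (40+ or 65+). ESP 2013 defines an open 95+ class
  (weight 200 per 100,000); the 13-class scheme needs separate 95–99 and
  100+ classes, so the weight is split 180/20 — a pragmatic, documented
  split that the user can change in the CSV.
* In `rate_table()`, classes with *no resident population* cannot carry
  standard weight; they are dropped and the standard renormalized over the
  populated classes (with a message). `age_adjusted_rate()` itself keeps
  the strict contract — an empty stratum with positive weight is an error
  naming the class — so silent zero-division can never occur.
* Bootstrap CIs for adjusted rates resample persons with replacement
  (percentile method, B = 5,000 by default, B ≥ 100 enforced). Because the
  person table is (age class × case flag), person resampling is *exactly*
  a multinomial redraw of the contingency cells; the implementation uses
  that equivalence, which turns a ~10-minute coverage simulation into
  seconds without changing the estimator. A class with zero resampled
  population contributes a zero rate to that replicate (it can only happen
  for near-empty classes, where the contribution is negligible). The
  degenerate all-control table returns (0, 0) with a warning; the all-case
  table collapses to (1000, 1000).
* IRRs compare crude incidence rates across years with the Poisson
  log-normal interval exp(ln IRR ± z·√(1/c₂ + 1/c₁)); zero counts are an
  error by design (no continuity correction), matching the published form.
* Display rounding is half-up to 2 decimals on the per-1,000 scale
  (`round_half_up()`; base `round()` is half-even). Internal values are
  never rounded.

## The synthetic world

The generator's defaults state the world the analysis assumes, and are not
tuned to any test outcome:

* age structure of an aging region over 13 five-year classes (shares sum
  to 1, female share rising from 0.49 to 0.72 across classes);
* planted prevalence rising with age — parkinsonism from 0.8‰ (40–44) to a
  ~55‰ plateau around 85–94, dementia from 1.5‰ to ~200‰ — and annual
  incidence gradients shaped the same way;
* 29% dementia comorbidity among parkinsonism cases;
* prevalent onsets uniform over the 10 years before the reference year, so
  the look-back sees evidence on both sides of its window; incident plants
  have onset in the reference year itself;
* detection probabilities per source (p_rx = 0.9, p_hdr = 0.25,
  p_exemption = 0.2) and yearly prescription counts of 2 + Poisson(4), so
  treated case-years always satisfy the repeated rule;
* dementia tracer mix dominated by the proxy drugs (antipsychotics 53.5%,
  trazodone 26.4%, mirtazapine 10.7%, anticholinesterases 4.9%, memantine
  4.7%), so proxy-identified cases dominate as observed in practice;
* 4% proxy-drug confounders among non-cases, half carrying psychiatric
  labels; mortality rising with age, 1.5× in cases; log-uniform
  municipality sizes for realistic small-area variance.

What a green test establishes: with perfect detection and no confounders
the adjudicator returns exactly the planted case set (algorithmic
correctness), the psychiatric veto removes exactly the labelled
confounders, the look-back flips on planted evidence, and the estimators
recover planted rates within binomial error. What it does **not**
establish: real-world sensitivity and specificity. The generator has no
miscoding, no drug switching, no care-disruption years (the pandemic dip
visible in real 2020 data is deliberately not modelled), no migration, and
detection probabilities are illustrative, not calibrated — there is no
public ground truth to calibrate them against.

## Known limitations

* The algorithm cannot subclassify (AD vs non-AD dementia, Parkinson's
  disease vs atypical parkinsonism): the tracer drugs are shared across
  subtypes, and most detections come from prescriptions.
* Proxy-identified cases carry no confirmatory diagnosis; specificity
  rests on the psychiatric veto.
* Municipal rates are mapped raw — no shrinkage or spatial smoothing — so
  small municipalities have unstable rates; conservation of counts, not
  stability, is the guaranteed property.
* Events outside a person's residency interval are retained (real extracts
  are known-dirty; orphan events, by contrast, are dropped and counted).
* CSV is the only container (the environment ships no Parquet reader);
  the schemas are documented in `?read_source`.
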