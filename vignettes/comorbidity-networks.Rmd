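---
title: "Comorbidity networks from general-practice prescriptions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity networks from general-practice prescriptions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comornet)
library(dplyr)
```

## The problem

General practitioners see a far broader slice of a population than hospitals
do, and every prescription they write — a drug, a laboratory test, a referral
— carries an ICD-9-CM diagnosis code. A decade of such general-practitioner
prescription (GPP) records is therefore a standing census of non-acute
morbidity. `comornet` turns these records into *comorbidity networks*:
weighted undirected graphs whose nodes are the 20 ICD-9-CM chapter groups
(CIRC circulatory, META endocrine/metabolic, RESP respiratory, ...) and whose
edges record how often two disease groups were prescribed together. The
package's motivating application is the excess comorbidity burden of
diabetes: diabetic patients (identified from drug prescriptions carrying
codes 250.00–250.99) are compared with non-diabetic patients through
per-patient co-prescription rates and their ratio.

## The network model

Every record's diagnosis code is pooled into its chapter group; the mapping
is the standard one (001–139 INFE, ..., 800–999 INJ, V codes SUPP, E codes
EXT) and sub-codes map with their three-digit stem, so 250.42 is META like
250. A *co-prescription event* is the multiset of groups prescribed to one
patient on one date. From a set of events in a stratum:

* **node weight** $w_g$ — the number of prescriptions carrying group $g$
  (records, not events: three CIRC prescriptions in one visit add 3);
* **link weight** $w_{gh}$ — the number of events in which the distinct
  groups $g$ and $h$ both occur; each unordered pair counts once per event
  and there are no self-loops;
* **strength** $s_g = \sum_h w_{gh}$ — the scalar comorbidity measure of a
  group. Summed over nodes it equals $2\sum_{g<h} w_{gh}$ (handshake
  identity), which the tests verify on random inputs.

To compare strata of different sizes, all weights are divided by the number
of patients contributing at least one record to the stratum
(`normalize_network()`). Per-patient weights are invariant to duplicating
the whole cohort, which is tested to 1e-12.

**Co-occurrence granularity.** "Prescribed together" could mean the same
prescription form, the same visit, or the same patient ever. The package
defaults to the visit — the (patient, date) pair — because visit intervals
(tens of days) make the visit the natural co-prescription occasion, while
whole-history co-occurrence would saturate every link over a ten-year
window. The whole-patient alternative remains available
(`co_events(cooccur = "patient")`) for sensitivity checks.

## Cohorts and strata

Patients are stratified by sex, by prescription type, by decade age class —
half-open intervals $(15,25], (25,35], \ldots, (75,85]$ with $(85,110]$
terminal, upper bound included, age 15 admitted to the first class — and by
diabetes status. Ages below 15 are rejected at validation: in the health
system these records come from, children are seen by pediatricians, not GPs.

Two deliberate choices:

* **Age at prescription, not at entry.** A record is stratified by the
  patient's age on the prescription date, so a patient ageing across the
  window contributes to several age strata and is counted once in each
  stratum's denominator. This keeps per-patient normalization well defined
  within every stratum.
* **Diabetes is a patient-level label.** It is computed once from a
  patient's full history (any Drug prescription with a 250.x code) and
  applied unchanged in every stratum — a label that flipped between strata
  would make D/ND comparisons incoherent. A laboratory test coded 250.x
  does *not* qualify: tests express a diagnostic question, drugs an
  established diagnosis.

`representativeness()` compares a sample's age histogram with a reference
(census-like) distribution, reporting both the squared Pearson correlation
of class percentages and the goodness-of-fit chi-square. The two answer
different questions: profiles can be near-proportional ($r^2 \approx 1$)
while the chi-square is still highly significant at large $n$, since it
detects any fixed relative distortion. Both numbers are reported without
re-interpretation.

## Rate ratios and confidence intervals

Co-prescription counts are treated as Poisson. For an observed count $k$,
the exact (Garwood) 95% interval is used:
$\left[\tfrac{1}{2}\chi^2_{0.025}(2k),\ \tfrac{1}{2}\chi^2_{0.975}(2k+2)\right]$,
computed via gamma quantiles, with lower bound 0 at $k=0$. The exact form is
preferred to the $k \pm 1.96\sqrt{k}$ approximation because per-stratum
counts can be small; the approximation is available behind
`poisson_ci(method = "normal")` for comparison. A Monte-Carlo test checks
nominal coverage at mean 12 over 2,000 draws.

The diabetic/non-diabetic comparison for a group $g$ anchors on META: with
counts $k_D, k_{ND}$ of $g$–META co-prescription events and patient
denominators $n_D, n_{ND}$, the ratio is
$\hat\rho = (k_D/n_D)\,/\,(k_{ND}/n_{ND})$. Its CI uses the standard
conditional construction for a ratio of Poisson rates: given
$k_D + k_{ND}$, $k_D$ is binomial with success probability
$p = \lambda_D/(\lambda_D + \lambda_{ND})$; the Clopper–Pearson interval
for $p$ maps to the ratio scale through $p/(1-p) \cdot n_{ND}/n_D$. When
$k_{ND} = 0$ the ratio is reported as infinite with a finite one-sided
lower bound. This propagates the uncertainty of *both* counts — whether
the error bars of such figures propagate one count or two is usually left
unstated; the conditional construction is the package's documented choice.

`window_years` is an explicit argument wherever per-patient-per-year rates
are computed, never inferred from record dates: published per-patient rates
can imply an *effective* window (here, the bundled reference marginals are
consistent with 11 years) that differs from the calendar span of the
observation window (2002-01-01 to 2013-12-31).

## The synthetic generator

No public GPP dataset exists at this granularity, so the package ships a
generator (`simulate_population()`, `simulate_gpp()`) whose output has
exactly the second-order structure the network stage measures. Its defaults
are anchored to the bundled reference marginals of a real decade of Italian
general practice (`gpp_reference()`): 14,958 patients, 48.4% male, 7.7%
diabetes prevalence, per-group annual base rates equal to the reference
group counts divided by patients and effective years (CIRC 2.75/patient/yr,
META 1.41, ..., summing to 10.5), and each group's prescription-type mix
equal to the reference row mix. Where the source states no value the
defaults are fixed, realistic choices: a census-like adult age structure
(weights 0.12/0.15/0.16/0.16/0.15/0.13/0.09/0.04 over the eight classes)
and an age profile multiplying all rates
(0.45, 0.60, 0.80, 1.00, 1.30, 1.60, 1.80, 1.20) that rises through
$(75,85]$ and dips in the terminal class, emulating the low morbidity of
survivors.

Mechanism, per patient:

1. **Visits.** Inter-visit gaps are uniform in an age-class-dependent range,
   narrowing with age within the 20–70-day envelope for non-diabetics and
   the 17–40-day envelope for diabetics; the range is re-selected from the
   patient's *current* age class as they age across the window.
2. **Diagnoses.** At each visit every group is drawn independently with
   probability (annual rate × age multiplier × diabetic multiplier) /
   (visits per year), and each configured group *pair* is drawn analogously
   from its coupling rate, emitting one record of each group. Because
   per-visit probabilities are annual rates divided by visit frequency,
   expected per-patient counts equal the configured annual rates regardless
   of how often a patient visits — so a coupling enriched 12× for diabetics
   yields a 12× expected per-patient co-prescription rate even though
   diabetics visit nearly twice as often. This linearity is what makes the
   parameter-recovery tests sharp.
3. **Records.** A drawn group emits one record with a representative ICD-9
   code of its chapter and a type drawn from the group's mix. Diabetic
   patients additionally receive, with per-visit probability `refill_prob`
   (default 0.5), a Drug record carrying a 250.x code — the generator's
   model of therapy refills, and the only source of 250.x drug codes, so
   generated non-diabetics are never mislabelled.

Default couplings are the package's own choice: CIRC–META 0.60/patient/yr
plus smaller CIRC–DIGE/MUSC/RESP/GEN and META–DIGE/GEN/RESP terms, with a
12× diabetic multiplier on pairs involving META and 1.5× elsewhere, placing
the diabetic enrichment inside the 10–20× band such cohorts display.

**What the generator does not emulate:** close repeat visits within a few
days (gaps never fall below 17 days), seasonality, mortality and dropout,
pharmacologically meaningful drug codes, and any correlation structure
beyond pairwise couplings. Passing tests therefore demonstrate that the
pipeline measures what the generative model puts in — not that real
primary-care data satisfy the model.

## Numerical and testing choices

* Base-rate and coupling draws are Bernoulli with probability capped at
  0.95; at default rates the cap is never near binding.
* Visit dates are floored to whole days, so observed record-date gaps can
  undershoot the configured minimum by one day; tests allow this slack.
* Groups absent from a stratum are omitted from its network rather than
  kept as zero-weight nodes; empty strata are omitted from curves rather
  than reported as zero.
* Validation rejects rather than repairs: every dropped row is counted by
  reason, and kept + rejected = input is asserted.
* Parameter recovery runs at 5,000 patients × 50 replicates with a
  single-pair model (CIRC–META coupling 0.2/yr, 15× diabetic multiplier,
  a flat age profile, and an ILL base rate of 2/yr so that every patient
  appears in the stratum denominators); qualitative age-curve checks run at
  4,000 patients with 30% prevalence so every class is well populated.
  These sizes give standard errors a few percent wide — small enough that
  the configured enrichment and orderings are sharply testable.

## Limitations

Prescription co-occurrence is not clinical comorbidity: coding practice,
reimbursement rules and diagnostic-question codes (notably on laboratory
tests) all shape the networks. The D/ND ratio conditions on a patient-level
label that is itself derived from the records, so under-treated diabetics
dilute the non-diabetic pool. No multiple-testing adjustment is applied
across groups, matching the descriptive intent of the method; users testing
many group pairs formally should adjust externally.
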