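# blcea

Cost-utility modelling of liquid-biopsy diagnosis for Burkitt Lymphoma in
Tanzania.

Burkitt Lymphoma (BL) is an aggressive childhood cancer and one of the most
common paediatric malignancies in sub-Saharan Africa. Diagnosis currently
requires an invasive tissue biopsy read by scarce histopathology services at
a referral cancer centre, so diagnosis is late, often at an advanced disease
stage, and sometimes wrong. Liquid biopsy — targeted sequencing of
circulating tumour DNA from a blood sample that can be drawn at the
patient's first healthcare contact — promises earlier, more sensitive
diagnosis at a higher unit cost. `blcea` is for health economists and
modellers who want to quantify that trade-off: it implements a full
decision-analytic cost-utility comparison of the two diagnostic strategies
from a Tanzanian provider perspective, with deterministic, probabilistic and
scenario sensitivity analyses.

## The model

Each diagnostic arm expands into a decision tree over true positives
(treated at limited or advanced stage) and false negatives (treated late,
by default at advanced stage; liquid-biopsy false negatives fall back to
the histopathology pathway and pay for both tests). Every branch then runs
a four-state Markov cohort model (`on_treatment` → `post_treatment` →
`post_disease`, plus `dead`) in 3-month cycles with half-cycle correction,
from entry age 10 to an age-100 cap. Mortality during the 24-month
disease-risk window follows a Weibull proportional-hazards model,

S(t | stage) = exp( −exp(β₀ + β_adv·I[advanced]) · t^γ ),  t in months,

with β₀ = −2.702, β_adv = 0.951, γ = 0.500, implying 24-month survival of
72% (limited) and 43% (advanced). Afterwards the cohort faces only
age-specific background mortality from a packaged life table calibrated so
that remaining life expectancy at age 10 is 65 years.

Outcomes are discounted DALYs (YLL at each death = (1 − e^(−rL))/r with
L the remaining life expectancy; YLD from state-specific and background
disability weights). Costs (TZS, discounted at 5%/year) cover diagnosis
(with a number-needed-to-test multiplier of 4 on the liquid-biopsy sample
cost), stage-specific treatment, follow-up, end-of-life care and 20%
overheads. The headline result is the incremental cost-effectiveness
ratio, ICER = ΔCost / ΔDALYs averted, compared against willingness-to-pay
thresholds of $3633, $1211 and $411 per DALY averted.

The package also includes a right-censored maximum-likelihood fitter for
the Weibull model (`fit_weibull_ph()`), a matching synthetic patient-record
generator (`simulate_patients()`), and generators for the calibrated
life-table fixture and an adverse-event cost table stub.

## Worked example

```r
library(blcea)

cfg <- bl_default_config()     # packaged base case
res <- evaluate_cea(cfg)       # both arms + incremental analysis
summary(res)
```

```
Per-arm discounted results (per patient)
       arm   cost_tzs  dalys
    liquid 10,675,518  9.360
 pathology  5,544,565 10.495

Cost components (TZS)
           diagnosis treatment adverse_events followup end_of_life overheads
comparator   5311205   4008351              0   395085       66825    894052
reference     413933   3830314              0   367109       78103    855105

Incremental analysis: liquid vs pathology
  incremental cost:  TZS 5,130,953 ($1,977)
  DALYs averted:     1.134 per patient
  ICER:              TZS 4,523,499 ($1,743) per DALY averted
```

Diagnosing by liquid biopsy costs about $1977 more per patient — almost
entirely the sequencing cost times the NNT multiplier — and averts 1.13
DALYs through the earlier, more accurate diagnosis, giving roughly
$1740 per DALY averted: cost-effective at a 3×GDP threshold ($3633) but
not at 1×GDP ($1211).

Uncertainty and scenarios:

```r
psa <- run_psa(cfg)            # 1000 Monte-Carlo iterations
psa
```

```
Probabilistic sensitivity analysis: 1000 iterations (seed 20260221)
  incremental cost 95% CI:  $1230 to $2787
  DALYs averted 95% CI:     0.07 to 2.70
  CEAC crosses 0.5 at:      $2030 per DALY averted
```

```r
run_scenario(cfg, "nnt", 2)            # 1 BL case per 2 tested
one_way_sa(cfg)                        # tornado table
stage_shift_sweep(cfg)                 # vary earlier-diagnosis stage mix
run_all(out_dir = "results")           # every table + manifest as CSV/JSON
```

Fitting the survival model to (synthetic) right-censored records:

```r
rec <- simulate_patients(500, 34/86, cfg$survival, seed = 42)
fit_weibull_ph(rec)
```

```
Weibull proportional-hazards fit (right-censored MLE)
  n = 500, events = 196, logLik = -809.352
              estimate     se
beta0          -2.7340 0.1684
beta_advanced   0.8521 0.1620
gamma           0.5157 0.0336
```

See `vignette("cost-utility-model")` for the full model description,
parameter provenance, and the reasoning behind the design choices
(overhead treatment, false-negative staging, background-morbidity
accrual, the synthetic life table).

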