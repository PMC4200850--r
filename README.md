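# almanet

Multi-target drug–target–assay link prediction with Markov–Shannon
entropy descriptors and moving-average (Box–Jenkins) operators.

## The problem

Public bioactivity databases report, for each compound *d*<sub>i</sub>,
outcomes of assays run under wildly heterogeneous conditions
*c*<sub>q</sub>: different experimental measures *s*<sub>x</sub>
(K<sub>i</sub>, IC<sub>50</sub>, % inhibition, …), assay protocols
*a*<sub>u</sub>, organisms *o*<sub>t</sub> and molecular or cellular
targets *t*<sub>j</sub>. A single model that predicts the binary link
indicator *L*<sub>ij</sub>(*c*<sub>q</sub>) — whether the compound gives
a strong outcome in that assay context — must therefore be
multi-target, multi-output and multi-scale at once. `almanet`
implements one such model family (ALMA: *Assessing Links with Moving
Averages*) for neuroprotective/neurotoxic compound data, plus the
tripartite drug–target–assay network analysis built on its predictions.

## The model

**Descriptor.** A molecule is a hydrogen-suppressed graph whose atoms
are weighted by Pauling electronegativities χ. A Markov chain on the
atoms steps to a closed-neighborhood member with probability
χ<sub>j</sub> / Σ<sub>l∈N(i)∪{i}</sub> χ<sub>l</sub>. With
⁰p = χ/Σχ and ᵏp = ⁰p·Πᵏ, the order-*k* Markov–Shannon entropy is

  θ<sub>k</sub> = −Σ<sub>j</sub> ᵏp(j) · log₂ ᵏp(j)  (bits, ≤ log₂ n).

The model uses θ₅; orders 0–5 are computed for diagnostics.

**Moving-average features.** For each condition class the active-set
moving average is *p*₁(*c*)·⟨θ₅(*c*)⟩ — activity prior times the mean
descriptor over active compounds of that condition subset. The five
model features are the data-quality term *p*(*c*<sub>l</sub>)·θ₅
(curation level → 1 / 0.75 / 0.5) and four deviation terms
Δθ₅(*c*) = θ₅ − *p*₁(*c*)·⟨θ₅(*c*)⟩.

**Classifier.** A two-class linear discriminant

  *S*<sub>ij</sub>(*c*<sub>q</sub>) = a₀ + a′·p(c_l)·θ₅ +
  Σ a″<sub>c</sub>·Δθ₅(c)

with a logistic score→probability link and links declared at
*p* > 0.5. The package ships the published reference coefficients
(`reference_model()`; intercept 1.139556) and can refit the
discriminant on any endpoint table (`fit_alma_lda()`).

**Networks.** Every positive (or predicted-positive) record contributes
the arcs drug→target, drug→assay, target→assay. Per node the package
reports δ<sub>in</sub>, δ<sub>out</sub>, δ and the first-order
Markov–Shannon entropy Sh₁ of the symmetrized graph.

## Worked example

```r
library(almanet)

g <- build_graph("C#CCN", "propargylamine")
round(markov_profile(g)$entropies, 4)
#> theta0 theta1 theta2 theta3 theta4 theta5
#> 1.9956 1.9870 1.9814 1.9801 1.9796 1.9794
```

Four heavy atoms with unequal electronegativities: the step
distribution is nearly uniform, so θ₅ ≈ 1.98 bits, just under the
log₂ 4 = 2 ceiling. Scoring that compound in a specific assay context
against a condition-statistics table `st` (columns
`condition_class,condition_value,n,n1,p1,mean_theta5,ma_value`):

```r
pred <- predict_table(reference_model(), rec, desc, st)
pred[, c("compound_id", "theta5", "score", "prob", "label_pred")]
#>      compound_id theta5  score   prob label_pred
#> 1 propargylamine  1.979 0.4285 0.6055          1
```

The score 0.43 maps through the logistic link to p = 0.61 > 0.5, so a
link is predicted. Evaluation reproduces published-style Sp/Sn/Ac
blocks from raw counts:

```r
cs <- confusion_from_counts(1092, 290, 412, 4438)
report_table(list("ALMA-entropy" = list(Train = cs)))
#>          model split metric value_percent numerator denominator
#> 1 ALMA-entropy Train     Sp          79.0      1092        1382
#> 2 ALMA-entropy Train     Sn          91.5      4438        4850
#> 3 ALMA-entropy Train     Ac          88.7      5530        6232
```

(Sp is reported on the observed-link row to match the published
layout; pass `labels = "conventional"` for the standard orientation.)

A full synthetic study — generate a CHEMBL-shaped endpoint table with
planted coefficients, refit, evaluate held out, build networks — is
available from R (`generate_endpoints()`, `fit_alma_lda()`,
`confusion_summary()`, `build_predicted()`) or from the shell:

```sh
alma simulate --config sim.yaml --out endpoints.csv \
     --truth truth.json --stats-out stats.csv
alma fit --endpoints endpoints.csv --stats stats.csv --out model.json
alma predict --model model.json --endpoints endpoints.csv \
     --stats stats.csv --out pred.csv
alma evaluate --predictions pred.csv --out report.csv
alma network --predictions pred.csv --out-prefix net
```

See `vignettes/alma-entropy.Rmd` for the model assumptions, the
synthetic-data design and its limitations.

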