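# inhalrisk

Bioaccessibility- and deposition-adjusted inhalation health-risk
assessment for PM2.5-bound heavy metals (Cd, Pb), built for exposure
scientists working on particulate metal pollution around smelting
districts.

Classical inhalation assessments feed the total airborne metal
concentration into the USEPA dose equations and overestimate risk: only
a fraction of inhaled PM2.5 deposits in the pulmonary region (the
deposition fraction, DF), and only a fraction of the deposited metal
dissolves in lung fluid (the bioaccessibility). `inhalrisk` implements
the revised pipeline that corrects for both:

1. **Bioaccessibility** — fluid-specific fractions
   `100 · C_extract / C_total` for artificial lysosomal fluid (ALF,
   acidic) and Gamble's solution (GS, neutral), with the four-level
   classification (low < 15% ≤ intermediate < 30% ≤ high ≤ 50% <
   very high).
2. **Deposition** — regional (head / tracheobronchial / pulmonary)
   fractions per age/sex cohort, from ICRP-66 closed-form fits plus a
   ventilation/FRC scaling rule, or from an override table standing in
   for an external MPPD run.
3. **Exposure** — average daily doses for six assessment
   concentrations (Total, ALF, GS, DF, ALF+DF, GS+DF):

   `ADD (LADD) = C · InhR · EF · ED / (BW · AT_n (AT_c))`

   with EF = 350 day/yr, ED = 6 yr (children) / 26 yr (adults),
   AT_n = ED·365 d, AT_c = 70·365 d.
4. **Risk** — `HQ = ADD/RfD`, `HI = Σ HQ`, `ILCR = LADD · CSF` with the
   standard category thresholds (HI > 1; ILCR 1e-6 / 1e-4).
5. **Monte Carlo** — seeded propagation of respiration-rate uncertainty
   (truncated normal, CV 0.3 by default, 5000 iterations) into
   cumulative-probability and exceedance summaries.

A synthetic filter-sample generator (log-normal concentrations,
beta-distributed extractable fractions, moment-matched to annual
mean ± sd site profiles) makes every stage testable offline, and the
shipped registries reproduce the study area's published dose and risk
tables (see the methods vignette for how they were calibrated and which
published cells are internally rounded).

## Worked example

```r
library(inhalrisk)

conc <- study_conc_summary()          # pooled annual means, ng/m3
risks <- risk_table(dose_table(conc)) # shipped registries and DF table
print(subset(as.data.frame(risks), age_group == "23-30" & sex == "male",
             select = c(variant, hi, ilcr, ilcr_category)), digits = 3)
#>    variant       hi     ilcr ilcr_category
#> 49   Total 0.026766 5.93e-06     potential
#> 50     ALF 0.008748 1.94e-06     potential
#> 51      GS 0.004430 1.18e-06     potential
#> 52      DF 0.003712 8.23e-07          none
#> 53  ALF+DF 0.001213 2.69e-07          none
#> 54   GS+DF 0.000614 1.64e-07          none
```

Reading: for the cohort with the highest cancer risk (23–30-year-old
males), Cd's lifetime cancer risk under the acid-fluid concentration
alone (1.94e-6) sits in the *potential* band, but once both deposition
and bioaccessibility are applied (ALF+DF: 2.69e-7) it drops below the
1e-6 de-minimis line — and every hazard index is far below 1. The full
analysis narrative lives in `analysis/01_simulate.R` …
`analysis/06_monte_carlo.R`, which write their tables under `results/`.

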