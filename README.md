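# teenits

Interrupted time series analysis of social-media engagement and
emotion in teen communities.

## The scientific problem

During a population-level shock such as the COVID-19 pandemic
declaration, do adolescents change how much they engage on social
media and how much negative emotion they express — and do teens with
mental-health concerns respond differently from their peers?

`teenits` packages the analytic pipeline for answering this with
Reddit-like event data from four communities: one general teen
community (`teen`) and three mental-health communities (`depression`,
`anxiety`, `suicidewatch`):

1. **Cohorts by username matching.** Authors active in the teen
   community who ever posted/commented in a mental-health community
   during the study year form the *MH* cohort; the remaining
   teen-community authors form *NMH*. Mental-health-community items
   from authors never seen in the teen community are excluded.
2. **Weekly engagement.** Weeks are epoch-aligned (the only 7-day
   grid whose partial first/last weeks leave exactly 52 complete
   weeks in 2020). Per week and key: unique active participants
   \(P_w\), items \(I_w\), and posting frequency \(I_w / P_w\).
3. **Lexicon emotion scoring.** Each text is cleaned (stopwords,
   contractions, emojis, URLs), tokenized, and scored against a
   word–emotion lexicon: five proportions in \([0,1]\) for anger,
   fear, happiness, sadness, surprise, and the compound
   negative-emotion scale

   `compound = anger + fear − happiness + sadness` (surprise dropped).
4. **Two-group interrupted time series.** With interruption week
   \(T_0\), post indicator \(D_t = 1\{t \ge T_0\}\), post-time
   \(P_t = (t - T_0) D_t\) and group flag \(g\):

   \[ y_{gt} = b_0 + b_1 t + b_2 D_t + b_3 P_t
      + g (b_4 + b_5 t + b_6 D_t + b_7 P_t) + e_{gt} \]

   estimated by OLS with Newey–West (Bartlett-kernel) HAC standard
   errors computed within each group's series, plus an ACF-based lag
   diagnostic.

Because no public accession exists for the original corpus, the
package ships a **synthetic corpus generator** with planted ground
truth (cohort labels, segmented posting intensities, emotion-word
mixtures, per-user activity multipliers), so that every stage of the
pipeline can be validated against known truth.

## Worked example

```r
library(teenits)

cfg <- pipeline_config(out_dir = "run1",
                       sim = sim_config(n_users = 1000, seed = 7),
                       seed = 7)
res <- run_pipeline(cfg)
res$cohorts
#> cohorts: 28 MH / 972 NMH teen-community authors (mh_fraction 0.0280); 0 MH-community-only authors excluded
print(res$fits$frequency)
#> Two-group interrupted time series fit
#>   groups: NMH vs MH  (reference: NMH )
#>   n = 104  interruption week = 11  Newey-West lag = 12
#>
#>  Parameter      b Approx. SE t Value Pr > |t|
#>         b0  5.091      0.018  281.02   <1e-04
#>         b1 -0.036      0.003  -13.41   <1e-04
#>         b2  0.775      0.024   32.14   <1e-04
#>         b3  0.039      0.003   15.35   <1e-04
#>         b4  5.502      0.162   33.95   <1e-04
#>         b5 -0.159      0.028   -5.64   <1e-04
#>         b6  1.775      0.223    7.96   <1e-04
#>         b7  0.141      0.028    5.06   <1e-04
#>
#> R-square = 0.966
```

Reading the output: the NMH cohort starts near 5.09 posts/comments
per participant-week (`b0`; the planted level is 4.948 before the
active-participant correction) and declines per week (`b1 < 0`).
At the interruption (week 11) its level jumps by ~0.78 (`b2`) and the
trend reverses (`b3 > 0`). The MH cohort posts about twice as often
(`b4`), declines faster pre-interruption (`b5 < 0`), and accelerates
faster afterwards (`b7 > 0`) — exactly the planted structure (the MH
contrasts are noisy at 28 MH users; the default 5000-user corpus
pins them down).
`run1/` then contains the weekly series CSVs, two ITSA JSON
summaries, the fit/summary tables and the five standard figures.

Reported week-to-week comparisons use the same helper as the tests:

```r
percent_change(4.56, 6.15)
#> 35% increase
```

## Command line

```sh
Rscript -e 'teenits::teenits_cli()' simulate --seed 1 --out simdir
Rscript -e 'teenits::teenits_cli()' run-all  --seed 1 --out rundir
```

(Subcommands: `simulate`, `score`, `aggregate`, `itsa`, `run-all`;
an executable wrapper ships in `inst/cli/teenits`.)

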