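---
title: "Methods: segmented regression of weekly engagement and emotion with a synthetic Reddit-like corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(teenits)
```

# Overview

`teenits` implements a four-stage pipeline for studying how an abrupt
population-level event changes posting behaviour and expressed emotion
in online teen communities, comparing users with and without
mental-health (MH) concerns. Because the original platform data carry
no accession, a synthetic corpus generator with planted ground truth is
a first-class part of the package: it defines exactly what a green test
establishes, and what it does not.

# The model

For cohort $g \in \{0 = \mathrm{NMH}, 1 = \mathrm{MH}\}$ and week
$t = 1, \dots, 52$, with interruption week $T_0$, post indicator
$D_t = 1\{t \ge T_0\}$ and post-time $P_t = (t - T_0) D_t$:

$$ y_{gt} = b_0 + b_1 t + b_2 D_t + b_3 P_t +
   g\,(b_4 + b_5 t + b_6 D_t + b_7 P_t) + e_{gt}. $$

Both groups are stacked into a single OLS fit (`fit_itsa()`), which
matches the usual multi-group segmented-regression parameterization:
$b_0, b_1$ are the reference group's pre-period level and slope,
$b_2, b_3$ its level and slope change at the interruption, and
$b_4$–$b_7$ the group differences in those four quantities.

**Post-time origin.** $P_{T_0} = 0$, so $b_2$ is the level change *at*
the interruption week itself. This is the most common segmented
convention; the alternative ($P_{T_0} = 1$) only relabels $b_2$ by
$b_3$.

**Standard errors.** `newey_west_cov()` computes the Bartlett-kernel
HAC sandwich $(X'X)^{-1} M (X'X)^{-1}$ with
$M = \sum_t e_t^2 x_t x_t' + \sum_{l=1}^{L} w_l \sum_t e_t e_{t-l}
(x_t x_{t-l}' + x_{t-l} x_t')$, $w_l = 1 - l/(L+1)$. Lagged products
are taken strictly within each group's own time-ordered series — the
stacked design must never difference residuals across the group
boundary. A small-sample factor $n/(n-k)$ is applied (toggleable).
P-values use a Student-$t$ with $n - 8$ degrees of freedom over the
stacked rows.

**Lag choice.** `select_lag()` reports residual autocorrelations per
group with $\pm z_{1-\alpha/2}/\sqrt{n}$ bounds and suggests the
largest significant lag. It is a transparent diagnostic; $L$ remains a
user decision (the analysis profile default is $L = 12$ for a 52-week
series with strong autocorrelation).

# Emotion scoring

Texts (title and body joined by one space; comments have empty titles)
are lowercased; URLs stripped; emojis mapped to words; contractions
and common shortcuts expanded token-wise; stopwords and
non-alphabetic tokens removed. Each remaining token is looked up in a
word→emotion lexicon over {anger, fear, happiness, sadness, surprise};
each emotion's score is its hit count divided by the *total
post-cleaning token count*, so the five scores are jointly bounded by
1 and unlisted tokens dilute all five equally. The compound
negative-emotion scale is $anger + fear - happiness + sadness$
(surprise is dropped as valence-ambiguous; happiness is
reverse-coded via the minus sign). Empty-after-cleaning texts score
zero, are flagged, and stay in weekly means — no exclusion rule is
defensible without ground truth about why a text emptied.

The bundled lexicon is a small curated list assembled for this
package; the original third-party tool's dictionary is not available.
Absolute score levels therefore depend on the lexicon and are not
comparable across lexica — which is why the acceptance tests validate
scoring against *planted mixtures*, never against any published
absolute emotion value.

# Week convention

Weeks are aligned to the Unix epoch week (a 7-day grid in which a week
boundary falls on 1 January 1970, a Thursday), and only weeks lying
entirely inside the study year are kept. A 366-day year splits into 52
complete weeks plus two partial ones only when each partial week holds
a single day, which for 2020 happens exactly on this Thursday-aligned
grid; Monday- or Sunday-start weeks leave 51 complete weeks. The
epoch-aligned grid is also what timestamp-bucket arithmetic
(`floor(ts/604800)`) produces, making it the natural convention for
epoch-seconds data.

# The synthetic world

`sim_config()` defaults state the world the analysis targets:

* `n_users = 5000`, `fraction_mh = 0.035` — the cross-community
  overlap rate of the study population.
* 52 complete weeks of 2020, interruption at week 11.
* Weekly posting intensities per stream follow the segmented trend
  with the published coefficient table as planted parameters:
  NMH-teen `(4.948, -0.028, 0.741, 0.032)`; MH-teen is the sum of
  base and contrast columns `(9.832, -0.160, 2.253, 0.146)`; the
  MH-forum stream `(3.0, 0, 0.3, 0.01)` reflects the reported 2.5–3.7
  posts/participant range of the mental-health communities.
* Per-user activity multipliers are Gamma with mean 1 and variance
  0.125 (`user_heterogeneity`), giving negative-binomial weekly counts
  marginally — posting behaviour is overdispersed, but closed-form
  means survive for tests. The paper states nothing about per-user
  dispersion; 0.125 (CV ≈ 0.35) is a modest, realistic choice made
  once.
* Emotion-word mixtures per stream are chosen so the planted compound
  equals the published levels: 0.231 (teen/NMH), 0.265 (teen/MH,
  i.e. +0.034), and 0.45/0.48/0.47 for the three MH communities
  (reported range 0.37–0.58). Mixtures are static in time: emotion
  trends in Table-2 style are exercised through direct noiseless and
  noisy series, not through the corpus.
* Text bodies are 5–30 token bags-of-words; 90% of items are comments
  (the general community's post:comment ratio is ≈1:9). Tokens are
  drawn class-first (emotion vs neutral) then uniformly within class,
  with no stopwords emitted, so the scorer is exactly unbiased for the
  mixture.
* Timestamps are uniform within complete weeks; MH users are
  guaranteed at least one forum item so the planted cohort is
  identifiable from the data, as the ledger asserts it is.

**What a green test establishes.** Recovery tests condition on the
generated roster: the expected weekly posting frequency of cohort $c$
is $\lambda_w \sum_i m_i / \sum_i (1 - e^{-m_i \lambda_w})$
(`planted_frequency_path()`), whose regression on the design gives the
effective planted coefficients. Green means the pipeline — filtering,
week assignment, cohort matching, counting, ratio construction,
fitting — reproduces that closed form. It does not establish realism
of Reddit threading, diurnal rhythm, topic drift, author churn, or
lexicon validity on natural language.

# Numerical and statistical choices

* **Denominator convention** (post-cleaning token count) is recorded
  in scoring metadata.
* **Weekly emotion means average over items**, not authors; the
  source analysis is silent and item-weighting matches per-item
  scoring.
* **Zero-SST responses** define $R^2 = 0$; rank-deficient designs are
  an error naming the collinear columns; missing weekly values are
  rejected, never imputed.
* **Percent changes** are `round(100 * (v2 - v1) / v1)` with
  half-away-from-zero rounding, declines reported as positive decline
  magnitudes — the reporting style of the source.
* **Heteroskedastic recovery intervals.** The MH cohort is ~27×
  smaller than NMH, so cohort-level weekly noise differs by an order
  of magnitude; recovery tests therefore use group-wise residual
  variances in the OLS sandwich rather than the pooled classical
  estimator, which would over-cover the reference block and
  under-cover the contrasts.

# Known limitations

* **HAC coverage at short lengths.** Bartlett HAC intervals for the
  pre-slope $b_1$ in this 8-column design undercover severely at the
  52-week scale (empirically ≈ 0.43 at $L = 12$, ≈ 0.82 even with iid
  noise at $L = 0$, due to truncation bias plus the high-leverage
  early-interruption layout), and approach nominal slowly: ≈ 0.92–0.94
  by 2000 weeks/group. The coverage tests therefore run in the
  $n \gg L$ regime (800–2000 points) and the vignette flags that
  published 52-week HAC t-statistics should be read as optimistic.
  This mirrors the known fixed-$b$ critique of HAC inference; the
  implementation itself agrees with standard references to 10⁻⁸.
* **Sign power at published noise.** With iid noise calibrated to the
  published $R^2$ (0.855), the sign of the reference slope change
  ($b_3 = 0.032$) is recovered in only ≈ 65–77% of refits — the
  published effect is not large relative to honestly-estimated
  sampling noise at 52 weeks. The power test instead derives its
  noise from the default 5000-user synthetic world, where both
  interruption contrasts are essentially always detected.
* The generator does not model reply structure, karma, diurnal or
  seasonal rhythm, author churn, or time-varying emotion mixtures;
  natural-language effects (negation, sarcasm, context) are outside
  the lexicon scorer by design.
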