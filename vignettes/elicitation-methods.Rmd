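---
title: "Simulating and analyzing health-state preference elicitation for breast reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing health-state preference elicitation for breast reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health utilities place every health state on a cardinal scale from 0 (death)
to 1 (perfect health), which makes treatment options comparable in
cost--utility terms. For women deciding among tissue-based reconstruction,
implant-based reconstruction, or no reconstruction after total mastectomy,
three instruments are in standard use: ranking outcome cards from most to
least preferred, placing them on a 0--100 visual analog scale (VAS,
"feeling thermometer"), and the standard gamble, in which the respondent
chooses between the certainty of an intermediate outcome and a lottery over
a better and a worse one.

Interview data of this kind are small (tens of participants) and rarely
public. `reconpref` therefore pairs the complete analysis pipeline with a
generative model of the interview itself, so that every stage — titration,
chained composition, ranking, rating, summary statistics, nonparametric
comparisons, and covariate regressions — can be exercised, validated, and
power-analyzed on synthetic cohorts with known ground truth.

## The chained standard gamble

A respondent with latent utilities $u(s)$ faces a deck of nine outcome
cards: four implant qualities (excellent, good, fair, poor), four tissue
qualities, and no reconstruction. The interview proceeds in two stages:

1. **Stage 1.** Each of the seven intermediate states is offered against a
   lottery between the respondent's most and least preferred states. The
   probability of the best outcome starts at 1.00 and falls in fixed
   decrements (default 0.05) until the respondent first takes the
   certainty; the indifference probability $P_{1i}$ is the midpoint of the
   bracketing interval.
2. **Stage 2.** The least preferred state is offered against a lottery
   between the most preferred state and death, yielding $P_2$.

With $u(\text{best}) \equiv 1$ and $u(\text{death}) \equiv 0$, the two
stages compose to a death-anchored utility

$$u(\text{outcome}_i) = P_{1i} + (1 - P_{1i})\,P_2,$$

which is `chain_utility()`. The composition is exact algebra: substituting
$u(\text{worst}) = P_2$ into the stage-1 expected-utility identity
$u_i = P_{1i}\,u(\text{best}) + (1 - P_{1i})\,u(\text{worst})$ gives the
combined formula, and in the small-step limit the composed utility
converges to $u_i / u(\text{best})$.

### The respondent model

Human choices are simulated by a stochastic expected-utility respondent.
An offer with best-outcome probability $p$ is accepted (the gamble chosen)
when

$$w(p)\,u(\text{best}) + (1 - w(p))\,u(\text{worst}) > u(\text{certain}),$$

where $w$ is a one-parameter inverse-S probability-weighting function
(`weighting_gamma = 1`, the default, is the identity and gives the
expected-utility respondent the composition formula assumes). Exact
indifference resolves to the certainty, which makes the noiseless switch
point deterministic. Under positive `choice_noise` $\tau$ the choice is
logistic in the expected-utility difference with temperature $\tau$;
$\tau = 0.005$ by default, small relative to the utility differences in
the deck, so reversals are rare but present.

### Numerical behavior of the titration

* The noiseless indifference estimate is within half a step of the true
  relative utility; the package verifies $|P_1 - v| \le s/2$ by brute
  force over a grid of $v$ and step sizes.
* A respondent who takes the certainty at the very first offer (the
  certain state is at least as good as the best lottery arm) is flagged
  *degenerate-high* and assigned $1 - s/2$; one who never switches even at
  $p = 0$ is flagged *degenerate-low* and assigned $s/2$. Degenerate
  traces are kept and flagged, never dropped — exclusion policy belongs to
  the analysis stage.
* **Resolution limit.** States whose relative utilities differ by less
  than one step land in the same bracket and elicit tied utilities. Rank
  agreement between the gamble and the finer-grained instruments is
  therefore perfect only for profiles whose utility gaps exceed the step;
  cohorts with compressed (equipoise) or ceiling-compressed profiles
  genuinely lose rank resolution in the gamble. This is a property of the
  instrument, not an artifact.
* Chained and direct death-anchored titrations agree within one step in
  the regime this population occupies. A deterministic scan over the
  quantization lattice shows the worst-case discrepancy is 0.048 (below
  the 0.05 step) whenever the anchor ratio
  $u(\text{worst})/u(\text{best})$ is at least 0.65; synthetic cohorts sit
  above 0.65 in more than 99% of profiles. For hypothetical low-utility
  anchors the discrepancy can reach about 0.07.

## The synthetic cohort generator

### Covariates

Covariates are drawn per participant from the distributions reported for
the study population: age 51.65 ± 11.66 y (range 27--68), 30/40/30%
normal/overweight/obese, 40/60% unilateral/bilateral, ASI-R subscales on
1--5 and BREAST-Q scores on 0--100 with their published means, SDs, and
ranges. Continuous covariates are censored normals clipped at the reported
min/max; because censoring shifts the mean (about −0.34 y for age), the
generator solves for the pre-clip location whose *censored* mean equals
the configured mean, so the configured mean is the target moment of the
delivered distribution. Covariates default to mutual independence (no
correlations are reported); the ASI-R total is drawn as its own censored
normal so that its marginal matches the reported 3.28 ± 0.59, at the cost
of not being exactly the mean of its subscales — under independence the
subscale mean would have SD ≈ 0.40, understating the reported spread.

Every random draw derives from `(rng_seed, participant_id, operation)`,
one stream per participant and instrument, so cohorts are bit-stable under
reordering and subsetting and two runs with the same seed are
byte-identical.

### Latent utilities

Each participant's latent utility for a state is

$$u_{js} = b_s + \sum_k \beta_{k,g(s)}\,\tilde{x}_{jk}/100 + \varepsilon_{js},$$

with base values $b_s$ set to the published median standard-gamble
utilities (implant 0.99/0.96/0.94, tissue 0.97/0.95/0.94/0.92, no
reconstruction 0.86; the implant-poor default is 0.93, one
printed-precision step below implant-fair, so the within-modality ordering
excellent > good > fair > poor is strict at zero noise). Covariate effects
$\beta$ are configured in VAS points and divided by 100 to act on the
latent scale; continuous covariates enter centered at their configured
means. The defaults encode the published multivariable coefficients for
the without-death VAS models: BREAST-Q breast +0.46/point on implant
states, BREAST-Q outcome −0.25/point on no reconstruction, obesity −16.15
on implant and +10.59 on tissue states, and ASI-R behavior +4.20 and
self-evaluation −6.96 per point on all reconstruction states. Those
coefficients come from four separately fitted models and cannot all hold
at once under an additive state-level scheme — the pooled "any
reconstruction" coefficient is then forced to be the implant/tissue
average — so the defaults reproduce the modality-specific cells exactly
and imply a pooled BREAST-Q coefficient of 0.23 rather than the printed
0.29.

The per-state noise SD defaults to 0.005 on the latent scale. The deck
spans only ~0.13 latent units, so noise much larger than the 0.01--0.02
quality gaps does not add realism — it destroys the quality ordering
entirely.

Utilities are floored at 0 and passed through a strictly increasing soft
ceiling above 0.99 (`1 - 0.01·exp(-(x-0.99)/0.01)`), so ceiling effects
compress preferences toward 1 instead of piling several states into an
exact tie at 1; at most the single best state can sit at 1. The *unclipped*
linear index is kept alongside the bounded utilities (`latent_index`) as
the generating truth for recovery analyses (below).

### Special response behaviors

Two documented behaviors get explicit mechanisms:

* **Equipoise** (default prevalence 0.25): the non-excellent utilities are
  compressed toward their mean (residual spread factor 0.2), emulating
  participants who prefer the excellent options and value the rest almost
  equally.
* **Unexpected rankings** (`unexpected_rank_fraction`): a random fair or
  poor state is promoted into the participant's top three by swapping
  utility values — a transposition that always violates at least one
  within-modality quality ordering and always triggers the top-3/bottom-3
  flag, so the flagged fraction tracks the configured fraction exactly
  when other flag sources are disabled.

A point worth understanding before tuning these dials: with the default
covariate effects, *most unexpected rankings are emergent*, not injected.
Obesity separates the implant and tissue blocks by ~0.27 latent units,
which places tissue-fair in the top three of every obese participant's
ranking; high BREAST-Q scores push implant states into the ceiling region.
Effects alone make roughly half of all rankings "unexpected" (a fair/poor
state in the top 3 or an excellent state in the bottom 3), and any noise
adds more. The default `unexpected_rank_fraction` is therefore small
(0.05), covering idiosyncratic preference only, and a default cohort shows
roughly two-thirds unexpected rankings — above the reported 45%, which is
not jointly attainable with the published effect magnitudes on this
compressed latent scale. The flag-fraction invariant is validated with
effects disabled, where the dial is the only flag source.

## The instruments

**Ranking** orders the deck by latent utility perturbed by rating noise;
values tying within `tie_epsilon` share midranks.

**VAS rating** min--max rescales the noisy latent utilities over the
presented card set to 0--100 and snaps to a 2.5-point grid (quarter-point
medians in the published tables suggest such a grid; configurable among
0/0.5/1/2.5/5). Without the death card, the respondent's best and worst
cards anchor at exactly 100 and 0 — the anchoring behavior every study
participant showed. With the death card in the rescaling set, the
reconstruction states compress toward 100, reproducing the documented
clustering. If all perturbed utilities are equal the instrument returns 50
for every card rather than dividing by zero. Rating noise is specified in
points of the death-anchored 0--100 scale (default SD 0.5).

**A consequence of anchoring worth stating plainly:** the per-participant
min--max rescaling makes the without-death VAS rating a *participant-specific*
affine transform of latent utility. A covariate that shifts a whole block
of states (including the participant's own best or worst state) largely
cancels out of the rescaled rating, so regressing `vas_rate()` output on
covariates does **not** recover the generating coefficients — by design,
since the anchoring is exactly what the real instrument does. Recovery
analyses therefore regress group scores of the unclipped latent index
(×100, the scale on which effects are configured), where the linear
estimand is intact. This is also why the bundled recovery experiments
report effects on that scale.

## The analysis pipeline

* **Summary table.** Per participant, each (option-group × quality) cell
  score is the mean of the cell's states — "any reconstruction" pools all
  eight reconstruction states — with the within-participant aggregator
  configurable (mean or median). Cells are summarized across participants
  by median and IQR (quartile type 7); a participant missing any state of
  a cell is excluded listwise from that cell, and empty cells are reported
  as missing, never zero. Exclusion counts are logged per instrument.
* **Spearman** correlations (midranks for ties) relate rankings, ratings,
  and utilities; constant vectors are reported as missing with a warning.
  Exact two-sided p-values at small n match full-permutation enumeration.
* **Wilcoxon signed-rank** contrasts (reconstruction vs none, implant vs
  tissue) drop zero differences, use the exact null up to 25 nonzero
  differences without ties, and the normal approximation with continuity
  correction beyond; an all-zero contrast is degenerate with p = 1.
* **Kruskal--Wallis** compares ratings across BMI categories. The p-value
  is the chi-square approximation (as in standard software); at n = 8 it
  can deviate from the exact permutation p by up to about 0.11 in the
  mid-range, which is the documented approximation error the validation
  suite tests against. The two-group case collapses exactly to the
  Mann-Whitney normal approximation without continuity correction.
* **Regressions.** For each of three instruments (VAS without death, VAS
  with death, gamble utility) and four option groups, candidate covariates
  are screened univariately (single-covariate linear models, joint F test
  for factors, retained at p < 0.2; zero-variance candidates excluded with
  a warning), then backward-selected by AIC: repeatedly remove the single
  covariate whose removal most reduces AIC, stop when none does, ties
  broken toward the larger F-test p-value, perfectly collinear covariates
  dropped (largest univariate p first) before selection. Coefficients are
  reported with Wald-type t-based 95% intervals. P-values are unadjusted
  for multiplicity, matching the per-test two-sided 0.05 convention of
  this literature; `adjust_test_results()` applies a Holm correction when
  one is wanted.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle: the
titration against closed-form relative utilities on a grid (1,000 random
profiles per step), the chained composition against direct death-anchored
titration (500 noiseless generator profiles), rank tests against
exhaustive permutation/sign-flip enumeration at n ≤ 8, the univariate
screen against its nominal 20% null retention rate (1,000 replicates at
n = 500), and the full screen-plus-backward-AIC pipeline against the
generating coefficients (200 replicates at n = 2,000, where every nonzero
effect is retained in well over 90% of replicates and interval coverage
sits at the nominal 95%). Cohort sizes in the bundled experiments (40 for
study-scale runs, 2,000--4,000 for calibration runs) were chosen so each
check has the power it needs while a full run stays comfortable on a
laptop.

## What the synthetic cohort does and does not show

The generator reproduces the *structure* the analysis assumes — covariate
marginals, a latent utility scale with known covariate effects, anchoring
and compression behaviors, titration quantization — with known ground
truth. Passing tests demonstrate that the machinery is correct and that
the pipeline recovers what the generator put in. They do not demonstrate
anything about real patients: the study's raw interview records are not
public, its printed medians and coefficients derive from 40 real
interviews, and no synthetic cohort can validate those numbers. Further
modeling simplifications to keep in mind:

* one latent scale drives all three instruments; real rating and gambling
  may engage different constructs (the published VAS-vs-gamble contrasts
  are significant for most rows);
* covariates are independent by default; psychosocial scales correlate in
  reality;
* the probability-weighting parameter defaults to 1 (pure expected
  utility); risk-attitude distortions are available but unvalidated;
* interview-order effects (ranking before rating before gamble, without
  death before with death) and fatigue are not modeled;
* the "unexpected ranking" mechanism is one of many that could produce
  the reported behavior; the promotion transposition is a modeling choice,
  not an observed process.
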