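---
title: "Separating correlated responses to selection from genetic drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating correlated responses to selection from genetic drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linedrift)
```

## The problem

Artificial-selection experiments keep two closed lines: one bred for an
index trait (for example, home-cage locomotor activity in mice) and one
bred at random as a control. When a *secondary* trait — operant
impulsivity, maze exploration, motor coordination — differs between the
lines, two explanations compete. The difference may be a **correlated
response**: the secondary trait shares genetic basis with the selected
trait, so selection dragged it along. Or it may be **genetic drift**: two
reproductively isolated populations of modest size will diverge in any
heritable trait by chance alone, and the divergence grows with the
inbreeding that accumulates in each line.

`linedrift` implements the test that separates the two, together with
everything needed to feed and verify it: conversion of published group
summaries into standardized divergences, pedigree inbreeding
coefficients, scoring of the behavioral endpoints that typically enter
such tables (Go/No-go operant sessions, Y-maze spontaneous alternation,
accelerating rotarod), and a breeding simulator used to check the test's
statistical calibration.

## The statistic and the drift interval

For each trait the selected ("High-Active") and control lines are
summarized by a mean, an SEM and a group size. The standardized
divergence is

$$D_y = \frac{\bar{x}_{\mathrm{sel}} - \bar{x}_{\mathrm{ctl}}}{s_p},$$

with $s_p$ the degrees-of-freedom-weighted pooled standard deviation
(each group SD recovered as $\mathrm{SEM}\sqrt{n}$). Pooling with df
weights, rather than using the control SD alone or an unweighted
average, is a deliberate choice: it is the convention behind Cohen's
*d*, it behaves sensibly for unequal group sizes, and it reproduces the
standardized divergences printed in the selection-experiment literature
this package was built around. The sign of $D_y$ is kept, so a trait
lower in the selected line is negative.

Under pure drift, $D_y$ for a neutral trait is expected to fall inside

$$\pm\,z_{1-\alpha/2}\,\sqrt{2\left(2 F h^2 + \frac{2}{n}\right)},$$

where $F$ is the pedigree inbreeding coefficient of the colony (a
dimensionless probability in $[0,1)$), $h^2$ the trait's narrow-sense
heritability taken from the literature, and $n$ the number of families
represented in the measurement. We read the variance model as per-line
drift variance $2Fh^2$ (the classic between-replicate-line variance of a
standardized genetic mean) plus per-line family-sampling variance $2/n$,
doubled because two independent lines are differenced. The closed form
is reverse-engineered: the studies that use this test cite it without
printing the formula, and this expression is the one that reproduces
every published interval we could check to the printed precision. Users
should treat it as a documented model choice, and the calibration
machinery below exists precisely so the choice can be audited.

A trait *exceeds drift* when $|D_y|$ is larger than the half-width. Three
numerical decisions matter:

* the quantile is normal ($z_{0.975} = 1.96$ at the default
  $\alpha = 0.05$), not a *t* quantile — the drift variance is a model
  quantity, not an estimate with sampling degrees of freedom;
* the exceeds comparison uses full precision; rounding to two decimals
  happens only in the report writers;
* no multiple-testing correction is applied across rows, matching field
  practice for these tables; `alpha` is exposed if a user wants
  otherwise.

Traits without a literature $h^2$ (or without a family count) cannot be
tested; they are carried through reports as dashes rather than dropped,
and `evaluate_trait()` marks them `testable = FALSE`. We deliberately do
*not* auto-drop rows whose line comparison is non-significant: published
tables occasionally test traits with borderline p-values, so filtering
is left to the user.

## Pedigree inbreeding

`inbreeding_coefficients()` computes exact pedigree $F$ — the
probability that an individual's two alleles at a locus are identical by
descent, equal to half the additive relationship of its parents — with
the Meuwissen–Luo algorithm in compiled code, incremental over an
append-only pedigree so that the simulator can track $F$ generation by
generation cheaply. Unknown parents are treated as unrelated, non-inbred
founders. The test suite holds the implementation to the brute-force
tabular relationship-matrix method, an independent oracle kept in the
test helpers, on random pedigrees up to 200 individuals, and to Wright's
path-counting results (full-sib offspring $F = 0.25$, half-sib
$F = 0.125$).

The colony-level $F$ that enters the drift test is the mean individual
$F$ of a generation within (or across) lines, `mean_line_F()`. For a real
colony the value is usually supplied directly from the breeding records;
the pedigree module exists so that simulated and user-supplied pedigrees
get the same treatment.

## Behavioral scoring

The operant endpoints are computed from time-stamped event logs with a
fixed trial grammar: a variable precue period (house light on), a cue
(go or no-go), a reward period after correct responses, and a darkened
intertrial interval. Where the field's verbal definitions overlap, we
resolved them as follows, and these are contracts of the scorer:

* the response window is the cue window itself: the first cue-recess
  poke between cue onset and cue offset is the response (hit on go,
  false alarm on no-go); pokes after cue offset are never responses;
* response latency is poke time minus cue onset, averaged over responded
  trials only — unanswered trials contribute nothing rather than an
  imputed ceiling;
* a poke belongs to exactly one category, decided by time-window
  priority: cue-window response, then precue response (cue-recess pokes
  in the final 3 s of a precue period), then cue-side poke (cue-recess
  pokes at any other non-cue time). Center-recess pokes count only
  toward the poke total;
* reinforcers = hits + correct rejections, and efficiency is the raw
  percentage `100 * reinforcers / total_pokes`, uncapped — withholding
  correctly earns reward without a poke, so values above 100 are
  legitimate; with zero pokes efficiency is `NA`, never 0;
* the precue clock is not reset by precue pokes (no reset rule is part
  of the task definition we target), and precue durations default to
  {3, 4.5, 6} s in the generator.

Training progression uses the standard gate (at least 30 hits in under
40 minutes on two consecutive days, `evaluate_training()`), and
`apply_exclusions()` implements the reward-collection exclusion: any
session with earned but uncollected reinforcers excludes the animal.

Y-maze spontaneous alternation counts entry triplets into three distinct
arms over a sliding window, with percent alternation out of
`entries - 2` (the field convention for the denominator). Rotarod days
are summarized as mean and maximum of the four daily trials; trials
below a slip threshold (default 5 s — the protocols we target mention
slip retrials without quantifying "rapid", so the threshold is exposed)
are replaced by the supplied extra trial when one exists.

## The breeding simulator

`simulate_breeding()` is a forward simulator under the infinitesimal
model: breeding values are multivariate normal across traits with
additive variances $h^2_j V_{P,j}$ and a configurable genetic
correlation matrix; offspring receive the midparent value plus a
Mendelian sampling deviation with covariance
$\tfrac12 \Sigma_A (1 - (F_s + F_d)/2)$, so segregation variance shrinks
as parents inbreed; environmental deviations are independent across
traits by default (the correlation matrix is exposed). There are no
explicit loci: the colonies this emulates are outbred, polygenic
populations, and founder haplotype structure from the original
multi-strain cross is approximated as an outbred pool with the specified
variances.

Each line is closed. The selected line breeds by within-family selection
(the best male and best female of each litter on the selected trait,
ties broken by seeded randomness), mass selection, or random choice; the
control line always breeds at random within families. Matings pair the
chosen sires and dams across families, rejecting sibling pairs; litters
alternate offspring sexes so every family can contribute a breeder of
each sex (litter-size variation is not modeled). The pedigree is
recorded throughout and realized $F$ is computed from it exactly, which
is what the calibration feeds back into the drift interval.

Two classical checks pin the simulator to quantitative-genetic theory in
the test suite: one generation of mass selection recovers the breeder's
equation $R = h^2 S$ within Monte-Carlo error, and random within-family
breeding accrues inbreeding at roughly $1/(8n)$ per generation — half
the mass-breeding rate, which is the point of within-family designs.

For measurement, `generate_trait_table()` summarizes the final
generation with, by default, **one measured individual per family per
line**. This mirrors the design of the experiments this package
emulates, where measured cohorts are drawn from distinct families so the
group size is approximately the family count; it also makes the `2/n`
family-sampling term of the drift interval meaningful. The default is a
design statement, not a tuning knob.

## Calibration: what it shows and what it cannot

`run_calibration()` repeats the entire experiment in silico — breeding,
pedigree, measurement, drift test — and reports how often a
*genetically uncorrelated* trait exceeds the drift interval. At the
emulated study scale (10 families per line, 8 pups per litter, 16
generations, $h^2 = 0.33$, one measured animal per family) the null
exceedance over 2,000 replicates lands near the nominal 5% (slightly
conservative in our runs), and power rises steeply with the genetic
correlation between the tested and selected traits, approaching 1 at
$r_g = 0.9$. The acceptance tests run exactly this: 2,000 null
replicates plus 400 replicates at each of $r_g \in \{0, 0.3, 0.6, 0.9\}$,
a few minutes of compute; these sizes were chosen to keep Monte-Carlo
error near half a percentage point on the null rate.

Passing calibration shows that the reverse-engineered interval is honest
*under the generator's assumptions*: infinitesimal inheritance, normal
environments, equal family contributions, no shared-litter environment,
measurement of one animal per family. Real colonies violate several of
these (maternal effects, litter covariance, unequal family success,
selective dropout through training exclusions), and the calibration says
nothing about those violations. It also cannot validate the literature
$h^2$ values a user supplies — the test is only as good as its inputs.

## Known limitations

* The drift-interval formula is a reconstruction validated against
  printed values and simulation, not a derivation from the originating
  sources; alternative readings of the $2/n$ term (e.g. individual
  rather than family sampling) are not distinguishable from the
  published numbers alone.
* $h^2$ is always supplied, never estimated; there is no animal-model
  machinery here.
* Standardized divergences computed from printed summaries inherit the
  rounding of those summaries; we quote agreement to about one decimal.
* The simulator does not model dominance, epistasis, explicit genomes,
  maternal or litter environmental effects, or drug-response dynamics.
* Event-log scoring assumes the session grammar described above;
  hardware logs with different period semantics need mapping into it
  first (the format validators in `validate_formats()` catch structural
  problems, not semantic ones).
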