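---
title: "Auditing adverse-event synthesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing adverse-event synthesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmsynth)
```

## The problem

Two systematic reviews can pool the same body of trials, agree closely on
a treatment's benefit, and still reach opposite conclusions about its
harms. The motivating case is intraarticular hyaluronic acid (HA) for
knee osteoarthritis: reviews agree that HA gives a small function benefit
(a pooled standardized mean difference around −0.2 to −0.3), yet one
review's pooled serious-adverse-event (SAE) risk ratio was statistically
significant (about 1.4 with a CI excluding 1) while another's was not
(about 1.4 with a CI spanning 0.8–2.5). The divergence comes entirely
from synthesis decisions: which trials enter the SAE analysis, which
reported events count as "serious", whether implausibly attributed events
(a cancer diagnosed inside a 13-week trial) count at all, and how sparse
2×2 tables are pooled.

harmsynth makes each of those decisions an explicit, replayable object:
a classification scheme, a scenario, a pooling method tag, an imputation
problem. The package then quantifies how much each decision moves the
pooled estimate.

## Effect measures

**Binary harms.** Each study contributes a 2×2 table (events/size per
arm). The per-study measure is the log risk ratio
$\hat\theta_i = \log\frac{r_{Ti}/n_{Ti}}{r_{Ci}/n_{Ci}}$ with
delta-method variance $v_i = 1/r_{Ti} - 1/n_{Ti} + 1/r_{Ci} - 1/n_{Ci}$.
Zero cells follow the standard rare-harm convention: studies with zero
events in *both* arms carry no information about a ratio and are
excluded (but reported); studies with a zero in *one* arm are retained,
with a continuity constant (default 0.5, configurable — no single value
is canonical) added to all four cells. `rr_single()` flags every
corrected table, and continuity has provably no effect on zero-free
tables.

**Continuous outcomes.** The per-study measure is the pooled-SD
standardized mean difference with the Hedges small-sample correction
$J = 1 - 3/(4\,df - 1)$, $df = n_T + n_C - 2$, and the usual
large-sample variance. The sign convention is fixed package-wide and
asserted in tests: negative favors treatment (function scales where
lower is better). Pooled SMDs are judged against conventional
clinical-importance thresholds (−0.37, −0.20, −0.12), shipped as
`smd_thresholds`; `exceeds_threshold()` requires both sufficient
magnitude and the right direction.

## Pooling engines

Four engines share one interface, `pool_trialset(ts, method)`, because
the audit's central question is "does the conclusion survive a change of
method?":

* `iv_fixed` — inverse-variance fixed effect, weights $1/v_i$;
* `dl_random` — DerSimonian–Laird random effects: moment estimator
  $\hat\tau^2 = \max\!\big(0, (Q - df)/C\big)$ with
  $C = \sum w_i - \sum w_i^2 / \sum w_i$, weights $1/(v_i+\hat\tau^2)$,
  Wald CIs; $Q$ and $I^2$ reported throughout;
* `mh` — Mantel–Haenszel stratified risk ratio
  $\sum r_{Ti} n_{Ci}/N_i \big/ \sum r_{Ci} n_{Ti}/N_i$ with the
  Greenland–Robins variance, no continuity correction (single-zero
  strata are handled natively — the usual choice for sparse harms);
* `exact_conditional` — exact conditional inference on a common odds
  ratio.

**The exact engine** conditions on all margins of every stratum, making
the treated-arm count $X_i$ noncentral hypergeometric; under a common
odds ratio $\psi$ the sufficient statistic $S = \sum X_i$ has a
distribution proportional to $c_s \psi^s$, whose coefficients are the
convolution of the per-stratum binomial-coefficient polynomials. The
implementation accumulates the $\log c_s$ directly in log space, so
strata as large as 1000 per arm cannot overflow. The point estimate is
the conditional MLE ($E_\psi S = s_{obs}$); the 95% CI inverts the
*central* exact test, allocating $\alpha/2$ to each tail, by root
finding over $\log\psi \in [-15, 15]$ (uniroot tolerance $10^{-11}$;
the bound is far beyond any odds ratio estimable at these counts). When
$s_{obs}$ sits on the support boundary, the corresponding limit is 0 or
$\infty$ and the estimate is reported on the boundary. Strata whose
margins admit only one table — including double-zero strata — are
dropped as uninformative; an all-degenerate set is an explicit error,
not a number. In the 2–3% baseline-risk regime the OR tracks the RR
closely (checked by simulation), so the exact OR is reported alongside,
never converted to, the RR-scale methods.

Why an exact method at all? Published exact pooling of sparse harm
tables is often done with proprietary software whose precise procedure
is not stated. This package implements the standard exact conditional
approach and reports it next to MH and DL so that a replication can
identify which scheme a published number is closest to
(`method_match()`), rather than assuming one.

All pooled outputs are *bit-identical under permutation of studies*:
every internal reduction sums its terms in sorted order, and exact
convolution uses a canonical stratum order. Per-study weights always
sum to 1 (for the exact engine, weights are the strata's shares of
conditional Fisher information at the point estimate).

## Classification

`classify_events()` maps free-text AE terms to (severity, locality)
under a `classification_scheme`: severity is serious / non-serious /
not-an-AE, locality is injected joint / local non-joint / systemic
"other" (systemic events default to "other"). Two conventions are
representable: explicit clinician-team rules, and deference to the
original study authors (`fallback = "use_author_flag"`), which mirrors
how some reviews adopt author designations wholesale. Unknown terms
under the fallback are labeled from the author flag with a warning, so
coverage gaps are visible rather than silent. `scheme_diff()` tabulates
exactly where two schemes disagree — the table that explains why one
review counts "joint sprain" as serious and another does not.

`aggregate_counts()` turns labeled records into per-study 2×2 tables
for any severity × locality cell ("any" gives union cells such as *all
serious AEs*). Counts are persons-with-event per reported term; terms
within an arm are summed as reported, because trial reports rarely say
whether one person had two different events. Reclassification moves
exactly the reclassified counts between cells, conserving total
person-events — an identity the test suite checks exactly. Studies
reporting only aggregate SAE totals (no terms) bypass classification
and enter pooling as pre-built tables.

## The scenario ladder

A `scenario_spec` is a named transformation: exclusions, then a
subgroup restriction, then signed event deltas. The fixed order matches
how sensitivity tables are actually constructed (deltas are applied to
the studies that survive selection; a delta targeting a removed study is
dropped). Deltas are the formal version of "what if the two omitted
myocardial infarctions had been counted?" and "what if the four cancer
cases had not been?"; apply-then-negate restores the base set exactly.
"Large" in the conventional *large, blinded trials* subgroup has no
canonical definition, so the size threshold is a parameter (default
total n ≥ 200). `run_ladder()` crosses scenarios with pooling methods
and emits one labeled row each, with a significance flag defined as the
CI excluding 1; `leave_one_out()` reports each study's full-pooling
weight beside the estimate without it, which is how a single high-weight
outlier is exposed.

## Hidden-count imputation

When a published pooled estimate includes trials whose counts were
withheld but whose sample sizes are known, the counts can be recovered
by bounded integer search: find hidden $(r_T, r_C)$ per study so that
pooling the completed set reproduces the published triple (point,
ci_low, ci_high). The objective is the weighted squared log-scale
distance with default weights (2, 1, 1) — the point estimate is the
primary published quantity, but matching the CI endpoints is what makes
recovery essentially unique; setting the CI weights to 0 recovers
point-only matching. Published targets are printed to 2 decimals, so
"attained" means agreement within 0.005 per matched component.
`invert_counts()` enumerates exhaustively up to a candidate cap
(default $10^7$) and otherwise offers deterministic multi-restart
coordinate descent; ties within tolerance are all reported (smallest
total events first), and uniqueness is a reported flag, never an
assumption. On synthetic problems with forward-computed targets the
search recovers the generating counts exactly in well over 80% of
replicates.

## The synthetic generator and what it does (not) show

`gen_binary_trialset()` draws per-arm sizes uniformly from `n_range`
and binomial event counts at control risk `p0` (default 0.025; SAE
rates in this literature run at 2–3%) and treatment risk
`p0 × true_rr`. The optional outlier study multiplies the baseline by
3 by default — near 7%, the rate that made one real trial dominate a
pooled SAE analysis with ~31% weight. Two outlier shapes exist because
they answer different questions: `arm = "both"` (default) is the
high-rate but ratio-neutral pattern; `arm = "treatment"` is a
harm-inflating outlier whose removal demonstrably de-biases the pooled
RR. `gen_continuous_trialset()` simulates patient-level normal outcomes
(treatment mean shifted by `true_smd × sd`) and summarizes them to the
mean/SD/n a meta-analyst would actually see. Generators use one root
seed with counter-derived per-study substreams, so adding studies never
reshuffles earlier ones, and they restore the caller's RNG state.

The generator emulates summary-level structure only: independent
binomial/normal arms, no correlation between arms, no selective
reporting, no time-varying risk, no misclassification noise in the AE
terms. Tests passing on these sets validate the *arithmetic and
calibration* of the pipeline, not the clinical conclusions drawn from
any real trial set.

`make_paper_fixture()` deserves a caveat in bold: **its per-study split
is synthetic.** Published safety tables print only aggregate margins
(8 studies, 27/1056 treated vs 16/1017 control serious events; 10
studies, 415/1645 vs 375/1564 non-serious); the fixture invents a
per-study decomposition summing to exactly those margins, including one
deliberately high-rate study in the outlier role, plus the full 16-row
scenario ladder (4 delta variants × outlier in/out × full
sample/large-blinded). It exists so the whole pipeline can be exercised
end to end; its pooled values are not a reproduction of any published
per-study analysis.

## Study sizes used in the validation suite

The simulation-based checks fix their conditions once, on the scale of
the motivating literature: coverage runs 2000 replicates of 14 trials
(100–600 per arm, `p0 = 0.025`, true RR 1) and requires every method's
95% CI to cover in 93–97% of replicates; SMD recovery runs 500
replicates of 10 trials (~100 per arm, true SMD −0.23, tolerance
±0.03); RR recovery runs 500 replicates of 14 trials (true RR 1.4,
tolerance ±0.1); imputation recovery runs 200 replicates of 5-trial
sets at 2% baseline risk with one hidden study (search bounds 20 events
per arm, ≥80% exact recovery required). The exact engine is verified
against full enumeration of the (joint) hypergeometric support for all
informative single-stratum tables with per-arm n ≤ 12 (probabilities to
1e−12) and for random two-stratum pairs, with CI endpoints to 1e−6
against an independently coded enumeration-based inversion;
`fisher.test` and `mantelhaen.test(exact = TRUE)` serve as additional
cross-checks at their own (looser, ~1e−3) root-finding accuracy.

## Numerical choices and edge cases

* Continuity constant 0.5, CI level 0.95, subgroup threshold 200: all
  surfaced as arguments, none hard-coded.
* Ratio estimates are back-transformed and rounded only in reports;
  analysis-scale values are never rounded internally.
* Double-zero studies: excluded from every ratio method, listed in the
  `excluded` field of the result rather than dropped silently.
* Undefined CI endpoints (boundary exact estimates) propagate as
  `NA`/empty report cells with a `defined = FALSE` flag.
* Tie-breaking in imputation reporting: smallest total events first,
  then lexicographic — deterministic output for symmetric problems.
* Heterogeneity statistics: `tau2` is `NA` for the fixed-effect MH
  method (Q and I² are reported descriptively from per-study log RRs);
  all heterogeneity fields are `NA` for the exact conditional method,
  where they are not defined.

## Known limitations

* The exact engine infers a common *odds ratio*; it is reported beside
  RR-scale methods, and the OR≈RR identification holds only in the
  rare-event regime.
* DL between-study variance is noisy at small k; with k ≤ 3 the
  random-effects CI can be anti-conservative. The ladder's
  method-crossing exists precisely so conclusions are not staked on one
  weighting scheme.
* Person-level multiplicity is unresolvable from study reports: summing
  term counts within an arm can double-count patients with two distinct
  events. Counts are used as reported.
* Imputation recovers counts only up to the information in the target:
  symmetric hidden studies yield ties (reported, flagged non-unique),
  and a coarsely rounded target may admit several exact-objective
  optima.
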