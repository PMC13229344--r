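---
title: "Feedback-driven synthesis of household-structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-driven synthesis of household-structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhsynth)
```

## The problem

Agent-based models in transport, epidemiology and disaster management need a
synthetic population: individual people, with ages, genders and household
memberships, whose aggregate statistics match what is known about a study
region. Classical synthesis methods (IPF, IPU, combinatorial optimisation)
reweight census *microdata* — individual-level sample records — to match
aggregate targets. Microdata are often unavailable, outdated, or restricted;
aggregate marginal distributions (shares per age band, gender, household size,
household composition) are far easier to obtain.

`hhsynth` implements a *sample-free* alternative: households are proposed by a
pluggable generator, validated against an attribute schema and structural
rules, and accepted into the growing population; at each batch the generator
is shown both the target marginals and the empirical marginals of the
population so far, so it can steer subsequent proposals toward the remaining
deficits. The generator is abstract: it can be a large language model reached
through `llm_backend()`, a scripted stub for testing, or the package's own
seeded deficit-proportional sampler, which makes the whole loop runnable and
testable offline.

## Formal setting

A population $P = \{h_1, \dots, h_N\}$ is a set of households; household
$h_i$ is a set of persons $p_{ij}$, each an attribute vector (age, gender,
relationship to the household head, ...). Derived attributes are the
household size $n_i$ and the household type $\phi(h_i)$, a categorical label
computed from member roles and ages (one-person, couple, couple with
children, lone parent, extended family, non-relatives).

The inputs are a set of target descriptors $D = \{D_k\}$ — here, marginal
distributions supplied as two-column CSV files (category, percentage share) —
plus a schema $S$ (attribute domains, e.g. age an integer in $[0, 120]$) and
structural rules $R$. Writing $G_k(P)$ for the empirical distribution of
descriptor $k$ in the synthetic population, the synthesis objective is

$$\min_{P \in F(S, R)} \sum_k \delta_k\!\left(G_k(P), D_k\right),$$

where $F(S,R)$ is the feasible set of schema- and rule-conforming households
and $\delta_k$ a discrepancy measure. Validity of a single household is the
indicator $I(h; S, R)$, and the *feasibility rate* of a population is the
mean of that indicator.

The default rule set encodes the three structural constraints that make
household data coherent — exactly one head per household, no minor living
alone, parents strictly older than their children — plus a minimum head age.
The minor threshold is 18 (the dependent-child cut used by the composition
classification) and the minimum head age 16, the youngest plausible
household-reference-person convention; both are configurable. The
parent-older-than-child rule demands only strict inequality; a stricter
`parent-child-gap` rule (default 15 years, off by default) is available for
studies that want demographic plausibility rather than bare consistency.

## The generation loop

`generate_population()` implements the loop. Until $N$ households are
accepted:

1. compute the empirical descriptors of the population so far;
2. build a prompt containing, in order: task instructions (output format and
   batch size $B$), a schema excerpt, the target distributions, and the
   current distributions (omitted when `feedback_enabled = FALSE`);
3. ask the backend for $B$ candidate households;
4. parse and validate each candidate; invalid ones are returned to the
   backend together with their diagnostics and re-requested, up to
   `retry_limit` total attempts per household slot, after which the slot is
   counted failed.

Errors are recorded per class — `parse` (malformed responses), `schema`
(wrong structure or out-of-domain values), `rule` (structural violations),
`api` (backend failures) — and the per-batch empirical snapshots feed
`convergence_trace()`. The defaults $B = 10$ and `retry_limit = 3` reflect
the batch size at which per-household cost, reliability and fit balance best
and the conventional three-strikes retry budget. Empirical descriptors are
recomputed once per batch, not per household, which bounds the bookkeeping
cost at scale.

## The reference sampler

`reference_sampler_backend()` is a seeded backend that plays the generator's
role offline. It deliberately communicates with the loop *only through the
prompt text*: it parses the target and current tables back out of the prompt,
so it exercises exactly the same interface an external model would.

Internally it works in three steps.

**Reconciling the household-level marginals.** Household size and household
composition both constrain the same discrete choice (what kind of household
to build next), and nothing guarantees the two marginals agree. The sampler
therefore builds a joint target $\tau(c, b)$ over (composition category,
size bin) pairs, supported on the structurally compatible pairs (a couple
household cannot have size 3; a one-person household has size exactly 1),
by iterative proportional fitting from a compatibility-masked seed matrix.
When the marginals are mutually consistent IPF converges and $\tau$
reproduces both exactly. When they conflict, the row-scaled and
column-scaled iterates disagree forever; the sampler averages the two final
iterates, which for a disconnected block such as one-person households
splits the difference between the two imposed shares. This is why
generation against targets that give one-person households 14.5% (size) and
9.6% (composition) settles near 12%: the sampler treats competing marginals
as equally weighted and partially satisfies each, rather than privileging
one.

**Deficit chasing.** Each draw is made from deficit-proportional weights
$w_j = \max\{t_j (n+1) - c_j,\ \varepsilon\}$, where $t_j$ is the target
share, $c_j$ the count so far and $n$ the number of units so far: the
distribution of what *should* be drawn next so the running tally tracks the
target. The floor $\varepsilon$ (default $10^{-6}$) keeps every category
reachable and breaks ties toward first-listed categories. Household
structure is drawn from $\tau$ tilted by the size and composition deficits;
member ages and genders are drawn from the person-level deficits restricted
to role-compatible ranges (heads adult, children strictly younger than the
youngest parent with a 16-year generator-side gap, partners within 15 years
of the head). Within a batch the sampler updates its local tallies after
every draw, so a batch of ten does not overshoot a nearly-satisfied
category.

**Structural realisation.** Composition categories are interpreted as
constructive patterns (single, couple, couple with children, lone parent,
extended family, housemates); the member list is built head-first so every
output household satisfies the rules by construction. The loop still
validates everything — accepted output has feasibility rate 1 by double
enforcement, and the validator is what guards arbitrary backends.

With feedback disabled the sampler receives no current tables and draws
i.i.d. from the reconciled targets. The remaining error is then pure
multinomial sampling noise, which is why feedback-enabled runs dominate the
ablation on every seed: active deficit correction cancels noise at rate
$O(1/n)$ rather than $O(1/\sqrt{n})$.

## Fit metrics

For aligned share vectors $p$ (target) and $q$ (synthetic) over $n$
categories:

* **SRMSE** $= \sqrt{n \sum_i (p_i - q_i)^2}$ — the RMSE divided by the mean
  target share $1/n$. This is the standard population-synthesis convention;
  it is 0 at a perfect match, unbounded above, and grows with the category
  count at fixed per-category error, so values are comparable only within a
  descriptor.
* **JSD** with base-2 logarithms, bounded in $[0,1]$, 0 iff identical and 1
  on disjoint supports; zero-mass terms contribute zero.
* **Ordinal Wasserstein** $W_1 = \sum_i |F_P(i) - F_Q(i)|$ over the
  cumulative sums, for ordered descriptors only. Categories are equally
  spaced; open-ended terminal bins ("80+", "6+") get width 1, which slightly
  understates transport cost into the tail — a deliberate, documented
  convention.

Cross-tabulation fit (`crosstab_r2()`) is the squared Pearson correlation
between synthetic and reference cell shares over the full category product,
the statistic usually annotated on observed-versus-target scatter plots; an
all-equal reference has no variance to explain, and is flagged as degenerate
rather than propagating `NaN`. Repeated-run uncertainty uses a seeded
percentile bootstrap (2.5/97.5) over resampled run means.

## The synthetic fixture

`make_latent_population()` builds the ground truth that replaces census
data in every test: a seeded mixture of structural household patterns
(30% one-person split 17/13 around the 66+ cut, 18% couples, 25% couples
with children split 20/5 dependent/non-dependent, 11% lone parents, 8%
extended-family, 8% shared non-relative households) with role-conditional
age profiles and a 15-year parent-child gap. The default 883 households
match a typical small-area census zone, the scale at which the loop has
essentially converged. `marginals_from_population()` then derives the four
conventional descriptors — 10-year age bands with an open 80+ bin, gender,
global size bins (1, 2-3, 4-5, 6+), global composition labels — by tallying
the fixture itself, so the targets are internally consistent by
construction and exactly recoverable (zero SRMSE). `inject_conflict()`
overwrites one category's share differently in two descriptors and rescales
the rest proportionally, reproducing the conflicting-marginal regime in a
controlled way.

What the fixture does *not* emulate: real age-pyramid shapes (its profiles
are piecewise-uniform), spatial heterogeneity, attribute correlations beyond
those induced by household structure, and reporting noise. Passing tests
therefore demonstrate that the machinery is correct and self-consistent —
that the loop converges on achievable targets, that conflicts are
compromised, that IPU recovers a biased sample — not that any particular
real population would be fitted to a given accuracy.

## The IPU baseline

`ipu_fit()` implements Iterative Proportional Updating, the sample-based
comparator: household weights are repeatedly rescaled so that each
constraint category's weighted total matches its target, sweeping
household-level constraints first and then person-level ones in declared
order (the conventional ordering; it is configurable because the update
order affects the oscillation pattern, though not the fixed points). Each
update exactly satisfies its own constraint at that moment; with consistent
constraints and a sample that already satisfies them, one sweep leaves
weights unchanged to machine precision. Targets supplied as fixture-derived
empirical descriptors carry exact unit totals; plain share-only targets fall
back to a bin-midpoint estimate of the person total. Convergence is
declared when constraint totals move by less than the tolerance
(default $10^{-8}$ relative) between sweeps, capped at 1,000 iterations.
Fit diagnostics are reported on within-level *shares*, which are scale-free.
Integerisation draws households with replacement proportional to weight —
the simplest unbiased realisation.

## Numerical choices and degenerate inputs

* Share vectors are normalised to sum 1 within $10^{-9}$; CSV loaders
  auto-detect percentages (sum in $[90, 110]$) versus proportions
  ($[0.9, 1.1]$) and refuse anything else as a probable unit error.
* Category labels match by exact string equality after whitespace trimming;
  no fuzzy matching, because a silent mis-mapping is worse than a loud
  error. A population unit that maps to no category of a descriptor raises
  a consistency error rather than being binned silently.
* Empty populations tally to all-zero shares with total 0; the feasibility
  rate of an empty population is an error, not `NaN`.
* Ordinal bin labels accept exactly the forms `"k"`, `"a-b"` and `"k+"`.
  Households larger than 12 members are outside the reference sampler's
  constructible range, and a size bin lying entirely above that is rejected
  at backend construction.
* All randomness flows through explicitly seeded streams that are isolated
  from R's global RNG state, so identical configurations give byte-identical
  population files, traces and reports.

## Problem sizes used in the tests

The shipped test-suite and acceptance checks run the loop at 800 households
(the scale by which convergence is essentially complete, roughly 2,000
individuals), the conflict study at 2,000 households over five seeds, the
ablation at 800 households over five seeds, and IPU recovery on a
200-household biased subsample of the 883-household fixture. These sizes
were chosen as the smallest at which the studied effects are stable and
cleanly separated from sampling noise.

## Known limitations

* The reference sampler shares the loop's vocabulary of composition labels
  through pattern matching on label text; an exotic classification would
  need its own pattern table. Categories that the classification can never
  derive (such as an "unknown" composition) are never produced, so positive
  targets on them are unreachable.
* Cross-tabulations are evaluation-only; the loop fits marginals.
* One-way marginal feedback cannot enforce joint structure the targets do
  not describe; cross-tab fit is whatever the household patterns induce.
* Spatial attributes, dwellings and activity schedules are out of scope.
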