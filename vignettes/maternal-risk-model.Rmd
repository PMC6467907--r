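---
title: "The maternal risk-management model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The maternal risk-management model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrisk)
```

## The model

Every breeding female faces the same accounting problem: how many, how
large, and how unequal must her offspring be so that at least two of them —
one fertile daughter, one outbreeding son — survive to the next generation?
`matrisk` treats that replacement criterion as a constant, **w = 2
offspring**, identical across species, and derives three quantities from a
species' observable investment traits.

**Predation mortality.** A breeder producing $N$ offspring against a
replacement requirement of $w$ can afford to lose the fraction

$$P \approx 1 - w/N,$$

which the model reads as the probability of offspring mortality by
predation (in the broad sense: consumers at any biological level, plus
abiotic lethality) that the strategy is adapted to. $P$ is undefined as a
probability when $N < w$; see the singleton rule below.

**Scarcity mortality / relative quality.** The ratio of offspring mass at
dispersal to breeder mass,

$$S = m/M,$$

measures how much provisioning each offspring received relative to what the
breeder could give, and doubles as the modelled probability of offspring
mortality by spatiotemporal scarcity (starvation, desiccation, exposure).
Dispersal — the moment maternal provisioning ends — is the measurement
point, which makes $S$ comparable between egg-layers and mammals with
extended care.

**Brood inequality.** Within one brood with per-offspring masses $m_i$,
mean $\mu$, and descending ranks $R_i$ (largest offspring has rank 1,
smallest rank $N$), the bias-corrected Gini coefficient is

$$G = \frac{N+1}{N-1} - \frac{2}{N(N-1)\,\mu} \sum_{i=1}^{N} R_i m_i
    \;=\; \frac{\sum_{i,j} |m_i - m_j|}{2N(N-1)\mu}.$$

$G = 0$ is a perfectly equal brood and $G = 1$ the one-owner extreme
(one offspring holds the entire surplus). The model's open conjecture is
that the joint mortality index $C = P \cdot S$ is associated with $G$:
where predation and scarcity are simultaneously severe, breeders should
diversify investment among offspring.

### The Gini form used

The published rendering of the inequality formula is typographically
corrupted (an undefined symbol and ambiguous parenthesisation), so the
package implements the standard bias-corrected rank-form Gini above. It is
the unique standard form consistent with the stated rank convention
(descending, largest = 1) and the stated endpoints (0 for an equal brood,
exactly 1 for the one-owner brood) — the uncorrected form $1 - \ldots$
variants reach only $1 - 1/N$ at the extreme. Both algebraic routes are
implemented: the default is the mean-absolute-difference (pairwise) form,
computed by the sorted-cumulative identity in $O(n \log n)$, because it
needs no tie-break rule; the rank form (with ranking applied to sorted
masses, which keeps it equal to the pairwise form under ties) is exposed as
`method = "rank"` and verified equivalent on random distinct-mass vectors to
1e-12 in the test suite.

## Parameters

| parameter      | meaning                                   | default | units |
|----------------|-------------------------------------------|---------|-------|
| `w`            | replacement fitness (survivors required)  | 2       | offspring |
| `s_setpoint`   | quality threshold between regions         | 0.1     | dimensionless (mass ratio) |
| `n_setpoint`   | quantity threshold between regions        | 10      | offspring |
| `n_substitute` | effective N for broods with N &lt; w      | 2.1     | offspring |

Set points are *study-scope decisions*, not estimates: a study of garden
arthropods and a study of pelagic fish will draw the lines elsewhere.
The defaults are the values used for the original 87-species demonstration.
`matrisk` deliberately provides no set-point inference.

**Boundary semantics.** Comparisons are exactly "≤ on the low side, strict
&gt; above": predation is $S \le s^\*, N > n^\*$; scarcity is
$S > s^\*, N \le n^\*$; weak is both low; convergent is both high. These
four half-open regions partition the positive quadrant, so every valid
record receives exactly one category — a property the suite checks on a
200×200 grid that includes both boundary lines.

**The singleton rule.** Species with $N < w$ (singleton-brood mammals, and
fractional averaged quantities below 2) would give negative $P$. Their
offspring quantity is replaced by `n_substitute = 2.1`, leaving
$P = 1/21 \approx 0.048$ — slightly above zero, as intended for species
whose strategy tolerates almost no brood loss. The trigger is $N < w$
rather than $N = 1$ so that averaged quantities such as 1.5 are also
caught; at the boundary $N = w$ no substitution happens ($P = 0$ is valid,
there is no negative number to prevent). The substitution is recorded in
`effective_n` and `singleton_rule_applied`, never applied silently, and
category assignment uses the effective quantity.

**Error policy.** $P$ is never clamped into $[0,1]$: a pre-substitution
$N < w$ reaching `predation_mortality()` is an error, so data problems
surface instead of disappearing into a plausible-looking zero. $S > 1$
(possible under multi-source averaging) is kept but warned about. Rows of
an input table that fail validation are skipped and itemised in an issue
report rather than aborting the run — trait tables compiled from
heterogeneous sources are dirty as a rule, and a single bad row should not
cost the run.

## Input conventions

Trait cells may contain ranges (`"2-6"`, hyphen or en-dash) or
`|`-separated multi-source values (`"100|200|300"`); both reduce to
arithmetic means, following the convention that mean quantity and quality
are used when sources differ. Thousands separators are accepted.
Per-offspring brood masses travel as a semicolon-separated column and
become a list-column on read; a missing `brood_masses` cell means $G$ is
unavailable (`NA`), never imputed. Masses only ever enter as ratios, so any
unit is fine as long as it is consistent within a row.

## The synthetic generator

`generate_species()` draws a community whose $(S, N)$ values fall
*strictly inside* the set-point region of their intended category, so the
classifier must recover every label — that recovery is an invariant of the
construction, asserted in the tests, not an empirical finding. The default
community has 87 species split 30/35/10/12 across
predation/scarcity/weak/convergent, emulating the cluster structure of the
original compilation (fish, reptiles and marine invertebrates in the
predation region; birds and mammals under scarcity; a few apex predators
under weak selection; social insects and mammals in the convergent region).
Quantity is log-uniform within per-category bounds (clutches span singleton
broods to $10^6$ eggs, so a linear draw would be degenerate), quality
uniform, and breeder mass log-normal with `meanlog = log(1000)` g and
`sdlog = 3`, spanning roughly insect to large-vertebrate masses.

What the generator does *not* emulate: phylogenetic correlation between
species, measurement error, allometric coupling between $N$, $m$ and $M$,
or species near the set-point boundaries. Passing label-recovery tests
therefore demonstrates the classifier's correctness on its own geometry,
not robustness on noisy real tables — boundary species in real data will be
sensitive to the set-point choice by design.

Brood mass vectors come from a symmetric Dirichlet split (gamma draws
renormalised to the exact brood total): concentration `alpha` is the
inequality dial, with small `alpha` concentrating mass in few offspring and
`alpha = Inf` implemented as an exact equal split. Mean $G$ is decreasing
in `alpha`, checked at `alpha` ∈ {0.1, 1, 10} with 5,000 replicates under a
fixed seed.

## The conjecture harness

The association between $C = P \cdot S$ and $G$ is an open conjecture; the
harness operationalises it with a deliberately minimal mechanism, chosen
here and labelled as the package's own:

1. draw a brood (Dirichlet, equal, or a fixed mass vector);
2. each offspring independently survives predation with probability
   $1 - P$;
3. survivors additionally survive scarcity only if their mass reaches the
   regime's threshold — scarcity acts after predation because $S$ is
   defined at dispersal, the later stage;
4. the brood replaces its breeder if at least $w$ offspring survive both.
   Offspring are not sexed; the one-daughter-one-son refinement of the
   replacement criterion is out of scope.

Per (regime × alpha) cell the harness reports replacement frequency, mean
$G$, the empirical scarcity mortality among predation survivors
$\hat{S}$, and $C = P\hat{S}$; the across-cell Pearson correlation of mean
$G$ with $C$ summarises the association. Because the mechanism is invented,
any agreement (or disagreement) between $C$ and $G$ here says nothing about
the conjecture's truth in nature — the harness only makes the conjecture
executable.

Everything random is seeded: generator configs and harness calls carry an
integer seed, results are bit-identical under identical seeds, and package
functions restore the caller's RNG state on exit.

## Numerical choices

- Equality assertions use a tolerance of 1e-12; the model is closed-form
  arithmetic with no iterative fitting, so nothing looser is needed.
- The pairwise Gini uses the sorted-cumulative identity
  $\sum_{i,j}|m_i-m_j| = 2\sum_k (2k - n - 1)\, m_{(k)}$, avoiding the
  $O(n^2)$ double loop (the test oracle keeps the naive double loop,
  deliberately).
- Degenerate inputs: broods of fewer than two offspring and all-zero broods
  are errors (inequality is undefined); a gamma underflow at very small
  `alpha` falls back to an equal split rather than dividing by zero.
- The quadrant plot log-scales the quantity axis by default (a linear axis
  is unreadable across six orders of magnitude); this is a display
  decision only, with a linear option.
- Test and check problem sizes — 1,000 random vectors for the Gini
  equivalence, a 200×200 classification grid, 400 synthetic species for
  label recovery, 20,000 Monte-Carlo replicates against the exact
  enumeration oracle for broods of n ≤ 12 (within 3 binomial standard
  errors) — were chosen as the sizes at which each property is convincingly
  exercised while the whole suite stays quick on a laptop.

## Known limitations

- No phylogenetic correction: species are treated as independent points,
  which overstates the evidence in any clustered clade.
- $C = P \cdot S$ is computed for every species, not only the convergent
  quadrant; readers who prefer the index only where both pressures are high
  can filter on the category column.
- Whether the original 87-species figure applied the $N \le 10$ boundary
  inclusively cannot be determined beyond the printed inequalities; the
  package follows the printed "≤" exactly.
- The supplement with the original 87 species' trait values is an optional
  input, not a package dependency; the packaged 8-species example table
  uses synthetic illustrative values, and the generator provides
  structure-matched stand-ins at any size.
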