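---
title: "Dominance hierarchies from bin event logs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance hierarchies from bin event logs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociodom)
```

## The problem

In group-housed cattle (and other gregarious livestock), access to feed
and water is mediated by a dominance hierarchy. The standard behavioural
currency for measuring it is the *competitive replacement*: one animal
withdraws from a feeder or drinker and another takes its place within a
short interval, the incomer (actor) having displaced the occupant
(reactor). Electronic bins record every visit with transponder-stamped
entry (`IN`) and exit (`OUT`) times, so replacements can be detected
algorithmically instead of by live observation. `sociodom` implements
that detection and the downstream dominance statistics.

## Replacement detection

The log is sorted by bin and entry time (a stable sort: simultaneous
entries keep file order, and a warning flags that the actor/reactor
assignment then depends on it). Within each bin, each visit is compared
with its immediate predecessor only — detection is one linear scan, the
simplest reading of "sequential visits". For predecessor p and successor
q the gap is

$$g = t_{in}(q) - t_{out}(p)$$

in whole seconds (the timestamps carry second resolution; no sub-second
logic exists). The pair is a replacement when the animals differ and
$0 \le g < \texttt{sec}$.

Three boundary decisions are explicit configuration rather than hidden
behaviour:

* **`gap_comparison`** — the default is strict (`g < sec`). Published
  threshold ranges are sometimes quoted inclusively, and a strict and an
  inclusive rule differ exactly on gaps equal to the threshold, so the
  inclusive variant (`g <= sec`) is a switch. All analyses accept either.
* **`allow_negative_gap`** — raw logs occasionally contain overlapping
  visits at one bin (next entry stamped before the previous exit).
  Because a replacement requires the reactor to have withdrawn
  completely, negative gaps are *not* replacements by default; the flag
  treats them as a gap of zero for systems whose clocks make genuine
  replacements look overlapped.
* **Chains** — in a sequence A, A, B at one bin, B is compared against
  the second A only. Merging repeated visits by the same animal into
  feeding bouts is deliberately out of scope: bout criteria are
  species-specific and orthogonal to detection.

The threshold `sec` itself is a scientific input, not something the
package estimates: reported optima are about 26 s for lactating dairy
cows at feed bins, about 29 s at water bins, 20–30 s for combined data,
and 0–10 s has been used for young Nellore bulls. Estimating the optimal
interval per species and category is an open research question and a
non-goal here.

## From interactions to a hierarchy

**Sociomatrix.** $X_{ij}$ counts interactions with $i$ as actor and $j$
as reactor. Internally rows are actors; the CSV serialisation transposes
to the conventional display (reactors down the rows, actors across the
columns), and reading the file back restores the internal orientation
exactly. Labels sort numerically whenever every id parses as an integer
— ear-tag ids like 227 print in their familiar order — and
lexicographically otherwise; ids are opaque strings throughout, so
leading zeros survive.

**Dyadic dominance.** Each dyad is reduced to the sign of its net
outcome, $S_{ij} = \mathrm{sign}(X_{ij} - X_{ji}) \in \{-1, 0, +1\}$,
with 0 covering both *tied* (equal non-zero wins) and *unknown* (no
interactions) relationships; the sign form also guards the 0/0 case of
the ratio definition. The matrix is antisymmetric by construction.

**Kondo–Hurnik dominance value.** $S_i = \sum_j S_{ij}$ — the number of
herd mates animal $i$ dominates minus the number it is subordinate to.
Values sum to zero over the group and $|S_i| \le n-1$. The method's
appeal is that it weighs every relationship equally, without the
opponent-strength weighting of David's score or Elo.

**Social categories.** The observed value range spans
$\max - \min + 1$ integer points (the $+1$ covers the zero point). That
width is divided into $k$ equal real-valued bins
($\text{size} = \text{width}/k$, no rounding), and an animal with value
$v$ falls in bin $\lfloor (v - \min)/\text{size} \rfloor$, clipped to
the top bin; $k = 2$ gives social rank (low/high), $k = 3$ the social
hierarchy (subordinate/intermediate/dominant). The equal-width rule with
real-valued bin size was chosen because it is the only parameter-free
reading consistent with categorical extremes observed in published
worked examples when the range is not divisible by $k$. If all values
are equal the range is degenerate; every animal is then assigned the
middle (k = 3) or lowest (k = 2) category with a warning, since no split
of a single point is meaningful. Category labels are configurable
strings, so output can be made byte-compatible with tools that spell the
top category differently (e.g. "dominate").

## Linearity

Landau's index

$$h = \frac{12}{n^3 - n} \sum_a \left(V_a - \frac{n-1}{2}\right)^2$$

with $V_a$ the number of animals $a$ dominates, is 1 exactly on a strict
linear order and 0 when every animal dominates equally many (the
circular triad). The improved index adds a correction for the $u$ dyads
never observed interacting:

$$h' = h + \frac{6}{n^3 - n}\,u.$$

Two deliberate choices:

* $u$ counts *unknown* dyads only — both directed counts zero —
  determined from the sociomatrix (which is why `improved_index()` takes
  both matrices). Tied dyads are not unknown: the animals met, the
  record is balanced. The dyadic matrix alone cannot make this
  distinction.
* Both formulas are implemented exactly as written. With incomplete
  data $h$ (and hence $h'$) can exceed 1; no renormalisation is applied,
  and the `h > 0.9` "strongly linear" reading is surfaced as a text
  annotation, not a test. The randomisation test for linearity
  significance is out of scope.

## Comparison indices

**David's score** works on dyadic win proportions
$P_{ij} = X_{ij}/(X_{ij}+X_{ji})$ (0 for unobserved dyads):
$DS_i = w_i + w_{2,i} - l_i - l_{2,i}$ with $w_i = \sum_j P_{ij}$,
$w_{2,i} = \sum_j P_{ij} w_j$ and the loss terms mirror-image. The
`"Dij"` variant shrinks each proportion toward 0.5 by
$(P_{ij}-0.5)/(n_{ij}+1)$, damping dyads seen only a few times. Scores
sum to zero by construction.

**Elo** processes interactions sequentially: expected success
$E = 1/(1+10^{(R_l - R_w)/400})$, winner gains $k(1-E)$, loser loses the
same. Defaults $k = 100$, start 1000 follow common practice in animal
dominance packages; because the result is order- and $k$-dependent, Elo
is treated as a comparison method and its correlations are not used as
reproduction targets.

**Cross-method agreement** is quantified by pairwise Pearson $r$ with
the two-sided p-value from `stats::cor.test()`, over animals shared by
both score tables (at least 3 required).

## The synthetic generator

`simulate_interactions()` draws a latent strict order (random
permutation, dominant first), then stages contests on uniformly chosen
dyads; the higher-ranked animal wins with probability $1 - p_{upset}$.
`simulate_bin_log()` embeds such contests in a visit log: each bin's
timeline is a sequence of slots separated by `slot_gap` (default 300 s),
a slot being either one background visit or a staged replacement pair
whose gap is drawn uniformly from `gap_range` (default 0–9 s, matching
detection at `sec = 10`). Visit durations are exponential (mean 120 s, a
realistic feeding-visit scale for growing cattle), bin choice uniform,
and the background visit count Poisson with mean
`visit_rate × n_animals × n_days`. The slot construction guarantees that
no background pair can fall within any threshold below `slot_gap`, so
staged pairs are recoverable with precision and recall exactly 1 — this
is a *constructed* property used to validate the detector, not a claim
about field data. The generator's signature carries an explicit
`n_replacements` because the staged-pair count is the experimental unit
of every recovery check.

Default conditions used by the test-suite and the acceptance script:
20 animals, 5 bins, upset probability 0.1, 200 staged replacements for
detection checks, and a 2000-contest tournament for rank recovery — a
desk-scale version of a commercial feed-efficiency test pen (tens of
animals, a handful of bins, tens of thousands of visits), sized so the
full suite runs in seconds. One integer seed governs all draws and is
embedded in the returned truth object; the global RNG state is restored
on exit.

What the generator does **not** emulate: diurnal feeding peaks after
fresh feed delivery, social facilitation (synchronised feeding),
bin-specific preferences, and transponder misreads. Passing the recovery
tests therefore shows the algorithmic chain is correct under its own
assumptions, not that a 10 s threshold is right for any particular herd.

## Numerical and degenerate-input choices

* Gaps and durations are whole seconds; gap arithmetic rounds the
  POSIXct difference to kill floating-point noise.
* Timestamps are naive local times (no timezone or DST handling): bin
  systems stamp in local time and the analysis only uses differences.
* Empty inputs degrade gracefully: an empty log yields an empty
  interaction list; an empty interaction list with a roster yields a
  zero sociomatrix; a 0×0 dyadic matrix yields an empty dominance
  table. Landau's index requires $n \ge 2$ and errors below that.
* Strict validation is the default (errors name offending rows);
  `lenient = TRUE` drops bad rows with a warning and is exposed as
  `--lenient` on the command line.
* Frequency tables include only animals appearing in the interaction
  list, matching conventional output; a `roster` argument adds zero
  rows.

## Limitations

* Only the immediate-predecessor rule is implemented; detection cannot
  see a displacement across an intervening third visit.
* The I&SI ranking method and the de Vries randomisation test are not
  implemented; David's score and Elo serve as the comparison methods.
* The optimal detection threshold per species/category is the user's
  responsibility.
* Hierarchies are treated as static over the log; no sliding-window or
  temporal dynamics.
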