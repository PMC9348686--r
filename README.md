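# sociodom

Social dominance hierarchies from electronic feed-bin event logs.

Gregarious animals — cattle above all — compete for access to feeders and
drinkers, and that competition structures the group: dominant animals
displace subordinates, and the pattern of displacements is the standard
observable for inferring the group's social hierarchy. Modern electronic
bins (transponder-equipped feeders and water troughs) record every visit of
every animal with entry and exit timestamps, which makes the classic
*competitive replacement* detectable automatically: the animal occupying a
bin (the **reactor**) withdraws and another animal (the **actor**) takes
the same bin within a short time interval.

`sociodom` is for researchers in applied ethology and precision livestock
farming who have such visit logs (or conventional actor/reactor
observations) and want the group's dominance structure out of them.

## What it computes

Starting from a visit log with columns `equip_id`, `animal_id`, `IN`,
`OUT`:

1. **Replacement detection** — visits are sorted by bin and entry time;
   for consecutive visits p, q at one bin by different animals, the pair
   is a replacement when the gap `t_in(q) − t_out(p)` is below a threshold
   `sec` (species- and category-specific; reported optima are ~26 s for
   dairy cows at feeders and 0–10 s has been used for young Nellore
   bulls).
2. **Sociomatrix** `X`, with `X[i,j]` the number of times i displaced j,
   and the **dyadic dominance matrix** `S[i,j] = sign(X[i,j] − X[j,i])`
   ∈ {−1, 0, +1} distinguishing domination, subordination, tie and
   unknown relationships.
3. **Kondo–Hurnik dominance values** `S_i = Σ_j S[i,j]`, with the group
   split by equal-width binning of the value range into a 2-category
   **social rank** (low/high) and a 3-category **social hierarchy**
   (subordinate/intermediate/dominant).
4. **Linearity**: Landau's index
   `h = 12/(n³−n) · Σ_a (V_a − (n−1)/2)²` (V_a = number of animals a
   dominates; h = 1 for a strict linear order) and de Vries's improved
   index `h′ = h + 6u/(n³−n)` correcting for the `u` dyads never observed
   interacting.
5. **Comparison indices** — David's score (P_ij or D_ij variant) and a
   sequential Elo rating — with pairwise Pearson correlations between
   methods.
6. **Plots** — category bar plots, dominance-value box plots, and circular
   sociograms (edge width ∝ interaction count, arrows actor→reactor).

A synthetic-data generator (`simulate_interactions()`,
`simulate_bin_log()`) produces logs with a known latent hierarchy and
staged replacements, so the whole pipeline is testable without field data.

## Worked example

```r
library(sociodom)

# a synthetic 8-animal group, 3 bins, 150 staged replacements
sim <- simulate_bin_log(n_animals = 8, n_bins = 3, n_replacements = 150, seed = 42)
il  <- detect_replacements(sim$log, sec = 10)
il
#> <interaction_list> 150 interactions, 8 animals
#>   actor reactor equip_id                   t
#> 1   105     103       B1 2021-06-01 06:07:47
#> 2   101     105       B1 2021-06-01 06:29:22
#> ...

m <- sociomatrix(il)
d <- dyadic_matrix(m)
dominance_values(d)
#>   animal_id dominance_value social_rank social_hierarchy
#> 1       107              -7         low      subordinate
#> 2       103              -5         low      subordinate
#> 3       104              -3         low      subordinate
#> 4       102              -1         low     intermediate
#> 5       106               1        high     intermediate
#> 6       108               3        high         dominant
#> 7       105               5        high         dominant
#> 8       101               7        high         dominant

linearity_summary(d, m)
#> Linearity over 8 animals: h = 1.000000, h' = 1.000000 (u = 0 unknown dyads)
#> h > 0.9: strongly linear hierarchy

method_correlations(list(kondo_hurnik = kondo_hurnik_scores(d),
                         davids_score = davids_score(m),
                         elo          = elo_rating(il)))
#>       method_a     method_b         r            p n
#> 1 kondo_hurnik davids_score 0.9679983 0.0000799788 8
#> 2 kondo_hurnik          elo 0.9499931 0.0003010212 8
#> 3 davids_score          elo 0.9613749 0.0001399211 8
```

The dominance values range from −7 to +7 over 8 animals: animal 101 holds
a net winning record against all seven herd mates, 107 against none, and
the recovered order is exactly the generator's latent hierarchy
(101 > 105 > 108 > 106 > 102 > 104 > 103 > 107 — the staged upset rate of
10% is not enough to disturb it at 150 contests). h = 1 says the dyadic
relations form a strict linear order; u = 0 says every dyad was observed.
All three indices agree (r > 0.94, p < 0.001).

## Command line

```sh
SOCIODOM=$(Rscript -e 'cat(system.file("scripts", "sociodom", package = "sociodom"))')
Rscript $SOCIODOM simulate --animals 20 --replacements 200 --seed 4 --out events.csv
Rscript $SOCIODOM run --input events.csv --sec 10 --outdir out/
```

`run` chains detect → frequencies → matrices → dominance → linearity →
method comparison and writes a JSON run summary; each stage is also its
own subcommand (`detect`, `freq`, `matrix`, `dominance`, `linearity`,
`compare`, `plot`, `simulate`). Options of note: `--gap-cmp lt|le` for the
threshold boundary, `--datetime-format`, `--lenient` to drop rather than
reject malformed rows.

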