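# scattar

Navigate the evidence on health financing with context-matched
"scattar" plots.

Policy makers in low- and middle-income countries face a broad,
heterogeneous literature on domestic health financing — user fees,
community-based and national health insurance, private insurance, tax
funding, equity funds — that is hard to survey from journal articles.
`scattar` implements the engine of a visual evidence-navigation tool
for that literature: it stores a database of studies scored
qualitatively for the impact of **7 financing mechanisms** on **5
health-system goals**, scores how closely each study's countries match
the user's own context, and lays every study out as a dot in a
seven-sector polar display that shows, in one snapshot, how much
evidence exists per mechanism, how mixed it is, where it is lacking,
and how well it matches the user's context.

## The model

Each country is reduced to 11 indicators (health expenditure per
capita, maternal mortality ratio, under-5 mortality, HIV prevalence,
malaria incidence, education index, GDP, life expectancy, urban share,
extreme-poverty share, log10 population). Each indicator *I* is
min-max normalised over the countries in the table,

    T(I) = (I − min) / (max − min)  ∈ [0, 1],

so a country is a point {T(I)_j} in the 11-dimensional unit hypercube,
and the match between countries Y and Z is the Euclidean distance
d_YZ ∈ [0, √11] between their points (rescaled by √(11/k) when only
k dimensions are observed in both). A study's distance to the user's
country is the minimum over the countries it analysed.

The scattar layout then encodes, for a chosen country and goal:

* **sector** — which of the 7 mechanisms the dot's assessment belongs to;
* **radius** — d/√11: the inner ring holds reviews and studies of the
  chosen country itself, the outer ring the theoretical worst match;
* **colour** — the study's qualitative score for the chosen goal, green
  (evidence for) → red (evidence against), orange for definite evidence
  of no impact, grey where the goal was not considered (an evidence gap);
* **shape** — squares for literature reviews, circles for evaluations.

Positions depend only on the country and colours only on the goal, and
every plot of one database has the same number of dots.

## Worked example

No real evidence database ships with the package; the seeded generator
produces one with the published shape (78 studies carrying 88
mechanism assessments over 30 synthetic countries):

```r
library(scattar)

fx <- paper_shaped_fixture(seed = 1)
fx$db
#> <evidence_db> 78 studies (7 reviews, 71 evaluations)
#> provenance: synthetic evidence database (seed 1)

lay <- layout_scattar(fx$db, fx$table, country = "AAA", goal = "promote_equity")
lay
#> <scattar_layout> AAA / Promote equity: 88 dots in 7 sectors
#>
#>      equity_funds_discount_cards                       tax_funded
#>                                2                                2
#>         private_health_insurance         user_fees_implementation
#>                                4                               21
#>                user_fees_removal community_based_health_insurance
#>                               10                               24
#>        national_health_insurance
#>                               25

render_svg(lay, path = "scattar.svg")          # one plot
render_page(lay, layout_thumbnails(fx$db, fx$table, "AAA"),
            path = "page.svg")                 # plot + 5 goal thumbnails
```

88 dots — one per (study, mechanism) pair — split across the sectors
exactly as the per-mechanism study counts dictate; the same 88 appear
on every country/goal combination, only positions (country) and
colours (goal) move. Tabular drill-down mirrors the plot:

```r
impact_summary(fx$db, "community_based_health_insurance", "promote_equity")
#>                  score  n
#>       Evidence against  1
#>  Some evidence against  0
#>  No evidence of impact  0
#>      Some evidence for  4
#>           Evidence for  5
#>         Not considered 14

head(rank_matches(fx$table, "AAA"), 3)
#> # A tibble: 3 × 3
#>   country_code distance k_present
#>   <chr>           <dbl>     <int>
#> 1 AAP             0.870        11
#> 2 AAO             1.01         11
#> 3 AAS             1.05         11
```

Of the 24 CBHI studies, 10 assessed equity (mostly favourably), 14 did
not — the grey dots. `AAP` is the synthetic country whose indicator
profile lies nearest `AAA`'s.

A command-line interface wraps the same functions
(`inst/cli/scattar`): `plot`, `match`, `list`, `detail`, `validate`
and `simulate` subcommands, e.g.

```sh
Rscript inst/cli/scattar simulate --out-dir fixtures --seed 1 --paper-shaped
Rscript inst/cli/scattar plot --evidence fixtures/evidence.json \
    --indicators fixtures/indicators.csv \
    --country AAA --goal promote_equity --output scattar.svg
```

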