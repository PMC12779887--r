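# goosesim

An individual-based simulation of four goose species — barnacle (BAG),
greylag (GLG), pink-footed (PFG) and greater white-fronted goose (WFG) —
wintering on a managed grassland landscape, for researchers and wildlife
managers studying how species interactions (competition and facilitation
through shared swards) shape goose distributions and the costs of the
farmer–goose conflict.

## What it models

Flocks (1000/100/200/400 geese by species) are the agents on a grid of
1-ha patches typed roost / other / scaring-area / accommodation-area /
nature-area grassland. From November 1 to May 15 (195 days, 4680 hourly
steps) each flock follows a decision tree: roost when the day's maximum
weight is reached, otherwise forage on a remembered patch (100-entry
memory scored by age-discounted net energy gain) or via a composite random
walk whose step length `x` (hm) has survival

    P_x = P_BW exp(-λx) + (1-P_BW) (1 - (1 - x_min^(μ-1) x^(1-μ)) / (1 - (x_min/x_max)^(μ-1)))

— an exponential (Brownian) component mixed with a bounded Pareto
(truncated Lévy) component. Flight over `d` patches costs
`T = exp(S)·d·L/v` seconds with `S = 10/(1 + c1 (d·L·c3)^c2)` (geese
circle before landing). Flocks may join conspecifics, accept patches in
proportion to intake rate at the local sward height, and are displaced
~2 km when scared (most likely in scaring areas). Intake follows a
bite-based functional response capped at the species' maximal
instantaneous rate; energy balances move body mass, and a flock dies below
its species' minimum weight. Grass grows daily from temperature and
radiation; grazing removes 1 cm of height per 150 000 g dry matter per ha.
Yield loss is priced at €0.25 per kg — €37.50 per cm per ha against an
ungrazed reference — plus €10 per scaring event and configurable appraisal
costs.

The package also implements the calibration chain (roost detection from
GPS fixes, flight segmentation at >12 m/s, flight-time and step-length
fitting, flock-size quantiles), synthetic-data generators for every input,
and factorial population sweeps analysed with normalized-coefficient
linear models.

## Worked example

```r
library(goosesim)

land <- gen_landscape(100, 100, seed = 7)   # study-region composition
cfg  <- load_config()                        # full species parameter table
cfg$population_scalars[] <- 0.01             # desk-scale populations

res <- run_simulation(land, cfg, seed = 1, n_days = 120)
res
#> <goosesim_result> 2880 hourly steps over 120 days (seed 1)
#>   goose pressure (h): BAG 4467834, GLG 344789, PFG 133814, WFG 2021245
#>   scaring events: 3209 | deaths: 6 | yield loss: EUR 28405.06

round(res$pressure)
#>                   BAG    GLG   PFG     WFG
#> scaring       3517490 241387 78263 1175261
#> accommodation  700042  70885 35970  529042
#> nature         250302  32517 19582  316942

round(pressure_per_goose(res, "GLG", "agricultural"), 2)
#> [1] 4.84
```

The pressure matrix is cumulative goose-hours per grassland type: e.g.
barnacle geese spent 2.74M goose-hours on scaring-area grassland over the
120 days. `pressure_per_goose` converts this to hours per goose per day
(greylags foraged ~5 h/day on agricultural grassland here). `yield_loss`
monetizes the sward deficit on agricultural land. (Numbers above are from
the exact calls shown; your platform's RNG must be R ≥ 4.0 defaults.)

Population sweeps mirror the full factorial experiment:

```r
design <- build_design(c(0.5, 2))                 # fractions of the maxima
tab <- sweep_populations(design, land, cfg, seeds = 1:3, n_days = 120)
fit_importance(tab, response = "yield_loss")      # normalized coefficients
```

A thin command-line wrapper is installed at
`system.file("scripts", "goosesim", package = "goosesim")` with
subcommands `run`, `sweep` and `fixtures`.

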