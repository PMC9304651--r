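# concilium

Networks of simulated chemical oscillators that classify gene-expression
records — applied to predicting whether a multiple-myeloma patient will
respond to bortezomib (PS341) or dexamethasone (DEX) therapy.

## The idea

Each classifier is a network of three coupled two-variable Oregonator
oscillators, the reduced kinetics of the photosensitive
Belousov–Zhabotinsky reaction:

```
du_j/dt = (1/ε) [ u_j − u_j² − (f v_j + φ_j(t)) (u_j − q)/(u_j + q) ]
          − (α + β Σ_i s_ji) u_j + β Σ_i s_ji u_i
dv_j/dt = u_j − v_j
```

with ε = 0.3, q = 0.002, f = 1.1, symmetric 0/1 coupling `s`, lumped decay
and exchange rates α, β. Illumination
`φ_j(t) = 0.1 [1.001 + tanh(−10 (t − t_illum,j))]` holds each oscillator in
a stable steady state (u\* = v\* ≈ 0.00204 at φ = 0.2) until its switch
time, then releases it into a limit cycle of period ≈ 8.2 time units.

A patient record enters through timing: the expression value of one gene,
min–max normalized to `p` against fixed training ranges (`gene_ranges`),
sets the switch time of the network's input oscillator(s) via
`t_illum = t_start + (t_end − t_start) · p`. The readout is the number of
activator maxima above 0.05 on a designated output oscillator within
`[0, t_max]`; a trained count-to-class rule maps that integer to
responsive (1) or nonresponsive (0). Networks are trained by an elitist
genetic algorithm (population 100, elite 5, parents from the top 40, 500
generations) whose fitness is the training accuracy of the best induced
rule, and the 15 single-gene networks are combined by majority voting — the
*concilium* — which declares a record responsive when at least `k` of 15
members vote for it (k = 8 is strict majority). A 10-bin histogram vote on
raw expression values (`fit_histogram()`) serves as the no-dynamics
baseline.

The 15 trained networks and their readout rules ship as JSON fixtures
(`published_networks()`, `published_rules()`), together with the ±1%
single-parameter robustness perturbations (`published_perturbations`).

## Worked example

```r
library(concilium)

steady_state(phi = 0.2)
#>           u           v
#> 0.002040688 0.002040688

measure_period(phi = 1e-4)
#> [1] 8.248

# classify one RPS7 expression value with the bundled gene-13 network
cfg  <- published_networks(13)[[1]]
rule <- published_rules(13)[[1]]
p <- normalize_expression(6654.89, gene = 13)   # -> 0.5
simulate_record(cfg, p)
#> osc_1 osc_2 osc_3
#>     3     3     7
```

Seven supra-threshold maxima on the output oscillator (#3) fall in the
rule's nonresponsive set {0, 2, 6, 7, 8}, so this record is predicted
nonresponsive. The full ensemble works the same way per record:

```r
tab  <- synthesize_patients(6, overlap = 0.5, seed = 42)
conc <- published_concilium()
predict(conc, tab, k = 8)
#> # A tibble: 6 × 5
#>   record votes_for outcome drug  decision
#>    <int>     <int>   <int> <chr>    <int>
#> 1      1         3       0 PS341        0
#> 2      2         8       1 PS341        1
#> 3      3         5       1 DEX          0
#> 4      4         6       1 PS341        0
#> 5      5         7       0 PS341        0
#> 6      6         7       0 PS341        0
```

`votes_for` counts members voting responsive; `decision` applies the
threshold. (These six records are synthetic; the ensemble's published
accuracies are defined on the clinical table below.)

Training a fresh network on a table uses the same verbs:

```r
fit <- evolve_network(tab, gene = 1, ga = ga_config(generations = 50, seed = 1))
fit$trace            # per-generation best/mean fitness (tidy)
autoplot(fit)        # fitness trace
```

## The clinical dataset

The 239-record training table (15 expression values, outcome, drug, GSM
id per record) is third-party patient data and is not redistributed with
the package. To run the clinical pipelines, place it as
`inst/extdata/clinical/clinical_table.csv` (canonical columns
`gene_01..gene_15`, `outcome`, `drug`, `patient_id`) or drop the original
supplementary spreadsheet as `clinical_table.xlsx` (expression in columns
A–O, outcome in Q, drug in S, id in U) and reinstall; `read_patient_table()`
handles both dialects. The corresponding test-suite block then verifies
the published accuracies (histogram baseline 62.3% on RPS7, single-network
71.1%, concilium 84.9% at k = 8, and the ±1% robustness figures); without
the file that block reports failure.

## Command line

A thin CLI over the same functions lives at `inst/cli/concilium-cli.R`
(subcommands `steadystate`, `period`, `simulate`, `synth`, `baseline`,
`train`, `evaluate`, `concilium`); every run writes a JSON manifest with
the command, flags, seed, input checksums and package version. Example:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "concilium-cli.R", package = "concilium"))')" steadystate --phi 0.2
#> u* = 0.00204069, v* = 0.00204069
```

See `vignettes/oscillator-network-classifiers.Rmd` for the model,
numerical conventions, training design, and the limits of what the
synthetic-data checks demonstrate.
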