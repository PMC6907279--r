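# hetpath

Time-resolved drug repositioning on heterogeneous knowledge networks.

`hetpath` is for computational drug-repositioning researchers who work
with text-mined biomedical knowledge graphs (subject–predicate–object
triples with supporting publication ids) and want to evaluate
link-prediction models the honest way: not only by cross-validation on
randomly withheld indications, but by training on the literature as it
stood in a given year and testing on indications approved *afterwards*.

The package implements the full pipeline:

* **Network construction** — clean a raw triple table into a typed
  heterogeneous network (hetnet) via concept remapping, edge-type
  condensation, sparse-type filtering (< 0.1% of edges), top-*n* hub
  removal, and a ≥ 2-publication support filter.
* **Temporal slicing** — date every edge by its earliest supporting
  publication and reconstruct the network at any year.
* **DWPC features** — for a metapath *m* (a typed chain such as
  `CDrtCDtDO`, "drug related to a drug that treats the disease"), the
  degree-weighted path count between a drug *s* and disease *t* is

  DWPC(s, t; m) = Σ over node-distinct paths π conforming to m of
  Π over steps (u→v) of (d(u) · d(v))^(−w),

  with *w* the damping exponent (w = 0 gives raw path counts). DWPCs for
  all pairs are computed by sparse degree-weighted adjacency products
  with exact node-repeat corrections up to length 3, verified against an
  exhaustive path-enumeration oracle.
* **Learning** — ElasticNet logistic regression (glmnet) on
  scaled/standardized DWPC and degree features, with 10:1 negative
  sampling; repeated 5-fold CV removes held-out TREATS edges before
  feature extraction, and time-split runs train on past approvals and
  test on future ones.
* **Evaluation** — AUROC/AUPRC, per-drug and per-disease holdout ranks,
  per-model z-scoring, and relative-approval-year performance curves
  with a 5-year rolling mean.
* **Ablations** — edge dropout (25/50/75/100%, replicated) and
  time-resolved edge replacement quantify each edge type's importance.
* **Synthetic studies** — a seeded generator produces dated hetnets and
  gold standards with planted, recoverable path-level signal, so the
  whole pipeline is testable without any licensed data source.

## Worked example

```r
library(hetpath)
library(dplyr)

study <- generate_synthetic_study(synth_config(seed = 42))
study$net
#> <hetnet> 124 nodes, 809 edges
#> node types: Anatomy (12), Chemicals & Drugs (60), Disorders (40), Phenomena (12)
#> metaedges: CDtDO (331), CDrtCD (148), DOawDO (120), AloCD (30), AloDO (30), CDafPH (150)
#> dated edges: 800 spanning 1950 - 2015
```

Repeated cross-validation with holdout-edge removal:

```r
cv <- cv_run(study$net, study$indications, model_config(repeats = 1, seed = 1))
glance(cv)
#> # A tibble: 1 × 4
#>   mean_auroc mean_auprc sd_auroc n_folds
#>        <dbl>      <dbl>    <dbl>   <int>
#> 1      0.909      0.398   0.0244       5

tidy(cv$last_model) |> arrange(desc(abs(estimate))) |> head(5)
#> # A tibble: 5 × 2
#>   term              estimate
#>   <chr>                <dbl>
#> 1 (Intercept)         -5.96
#> 2 dwpc_CDtDO           1.55
#> 3 dwpc_CDrtCDtDO       1.42
#> 4 dwpc_CDtDOawDO       1.24
#> 5 degree_drug_CDtDO    0.433
```

The mean holdout AUROC of 0.909 shows the classifier recovers the
planted associations, and the largest coefficients sit exactly on the
planted templates: the direct treatment edge, drug–drug similarity
(`dwpc_CDrtCDtDO`) and disease–disease similarity (`dwpc_CDtDOawDO`).

Time-resolved evaluation — train on approvals up to each network year,
test on later approvals:

```r
ts <- timesplit_run(study$net, study$indications, slice_grid(1960, 2005, 5),
                    model_config(repeats = 1, seed = 1))
tidy(ts)
#> # A tibble: 9 × 6
#>   network_year n_train_pos n_test_pos n_dropped auroc auprc
#>          <int>       <int>      <int>     <int> <dbl> <dbl>
#> 1         1965           6         13        21 0.608 0.446
#> 2         1970           8         14        18 0.553 0.387
#> 3         1975           9         21        10 0.507 0.308
#> 4         1980          13         25         2 0.608 0.555
#> 5         1985          21         18         1 0.667 0.515
#> 6         1990          26         13         1 0.550 0.253
#> 7         1995          28         12         0 0.793 0.568
#> 8         2000          33          7         0 0.986 0.924
#> 9         2005          39          1         0 0.95  0.2
```

Prospective AUROC sits far below the cross-validated 0.909 — the central
point of the time-resolved protocol. Pooling all year models via
z-scores (`standardize_probabilities()` + `relative_year_curve()`) shows
the decay with the approval-year offset, and
`autoplot()` methods plot each result type. Edge-importance ablations run
through `perturbation_plan()` / `run_perturbation_suite()`.

A thin command-line interface over the same functions (subcommands
`simulate`, `build`, `slice`, `features`) is installed at
`system.file("cli", "hetpath.R", package = "hetpath")`, and small example
input tables live under `system.file("extdata", package = "hetpath")`.

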