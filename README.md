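# dupfates

Joint inference of ancestral tissue-specific gene expression and the
evolutionary fate of gene duplicates on small paralog trees.

## The problem

When a gene duplicates, the pair of copies typically follows one of three
routes: **subfunctionalization** (SF — the copies partition the ancestral
role), **conserved function** (CF — both keep it, doubling dosage), or
**neofunctionalization** (NF — one copy keeps it, the other gains a new
role). Using the expression level of a gene in a single tissue as a
quantitative proxy for its function, the three fates become arithmetic
relations between an ancestor *x* and its duplicates *a*, *b*:

- SF: *x* = *a* + *b*
- CF: *x* = *a* = *b* (relaxed to *a* + *b* = 2*x*)
- NF: *x* = min(*a*, *b*), the gaining copy reaching at least 2*x*

Classifying a duplication event needs the ancestral level, and
reconstructing the ancestral level needs the fate — so `dupfates` solves
both jointly. Ancestral expression on a rooted paralog tree (branch
lengths in dS) is reconstructed by **nonparametric belief propagation**:
each internal node carries a 3-component Gaussian mixture (one component
per fate), updated over many iterations of fate-specific forward/backward
particle passing and EM re-fitting. Each duplication event is then
classified probabilistically from the normalized triple (*x*, *a*, *b*)
mapped to the feature plane (*u*, *v*) = (*x* − max(*a*, *b*),
*x* − min(*a*, *b*)), where each pure fate is a line segment and

&nbsp;&nbsp;&nbsp;&nbsp;p<sub>SF</sub> = d<sub>CF</sub>·d<sub>NF</sub> / (d<sub>CF</sub>·d<sub>NF</sub> + d<sub>SF</sub>·d<sub>NF</sub> + d<sub>CF</sub>·d<sub>SF</sub>)

with d<sub>•</sub> the Euclidean distances to the three segments (and
cyclically for CF, NF), so the probabilities sum to 1.

The package is intended for analyses of paralog families with tissue
expression panels — e.g. human three- and four-member families across
dozens of tissues — and ships a synthetic-tree generator with known fates
for validation.

## Worked example

```r
library(dupfates)

# the canonical 3-leaf tree: two duplicates at 50, a third paralog at 200
tr <- read_paralog_trees(text = "((g1:1,g2:1):1,g3:1);")[[1]]
tr <- set_leaf_values(tr, c(g1 = 50, g2 = 50, g3 = 200))

fit <- run_nbp(tr, nbp_config(M = 100, T = 200, seed = 1))
infer_fates(fit)[, c("node_index", "x", "a", "b",
                     "p_sf", "p_cf", "p_nf", "label")]
#> # A tibble: 2 × 8
#>   node_index     x     a     b   p_sf  p_cf  p_nf label
#>        <int> <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl> <chr>
#> 1          1 112.   73.5   200 0.096  0.477 0.427 CF
#> 2          2  73.5  50     50  0.539  0.304 0.156 SF
```

Node 2 (the younger ancestor) is estimated at 73.5 expression units; of
the three fate relations, the triple (73.5, 50, 50) lies closest to the SF
segment in the feature plane, so SF gets the highest probability (0.54). Node 1 (the root) is weakly
identified — a known property of the oldest node, which receives forward
evidence only — and is here a near coin-flip between CF (0.48) and NF
(0.43). Classifying a
known triple directly:

```r
classify_fate(70.3, 50, 50)[, c("p_sf", "p_cf", "p_nf", "label")]
#> # A tibble: 1 × 4
#>    p_sf  p_cf  p_nf label
#>   <dbl> <dbl> <dbl> <chr>
#> 1 0.479 0.350 0.170 SF
```

Benchmarking on trees with known fates:

```r
acc <- run_table1_experiment(n_datasets = 5, n_trees = 200, layers = 2,
                             config = nbp_config(M = 100, T = 200), seed = 1)
acc[, c("node_index", "mean_accuracy", "sd_accuracy")]
```

Genome-scale per-tissue runs with the expression noise floor (200), the
high-confidence cutoff (0.75) and a per-gene permutation control go
through `run_all()`; a thin command-line front end is installed at
`inst/cli/dupfates` (subcommands `classify`, `simulate`, `infer`, `run`).

See the vignette (`vignettes/duplicate-fate-inference.Rmd`) for the model,
the sampler's numerical safeguards, and the generator's scope.

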