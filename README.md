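# topoqsar

Topological QSAR modelling of PRMT1 inhibitors with antileukemic
activity, in tidyverse-flavoured R.

Protein arginine methyltransferase 1 (PRMT1) drives survival of
FLT3-ITD⁺ acute myeloid leukemia cells, and small-molecule PRMT1
inhibitors are an active line of drug discovery. `topoqsar` implements a
purely graph-theoretic (2D, conformation-free) structure–activity
pipeline for a series of 17 such inhibitors: every molecule is reduced to
its hydrogen-depleted molecular graph, descriptors are computed from the
adjacency and topological distance matrices, and two linear models score
activity. It is aimed at computational chemists who want a transparent,
fully reproducible descriptor engine plus the screening rules — no
commercial descriptor software in the loop.

## The models

Each compound is described by, among others:

* **Gálvez topological charge indices** `GGIk` — with `M = A·Q`
  (`A` adjacency, `Q[i,j] = 1/D[i,j]²` the reciprocal square distance
  matrix), `GGIk = Σ_{i<j} |M_ij − M_ji| · δ(D_ij, k)`; `JGIk` is the
  mean charge-transfer term over the atom pairs at distance `k`;
* **Kier–Hall connectivity indices** `ᵏχ_t` over path, cluster and
  path-cluster subgraphs, with valence variants (`X0v = Σ_i (δᵢᵛ)^{-1/2}`);
* constitutional counts `nDB` (non-aromatic double bonds) and `nN`
  (nitrogen atoms), and `Mv`, the mean carbon-scaled van der Waals
  atomic volume over all atoms including hydrogens.

Activity is modelled by two shipped linear equations:

```
DF    = −14.123 + 0.848·nDB + 1.680·nN − 38.327·GGI9 + 392.190·JGI4
pIC50 = −42.089 + 314.536·JGI4 − 25.006·GGI7 + 59.732·Mv + 0.450·X0v
```

with the activity bands `DF ≤ 0 → I`, `0 < DF < 1 → NC`, `DF ≥ 1 → A`
and the screening rule *candidate ⇔ 1 < DF < 5 and predicted
pIC50 > 9* (pIC50 = −log₁₀ IC50, IC50 in M/10⁵ units). The package also
refits both models from scratch — ordinary least squares with
leave-one-out Q², and a two-group canonical LDA with Wilks' λ and
Mahalanobis posteriors — and draws pharmacological distribution diagrams
(expectancy `Ea = a/(i+1)`, `Ei = i/(a+1)` along the DF axis).

## Worked example

```r
library(topoqsar)
library(tibble)

ex <- qsar_predict(tibble(
  id = c("5", "31d"),
  smiles = c("NC1=NC(NC2=CC=CC(NC(C3=CC=CC(NC4=CC=NC5=CC=CC=C54)=C3)=O)=C2)=CC(C)=N1",
             "CNCCN(CC1=CC=CC=C1SC2=CC=CC=C2Cl)C")))
ex[, c("id", "df", "pred_class", "pic50_pred", "candidate")]
#> # A tibble: 2 × 5
#>   id       df pred_class pic50_pred candidate
#>   <chr> <dbl> <chr>           <dbl> <lgl>
#> 1 5      3.74 A                5.04 FALSE
#> 2 31d    3.93 A                8.62 FALSE
```

Both compounds score in the active band (`DF` 3.74 and 3.93, class `A`);
neither passes the screening rule because the predicted potencies (5.04
and 8.62) stay below pIC50 = 9. The underlying descriptors are a
`compute_descriptors()` call away:

```r
d <- compute_descriptors(tibble(smiles = "CNCCN(CC1=CC=CC=C1SC2=CC=CC=C2Cl)C"))
round(d[, c("nDB", "nN", "JGI4", "GGI7", "Mv", "X0v")], 3)
#>     nDB    nN  JGI4  GGI7    Mv   X0v
#> 1     0     2 0.045 0.288 0.627 14.046
```

Refitting the regression on the packaged 16-compound training table
(`load_table1()`, outlier 17a excluded):

```r
train <- dplyr::filter(compute_descriptors(load_table1()), id != "17a")
glance(fit_ols(train, "pic50_exp", c("JGI4", "GGI7", "Mv", "X0v")))
#> # A tibble: 1 × 5
#>      r2    q2   see     n     p
#>   <dbl> <dbl> <dbl> <int> <int>
#> 1 0.883 0.767 0.723    16     4
```

A command-line front end over the same functions lives in
`inst/scripts/topoqsar.R` (`descriptors`, `predict`, `screen`, `fit`,
`pdd` subcommands).

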