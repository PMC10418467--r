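---
title: "Topological QSAR of PRMT1 inhibitors: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological QSAR of PRMT1 inhibitors: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(topoqsar)
library(dplyr)
```

## The modelling problem

`topoqsar` implements a two-stage topological structure–activity model
for a series of 17 PRMT1 inhibitors assayed against leukemia cell
proliferation. The premise of molecular topology is that a useful share
of structure–activity signal survives the reduction of a molecule to its
hydrogen-depleted graph: vertices are heavy atoms, edges are bonds, and
every descriptor is a function of the adjacency matrix $A$, the
shortest-path distance matrix $D$, and per-atom labels (element, implicit
hydrogen count, valence electrons). Nothing here uses 3D geometry,
conformers or charges from quantum calculations; that is both the
method's main limitation and the reason it is cheap, deterministic and
exactly reproducible.

Stage one is a linear discriminant function on four descriptors
(`nDB`, `nN`, `GGI9`, `JGI4`) that separates actives
(IC$_{50} \le 1$ M/10$^5$, uncensored) from inactives; its score bands
are $\mathrm{DF} \le 0$ inactive, $0 < \mathrm{DF} < 1$ non-classified,
$\mathrm{DF} \ge 1$ active. Stage two is a multilinear regression of
pIC$_{50}$ on `JGI4`, `GGI7`, `Mv` and `X0v` that quantifies potency.
A compound is a screening candidate when $1 < \mathrm{DF} < 5$ *and*
predicted pIC$_{50} > 9$, all strict inequalities; since the candidate
window sits inside the active band, every candidate is also classified
active. Both fitted equations ship with the package as JSON
(`eq1_model()`, `eq2_model()`) and are evaluated, not refit, by
`qsar_predict()`; `fit_ols()` and `fit_lda()` refit them from the data
when asked.

## Descriptor conventions

Descriptor values are only meaningful relative to a set of conventions,
and different software disagrees in small but consequential ways. The
conventions below were chosen so that the package, run end to end on the
packaged compound table, reproduces the published per-compound
discriminant scores and predicted potencies; each is exposed as an
argument so other conventions can be explored.

**SMILES and hydrogens.** The parser covers the Kekulé dialect the
compound table is written in (uppercase atoms, explicit `=`/`#` bonds,
branches, ring digits, bracket atoms with charge). Implicit hydrogens
follow SMILES normal-valence rules; explicit `[H]` vertices fold into
the neighbouring heavy atom *and still count toward its bonded valence*,
so `[H]C(R)R'` is a CH$_2$ — this matters for several compounds of the
series written in that style.

**Aromaticity** is perceived with a planarity-free Hückel rule on
5- and 6-membered simple cycles: an atom double-bonded to any ring atom
contributes one $\pi$ electron, a pyrrole-type N/O/S contributes two, a
carbon with only single bonds disqualifies its ring, an exocyclic
carbonyl carbon contributes zero without disqualifying, and a ring is
aromatic on a $4n+2$ count. This reproduces the intended split on the
study set — benzene/pyridine/pyrimidine/quinoline/pyrazole-type rings
aromatic, cyclohexadiene and saturated heterocycles not — which is
exactly what the non-aromatic double-bond count `nDB` needs. The
original study computed descriptors with closed-source commercial
software whose aromaticity model is undocumented; this rule is the
package's own convention, validated against the published scores.

**Charge indices.** `gk()` implements
$G_k = \sum_{i<j} |M_{ij} - M_{ji}|\,\delta(D_{ij}, k)$ with
$M = A\,Q$, $Q_{ij} = D_{ij}^{-2}$. For the normalized form `jk()` the
classical definition divides by $N-1$; the descriptor software behind
the published models instead divides by the *number of atom pairs at
distance $k$* (a mean charge-transfer term). The two agree on acyclic
graphs at $k = 1$ but diverge elsewhere, and only the pair-count
normalization reproduces the published discriminant column — across all
17 compounds, including the charged ring system, to within $\pm 0.003$.
It is therefore the default (`normalize = "mean"`), with
`normalize = "classic"` available. Orders are computed up to $k = 10$
because the shipped equations use `GGI9` and `GGI7`. The valence
variants weight the adjacency diagonal by carbon-referenced Pauling
electronegativities (`electronegativity_weights()`); no shipped model
uses them, and the weighting is a documented package convention rather
than a reproduction of any particular tool.

**Connectivity indices.** `chi_index()` follows Kier–Hall:
$^k\chi_t = \sum_j \prod_{i \in S_j} \delta_i^{-1/2}$ over connected
$k$-edge subgraphs of type path, cluster or path-cluster, with
$\delta$ the heavy-atom degree and
$\delta^v = Z_v - h$ for second-row atoms, $(Z_v - h)/(Z - Z_v - 1)$
beyond. Formal charge is not subtracted from $Z_v$, so a quaternary
nitrogen has $\delta^v = 5$; only the one charged compound of the series
is affected, and it is excluded from the regression anyway. Cyclic edge
subsets (rings) fall outside the three tree types and are not counted.
Differences $^kD_t = {}^k\chi_t - {}^k\chi_t^v$ and quotients
$^kC_t = {}^k\chi_t / {}^k\chi_t^v$ are included; a quotient with a zero
denominator is `NA` in the assembled vector and an error when requested
directly.

**Mean van der Waals volume.** `Mv` averages carbon-scaled atomic
volumes over *all* atoms, implicit hydrogens included. The default
table (`vdw_volume_table()`) uses $(r/r_C)^3$ with Bondi radii for the
heavy elements and the revised Rowland–Taylor hydrogen radius of
1.09 Å. The hydrogen entry dominates (most atoms in a drug-like molecule
are hydrogens) and was the key degree of freedom in matching the
published predicted-potency column: a free per-element least-squares
calibration against that column recovered the Bondi/1.09 Å volumes
almost exactly, so the principled radii — not the free-fit values — are
shipped. With them the 16 training predictions agree with the published
column to $\pm 0.006$ pIC$_{50}$.

## Model fitting choices

* **Censoring.** Right-censored IC$_{50}$ entries (`">20"`, `">5"`)
  enter the regression at their bound (pIC$_{50}$ upper bounds 3.699,
  4.301), keeping the training set at 16 after removing the outlier
  compound 17a. The published experimental pIC$_{50}$ column is stored
  verbatim; one entry (compound 25d, 8.959) is inconsistent with its own
  IC$_{50}$ (0.039 → 6.409) and appears to duplicate the following row,
  but the verbatim value is what the published fit used, so
  `load_table1()` keeps it and also provides `pic50_from_ic50` for
  comparison.
* **LDA.** `fit_lda()` computes the two-group canonical axis
  $S_W^{-1}(\bar x_A - \bar x_I)$, scaled to unit pooled within-group
  score variance and centred on the grand mean; Wilks'
  $\lambda = 1/(1+\text{eigenvalue})$, cross-checked in the tests
  against the $\det(W)/\det(T)$ definition and against `MASS::lda()`.
  Posteriors use Mahalanobis distances to the centroids with **equal
  priors** (the convention of the statistics package the original
  analysis used); canonical coefficients are defined only up to sign and
  scale, so comparisons with the shipped equation go through affine
  alignment of the score vectors.
* **Leave-one-out.** `loo_q2()` uses the hat-matrix identity
  $y_i - \hat y_{(-i)} = e_i/(1 - h_{ii})$, which is algebraically equal
  to refitting $n$ times; the tests assert equality with the naive
  oracle at $10^{-12}$.
* **Stepwise selection.** `stepwise_select()` is a deterministic greedy
  forward/backward partial-F procedure (defaults $F_{enter} = 3.84$,
  $F_{remove} = 2.71$, alphabetical tie-break, rank guard). It is a
  simplified stand-in for the black-box stepwise machinery of commercial
  statistics packages and is not expected to retrace the published
  variable choice.
* **Distribution diagrams.** `build_pdd()` bins discriminant scores in
  half-open intervals $[lo, lo + w)$ with default width 1 (the published
  figure's granularity is not readable, so the width is a package
  default, configurable) and computes $E_a = a/(i+1)$,
  $E_i = i/(a+1)$ per bin.

## What reproduces and what does not

Running the pipeline end to end (see `scripts/acceptance.R`):

* the discriminant column reproduces for all 17 compounds
  ($\pm 0.003$), and with it every predicted class, including the one
  non-classified compound;
* the predicted pIC$_{50}$ column reproduces to $\pm 0.006$ (training
  set) and $\pm 0.02$ (the excluded outlier);
* the extreme training residual (compound 25d, $-1.27$) reproduces;
* refitting the regression gives $R^2 = 0.883$ against the published
  0.898 — and applying the *published* coefficients to the *published*
  per-compound columns also yields $R^2 \approx 0.88$, so the package's
  refit is at least as self-consistent as the original report;
* the published $Q^2 = 0.863$ does **not** reproduce: the leave-one-out
  refit gives $Q^2 \approx 0.77$, and no variant explored (recomputed
  25d response, squared-correlation form of $Q^2$, single-compound
  exclusions) reaches 0.863. Likewise the claim that 56.3% of training
  residuals lie within one standard error is inconsistent with the
  published per-compound columns themselves, which give 12/16 = 75%.
  Both quantities are reported as computed.
* the published $F(4,15)$ statistic and the exact per-group
  classification percentages are not modelled (inconsistent degrees of
  freedom, and a stated 5-active count against 6 active labels in the
  table); the refit discriminant's posteriors are instead checked
  qualitatively — above 0.9 for every active, below 0.5 for every
  inactive, $\lambda = 0.172$ matching the published value.

## The synthetic generators

Property tests need inputs with known structure, generated in code:

* `random_molecular_graph()` builds connected random graphs (random
  spanning tree plus a Poisson number of extra edges), degree capped at
  4 and sizes kept at $\le 12$ atoms so the brute-force descriptor
  oracles (exhaustive subgraph enumeration, element-wise matrix sums)
  remain instantaneous; elements are drawn degree-compatibly from
  {C, N, O, S, Cl} with all bonds single. These graphs exercise
  isomorphism invariance and oracle equality, not chemistry: they have
  no aromatic systems, multiple bonds or charges, so parser- and
  aromaticity-level behaviour is covered separately by the fixture
  compounds.
* `synthetic_qsar_dataset()` draws $y = X\beta + \varepsilon$ with a
  standard-normal design — the data-generating model the regression
  stage assumes. It underpins coefficient-recovery (exact at
  $\sigma = 0$; RMSE $< 0.05$ at $\sigma = 0.1$, $n = 200$) and the
  monotone approach of $Q^2$ to 1 as noise vanishes.
* `synthetic_classification_dataset()` shifts class means `df_gap`
  apart along a chosen direction, giving separable groups for the LDA
  checks (perfect reclassification at a gap of 10 pooled SDs).

All generators are pure functions of their seed and restore the global
RNG state. Passing these tests shows the descriptor and model machinery
is correct on graphs and linear data of this kind; it does not certify
behaviour on chemistry the study set does not contain (stereochemistry,
isotopes, organometallics, macrocycles beyond 6-membered aromatic
perception, aromatic lowercase SMILES).

## Problem sizes and determinism

The full test suite runs on one CPU in a few minutes: oracle
equivalences use 10–40 random graphs of 2–12 atoms per property,
permutation invariance 500 graph/permutation pairs, and the model
recovery checks use $n \le 200$. Every stochastic test fixes its seed;
the acceptance script takes `--seed` for interface parity even though
its computations are deterministic. Descriptor computations are exact
matrix arithmetic; the only tolerance-bearing comparisons are against
$10^{-12}$ oracles and the published 3-decimal values.
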