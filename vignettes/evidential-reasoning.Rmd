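---
title: "Evidential reasoning for multi-source evidence fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential reasoning for multi-source evidence fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(erfusion)
```

## The problem

A decision-maker holds several bodies of evidence about the same object
— expert judgements, survey summaries, per-criterion assessments — each
expressed as a distribution of belief over a common, exhaustive set of
mutually exclusive propositions `θ_1 … θ_N` (the *frame of
discernment*). Two kinds of uncertainty complicate naive averaging:
evidence may be *incomplete* (a source assigns less than total belief,
leaving `p_Θ = 1 − Σ_n p_n` unassigned), and sources differ in
*importance*. The evidential reasoning (ER) approach handles both by
converting each weighted body into basic probability masses and
combining them recursively, keeping the two kinds of unassigned mass
separate throughout.

## The combination

With normalized weights `w_i` (any non-negative raw importances are
accepted and rescaled to sum to one), evidence `i` contributes

- `m_n = w_i p_{n,i}` of mass to each proposition,
- `m̃_Θ = w_i p_{Θ,i}` of *incompleteness* mass, and
- `m̄_Θ = 1 − w_i` of *weight-remainder* mass.

Two mass assignments `a` and `b` combine into

```
conflict = Σ_{n≠k} a_n b_k,   K = 1 / (1 − conflict)
a'_n = K (a_n b_n + a_n b_Θ + b_n a_Θ)        with x_Θ = x̃ + x̄
ã'_Θ = K (ã b̃ + ā b̃ + ã b̄)
ā'_Θ = K (ā b̄)
```

`K` restores unit total mass after each step. The operator is
commutative and associative, so the result does not depend on input
order; the implementation folds left-to-right purely to fix
floating-point reproducibility. After the last body, the
weight-remainder mass is normalized away:
`p_n = a_n / (1 − ā_Θ)`, `p_Θ = ã_Θ / (1 − ā_Θ)`, so the reported
beliefs and uncertainty always sum to one. The conflict sum is computed
as `(Σ a)(Σ b) − Σ a b`, which equals the literal double sum at `O(N)`
cost; the test suite checks the equality against a double-loop oracle.

Only singleton propositions plus the whole frame carry mass; belief on
other subsets of the frame, interval-valued beliefs, and per-source
reliability factors are out of scope.

```{r}
dbf <- rbind(c(0.9, 0, 0), c(0, 0.9, 0), c(0, 0, 0.9))
colnames(dbf) <- c("Cold", "Common pneumonia", "COVID-19")
er_fuse(dbf, weights = c(10, 8, 5))
```

## The alternative rules

`dempster_fuse()` is the classical unweighted rule: the same numerators,
renormalized by `1 − conflict`, with all residual mass treated as one
undifferentiated ignorance. With unit, un-normalized weights the ER
combination reduces to it exactly (`er_fuse(..., normalize = FALSE)`
exposes that reduction as a verification hook, and the acceptance suite
checks it on 1,000 random pairs at `1e-12`).

`yager_fuse()` and `murphy_fuse()` are cited in the multi-source fusion
literature but their formulas had to be adopted from the standard
references rather than a printed source: Yager adds the conflicting mass
to the frame instead of renormalizing (so the rule is total — complete
conflict yields total ignorance rather than an error), and Murphy
averages the `L` bodies component-wise and then Dempster-combines the
average with itself `L − 1` times. Two points are deliberate
assumptions, stated here because the reference behaviour is unpublished:
multi-body Yager is sequential pairwise in input order (the sequential
rule is order-dependent), and Murphy performs exactly `L − 1`
self-combinations.

ER and Dempster refuse complete conflict (normalizing denominator
`≤ 1e-12`, since exact zero is measure-zero in floats) with a structured
`conflict` error identifying the step; the CLI maps it to exit code 3.

## Tunable parameters

- **Weights** (`er_fuse`, dimensionless, no default): raw relative
  importances; normalized automatically at every fusion boundary.
- **`tol`** (belief-sum tolerance, default `1e-3`): inputs transcribed
  from percentages rounded to two decimals can sum to slightly more
  than 1 (one hospital row in the shipped validation data sums to
  0.9999, others to 1.0000; overshoot is equally possible). Sums in
  `(1, 1 + tol]` are rescaled onto the simplex, anything larger is a
  validation error, and negative ignorance after rescaling is clipped
  to 0. An additional fixed `1e-12` of slack keeps `tol = 0` usable in
  the presence of floating-point round-off.
- **Presentation precision** (CLI `--precision`, writers' `digits`,
  default 4): rounding is half-even and applied only at output
  boundaries; nothing is rounded internally.

## Multi-level fusion

A hierarchical multi-attribute framework is materialized as a directory
tree: each folder is an attribute holding `<FolderName>_combined.csv`
(objects as rows; a `Weight` column carrying the attribute's importance
among its siblings, constant down the column; one column per
proposition), internal folders hold subfolders, and leaf folders hold
`Evidence*.csv` files of the same per-object shape whose `Weight`
column is the evidence source's weight. Fusion is bottom-up and
per-object; results for every node are written back into its combined
file with an appended `Uncertainty` column (dropped again on re-load,
making repeated runs byte-identical).

Two choices here were genuinely open and are package decisions. First, a
child's residual uncertainty `p_Θ` is carried upward as
*incompleteness* of the child's evidence body at the parent (the body's
beliefs sum to `1 − p_Θ`), which is the ER framework's native treatment
of unassigned belief; the alternative — renormalizing it away — would
silently overstate the confidence of poorly supported branches. Second,
sibling weights are normalized within each parent independently, so
"all attributes equally important" yields equal sibling weights at
every level regardless of branching factor. Traversal is depth-first in
lexicographic folder order, which only affects log order.

## The random-evidence generator

`generate_random_evidence()` emulates panels of partially incomplete
sources: each row is uniform on the belief simplex scaled by `1 − u`,
`u ~ Uniform(0, incompleteness_max)` (default 0.3, a moderate level of
incompleteness comparable to the worked examples' 10% plus headroom),
with positive gamma-distributed weights whose inequality is set by
`weight_skew` (default 1, exponential — mimicking the 10/8/5-style
spread of the worked examples). It generates valid evidence by
construction, which is what the property suites need; it does **not**
emulate correlated sources, systematically biased raters, or near-total
conflict, so a green property suite establishes the algebraic contracts
(conservation, order invariance, non-negativity, rule reductions) — not
robustness to dependent real-world evidence, which the ER model itself
assumes away (sources are treated as independent and equally reliable).
The default test run exercises a few hundred random tables plus two
1,000-pair oracle loops; the scale is chosen to keep the suite fast and
is documented rather than tuned.

## Numerical choices

- Conflict computed via the product identity (`O(N)`), property-tested
  against the literal double loop.
- Complete-conflict threshold `1e-12` on the normalizing denominator.
- Fold order fixed left-to-right; intermediate `K` factors are recorded
  on the fusion state (`last_K`) for diagnostics.
- CSV round-trips: results are written at full double precision by
  default; `digits = 4` is presentation only.

## Known limitations

- Focal elements beyond singletons + frame are not representable.
- Per-evidence reliability (as distinct from importance weight) is not
  modelled.
- Sequential Yager over more than two bodies depends on input order.
- XLSX support covers the first worksheet only, and the multilevel
  directory protocol is CSV-only.
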