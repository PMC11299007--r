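# erfusion

Multi-source evidence fusion under uncertainty with the evidential
reasoning (ER) approach, for decision problems where several sources —
experts, survey instruments, assessment criteria — each distribute belief
over a common set of mutually exclusive propositions (a *frame of
discernment*) and must be combined into one defensible distribution.
Typical users are analysts in health decision support, quality
assessment and multi-criteria decision analysis.

## The model

Evidence *i* assigns belief degrees `p_{n,i} ∈ [0,1]` to propositions
`θ_1 … θ_N` with `Σ_n p_{n,i} ≤ 1`; the shortfall `p_{Θ,i} = 1 − Σ_n
p_{n,i}` is the evidence's *ignorance*. Given normalized source weights
`w_i`, each body becomes a basic probability mass assignment

```
m_{n,i} = w_i · p_{n,i}        (support for θ_n)
m̃_{Θ,i} = w_i · p_{Θ,i}        (ignorance from incompleteness)
m̄_{Θ,i} = 1 − w_i              (ignorance from withheld weight)
```

and the masses are combined recursively; each step renormalizes by
`K = 1 / (1 − conflict)`, where the conflict is the product mass on
disjoint proposition pairs. After the last step, the weight-remainder
mass `m̄_Θ` is normalized away, giving combined beliefs `p_n` and a
residual uncertainty `p_Θ` with `Σ p_n + p_Θ = 1`. With unit weights the
combination reduces exactly to Dempster's rule; Yager's rule
(conflict → ignorance, no renormalization) and Murphy's averaging rule
are also provided. See `vignette("evidential-reasoning")` for details
and assumptions.

## Worked example

Three clinicians, with importances 10, 8 and 5, each put 90% belief on a
different diagnosis for the same patient:

```r
library(erfusion)
dbf <- rbind(c(0.9, 0, 0), c(0, 0.9, 0), c(0, 0, 0.9))
colnames(dbf) <- c("Cold", "Common pneumonia", "COVID-19")
er_fuse(dbf, weights = c(10, 8, 5))
#> <fusion_result: ER>
#>             Cold Common pneumonia         COVID-19      Uncertainty
#>           0.4332           0.3071           0.1639           0.0959
```

The fused distribution favours the highest-weighted source's diagnosis
(cold, 0.4332) but retains substantial belief on the alternatives, and
0.0959 of belief stays unassigned — the three sources are incomplete
(each left 10% unassigned) and none carries full weight.

The same run from a CSV evidence table, and the other rules:

```r
f <- system.file("extdata", "diagnosis.csv", package = "erfusion")
run_from_file(f)                      # ER (default)
run_from_file(f, "dempster")          # weight column ignored, with warning
```

Hierarchical assessment frameworks stored as a directory tree (one
folder per attribute, leaf folders holding `Evidence*.csv` files, every
folder holding a `<name>_combined.csv`) are fused bottom-up:

```r
multilevel_fuse("path/to/Objects")    # rewrites all *_combined.csv files
```

## Command line

```sh
Rscript inst/cli/fuse.R --input diagnosis.csv --algorithm er \
    --output out.csv --plot chart.png --precision 4
Rscript inst/cli/multilevel.R --root path/to/Objects
```

Exit codes: 0 success, 2 validation/unknown algorithm, 3 complete
conflict, 4 I/O, 5 internal.

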