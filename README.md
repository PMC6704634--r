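# bgsc — Bayesian gene selection for nested knockdown designs

`bgsc` predicts which genes a stimulus regulates through a receptor route
that **no single treatment isolates**. The motivating case is EGF
signalling through the truncated EGFR splice variants II–IV: one siRNA
silences only the full-length variant I, another silences all variants,
so the effect of isoforms II–IV is visible only as the *difference*
between knockdowns — a nested design for which standard pairwise
differential-expression contrasts have no direct answer.

The package is for transcriptomics analysts working with such nested
RNAi / knockout panels: it classifies each gene's expression profile into
the distinct regulation patterns the design can distinguish, and selects
high-confidence targets of the route of interest.

## The method

**Step 1 — design reduction.** With `k` regulator channels there are
`2^k` regulation modes (which channels drive the gene). Under each
treatment, a mode responds to the stimulus iff at least one of its
channels survives the knockdown. Modes with identical response vectors
are confounded and collapse into *pattern groups*; for the EGFR design
(channels: isoform I, isoforms II–IV, other receptors; treatments:
control, siRNA against variant I, siRNA against all variants) the eight
modes A–H reduce to four groups with indicator vectors over the six
conditions x1..x6:

| group | modes     | g1..g6          | interpretation                        |
|-------|-----------|-----------------|---------------------------------------|
| a     | A         | 0 0 0 0 0 0     | not regulated by EGF                  |
| b     | B,E,F,G   | 0 1 0 1 0 1     | regulation reaches through other receptors |
| c     | C,H       | 0 1 0 1 0 0     | via isoforms II–IV, not other receptors |
| d     | D         | 0 1 0 0 0 0     | via isoform I only                    |

**Step 2 — per-gene Bayesian model selection.** Each group `z` is a
normal model for the profile `x`: one shared variance, one mean for the
`g=0` conditions and (for b–d) a second mean for the `g=1` conditions,

    p(x | z, θz) = ∏ₙ N(xₙ | μ_{z gₙ}, σz),

with closed-form estimates (class means; σ̂² = SSE/5 for group a,
SSE/4 for b–d). Marginal likelihoods are approximated by the Bayesian
Information Criterion,

    p(x | z) ∝ p(x | z, θ̂z) / √n^|θz|,   n = 6, |θa| = 2, |θb..d| = 3,

and combined with priors p(a)=0.70, p(b)=p(c)=p(d)=0.10 via Bayes'
formula; each gene gets the maximum-posterior group. Putative targets of
isoforms II–IV are the group-c genes with posterior strictly above 0.75,
reported with log2 fold change μ̂c1 − μ̂c0 and Satterthwaite standard
errors.

## Worked example

```r
library(bgsc)
sim <- simulate_profiles(2000, seed = 20)   # known ground truth
fit <- bgsc(sim$x)                          # EGFR design, default priors
fit
#> Bayesian gene selection fit
#>   genes:      2000
#>   conditions: 6 (stimulus EGF)
#>   priors:     a=0.7, b=0.1, c=0.1, d=0.1
#>   assigned per group:
#>    a    b    c    d
#> 1190  286  255  269
```

2000 simulated genes (70% unregulated, effects of 1–2 log2 units, noise
0.2): 1190 land in group a and 255 in group c, the isoform II–IV group.
Selection and validation-style reporting:

```r
head(select_targets(fit, "c"), 3)
#>    gene_id posterior    log2fc         se       df direction selected
#> 1 gene0671 0.9999994 -1.876172 0.03241712 3.000000      down     TRUE
#> 2 gene0985 0.9999991 -1.536502 0.03072066 3.981516      down     TRUE
#> 3 gene1323 0.9999979 -1.501674 0.03761147 3.786051      down     TRUE
```

Each row is a gene assigned to group c: its posterior, the log2 fold
change between regulated and baseline class means, the Satterthwaite
standard error and direction call; `selected` marks posteriors above
0.75 (204 genes here). Against the simulation truth,
`evaluate_recovery(sim$truth, fit)` reports 0.894 overall accuracy —
regulated genes are recovered almost perfectly, while ~16% of unregulated
genes leak into regulated groups, a scale-free property of BIC selection
at n = 6 (see the methods vignette).

The arithmetic of the classification step on a real profile's maximized
group likelihoods (0.004, 0.035, 4.22, 0.012):

```r
lmarg <- bic_log_marginal(log(c(a=0.004, b=0.035, c=4.22, d=0.012)),
                          c(2, 3, 3, 3), 6)
round(exp(lmarg), 3)
#>     a     b     c     d
#> 0.001 0.002 0.287 0.001
round(group_posteriors(lmarg, c(a=.7, b=.1, c=.1, d=.1)), 3)
#>     a     b     c     d
#> 0.016 0.008 0.973 0.003
```

The gene is assigned to group c with posterior 0.973 — a putative
isoform II–IV target.

A command-line interface covers the same pipeline
(`design`, `classify`, `simulate`, `evaluate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","bgsc.R",package="bgsc"))')" \
  classify --input expr.tsv --design egfr-default --out results.tsv
```

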