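# alignhmm

Alignment of paired, unequal-length time-course gene expression profiles
with a gap-position hidden Markov model, and classification of
developmentally driven genes by alignment quality.

## The problem

When the same developmental process is profiled at two locations — the
motivating case is grape berry development measured weekly at two
vineyards, over a 19-week and a 17-week season — every gene yields a *pair*
of expression profiles of different lengths. The series are too sparse for
interpolation-based alignment (dynamic time warping produces pathological
many-to-one mappings at weekly resolution), yet an alignment is needed both
to integrate the two series into one profile per gene and to ask a
biological question: genes whose profiles share the same shape at both
sites are likely controlled by the developmental program, while genes that
fail to align are more plausibly responding to site-specific cues.

## The model

Each pair of `[0, 1]`-scaled profiles $(w_{1:T},\, c_{1:T_2})$ with
$T = 19$, $T_2 = 17$ is modelled as two emission sequences of **one**
latent state sequence $S_{1:T}$, $S_t \in \{1,\dots,N\}$, with initial
distribution $a$, transition matrix $A$ and Gaussian emissions
$b(x \mid \mu_j, \sigma_j^2)$. The long profile occupies every state
position; the short profile skips two **gap positions**
$1 < g_1 < g_2 \le T$ (the first time points are constrained to align).
The pair's log-likelihood marginalises over state sequences with two
Gaussian factors at doubly observed positions and one at gaps. Each gene
has its own state sequence, but $\lambda = \{a, A, B\}$ and $(g_1, g_2)$
are common to all genes and estimated by pooling all pairs, in two steps:

1. **Pooled Baum–Welch** over all individual profiles from both sites,
   ignoring the pairing (robust: non-alignable pairs cannot bias it), with
   the variance floor $\sigma_j^2 \ge 0.001$;
2. **Exhaustive grid search** over all $\binom{T-1}{2} = 153$ gap pairs,
   maximising the total alignment log-likelihood at the fixed
   $\hat\lambda$.

Alignment quality per pair is the **Hamming distance** $H$ between the
joint Viterbi path and the two individually decoded paths (0 = perfect
agreement, up to $T + T_2 = 36$); pairs with $H \le 10$ are classified as
developmental.

## Worked example

Simulate 1000 profile pairs from the default 5-state regime, 30% of them
contaminated (non-alignable), then fit, diagnose and classify:

```r
library(alignhmm)

dat <- simulate_alignment_data(1000, contamination = 0.3, seed = 42)
fit <- fit_two_step(dat$pairs, n_states = 5)
fit$gaps
#> <gap_search> 153 candidate gap sets over 1000 pairs
#>   best gaps: (2, 11)  log-likelihood -22786.7
```

The grid search recovers the generating gap positions (2, 11) despite the
contamination. The pooled parameter estimate recovers the generating
emission distributions (means 0, 0.25, 0.5, 0.75, 1; variance 0.01):

```r
tidy(fit)
#> # A tibble: 5 × 4
#>   state initial_prob    mean variance
#>   <int>        <dbl>   <dbl>    <dbl>
#> 1     1        0.195 0.00422  0.0105
#> 2     2        0.200 0.251    0.00997
#> 3     3        0.199 0.498    0.0109
#> 4     4        0.220 0.754    0.0100
#> 5     5        0.186 1.00     0.0101
```

Per-pair diagnostics and the Hamming-distance classification
(threshold $H \le 10$):

```r
d <- diagnose_pairs(dat$pairs, fit$hmm$params, gaps = fit$gaps$best_gaps)
head(d[, c("gene_id", "loglik", "hamming", "label")], 4)
#> # A tibble: 4 × 4
#>   gene_id   loglik hamming label
#>   <chr>      <dbl>   <int> <chr>
#> 1 gene0001    8.80       5 developmental
#> 2 gene0002  -94.3       22 non-developmental
#> 3 gene0003 -152.        23 non-developmental
#> 4 gene0004   11.9       2 developmental

table(d$label)
#>     developmental non-developmental
#>               691               309
```

Well aligned pairs have high log-likelihood and small $H$; the 309 pairs
classified non-developmental track the 300 truly contaminated ones.
Against the ground-truth flags the classifier is essentially perfect on
this synthetic set:

```r
roc_hamming(d$hamming, !dat$truth$contaminated)
#> <hmm_roc> AUC = 0.9999571  ( 700 positive / 300 negative )
```

`autoplot()` methods draw the gap-likelihood heat-map
(`autoplot(fit$gaps)`) and the ROC curve; `align_pairs()` returns the
average-profile and joint-Viterbi common representations for downstream
analysis; `preprocess_pairs()` takes replicate-level intensity tables
through averaging, the 2-fold-change filter and per-profile scaling. A
command-line interface over the same functions (subcommands `preprocess`,
`fit`, `align`, `diagnose`, `simulate`, `robustness`) is installed at
`system.file("cli", "alignhmm.R", package = "alignhmm")`.

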