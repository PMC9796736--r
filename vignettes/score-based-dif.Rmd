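---
title: "Score-based tests of measurement invariance for 2PL/3PL models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based tests of measurement invariance for 2PL/3PL models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
set.seed(1)
```

```{r setup}
library(scoredif)
```

## The problem

An item response model is *measurement invariant* when the same item
parameters describe every respondent. Differential item functioning (DIF)
breaks invariance: some items behave differently for respondents with
different values of a person covariate (age, cohort, language, ...), which
biases ability comparisons across those respondents. scoredif implements
*score-based* invariance tests: instead of refitting the model for every
candidate split of the covariate, it fits the model **once** under the null
hypothesis of invariance and asks whether the case-wise likelihood score
contributions, ordered by the covariate, fluctuate like noise or drift
systematically.

## Model

Responses are binary. The three-parameter logistic (3PL) model in
slope–intercept form gives person $i$ with ability
$\theta_i$ probability

$$
P_j(\theta_i) \;=\; c_j + (1 - c_j)\,
  \operatorname{logit}^{-1}(a_j \theta_i + d_j)
$$

of solving item $j$, with slope $a_j > 0$, intercept $d_j$ and
pseudo-guessing probability $c_j \in [0, 1)$; the 2PL model is the
restriction $c_j = 0$. Abilities are integrated out over a fixed
61-node quadrature grid on $[-6, 6]$ with renormalised normal weights.

Two estimation routes are available:

* **MML** — marginal maximum likelihood; and
* **MAP** — maximum a posteriori with independent item-parameter priors.
  The shipped `prior_agreeing()` uses log-normal LN(0, 0.0625) slopes,
  standard normal intercepts and Beta(4, 45) guessing parameters
  (its Beta shapes are configurable); `prior_noninformative()` uses
  diffuse N(1, 10) / N(0, 10) / Beta(1, 1) densities. The 3PL likelihood
  is poorly behaved in small samples, so a guessing prior is often
  needed for stable estimates.

Both routes run an EM phase followed by a quasi-Newton polish of the
marginal objective using the analytic score vector. The polish matters for
the tests below: at an MML optimum the case-wise scores sum to (numerically)
zero, and at a MAP optimum they sum to minus the log-prior gradient —
identities the test machinery relies on.

With a `group` column, a multiple-group model adds *impact*: each
non-reference group gets its own ability mean and variance (the reference
group is fixed at N(0, 1)) while item parameters stay constrained equal.
Impact is then part of the null model, so ability differences between
groups do not masquerade as DIF.

## The cumulative score process

Let $\hat\psi_i$ be the gradient of person $i$'s log marginal likelihood in
the stacked item parameters, evaluated at the fitted values, and
$\tilde\psi_i$ its globally centred version. With persons sorted by the DIF
covariate, the decorrelated cumulative sum process is

$$
\Psi(t) \;=\; N^{-1/2} \sum_{i \le \lfloor Nt \rfloor}
  \hat V_{g(i)}^{-1/2}\, \tilde\psi_i , \qquad t \in [0, 1],
$$

where $\hat V$ is either the pooled covariance
$N^{-1}\sum_i \tilde\psi_i \tilde\psi_i^\top$ or, in the group-wise
variant, each group's own covariance of the globally centred scores.
Under invariance each component of $\Psi$ behaves asymptotically like a
Brownian bridge; DIF aligned with the covariate produces systematic
excursions.

Two reductions of the process to a statistic are implemented:

* **DM** (double maximum), $\max_{i,j} |\Psi(i/N)_j|$ — suited to
  continuous covariates; and
* **LM$_{uo}$** (unordered Lagrange multiplier),
  $\sum_{l} \sum_j \{\Psi(t_l)_j - \Psi(t_{l-1})_j\}^2 / (t_l - t_{l-1})$
  over the category boundaries $t_l$ of a categorical covariate
  (an unweighted variant is available via `weighted = FALSE`).

## Two p-value engines

**Asymptotic (pooled).** With pooled decorrelation the process is tied
down at $t = 1$ and the closed-form references apply: the DM statistic is
compared against the supremum of $k$ independent Brownian bridges (via the
Kolmogorov distribution and $p = 1 - (1 - p_1)^k$), the weighted
LM$_{uo}$ statistic against $\chi^2_{k(m-1)}$ with $m$ covariate
categories.

**Simulation.** The asymptotic route ignores two finite-sample facts: with
multiple groups the group-wise covariances differ, and the group-wise
decorrelated process need not end at zero. The simulation engine therefore
draws $R$ replicates of $N$ iid standard normal $k$-vectors $s_i$, shifts
them as $\tilde s_i = s_i - \bar s + \Psi(1)/\sqrt N$ so every simulated
path shares the observed start *and end* point, recomputes the statistic on
each simulated path, and reports the add-one p-value
$(1 + \#\{T_{\mathrm{sim}} \ge T_{\mathrm{obs}}\}) / (R + 1)$. Standard
normal draws are already decorrelated, so no further transform applies.
The engine is deterministic given its `seed` and never touches the session
RNG.

## Worked example

Simulate a 2PL dataset with intercept DIF on one fifth of the items,
related to a two-category covariate:

```{r example}
dat <- sim_dataset(n_persons = 1000, n_items = 10, model = "2PL",
                   covariate = "categorical", dif = "intercept",
                   direction = "unbalanced", seed = 42)
attr(dat, "truth")$dif_items

res <- dif_test(dat, covariate = "covariate", model = "2PL", method = "MML")
res
tidy(res)
```

The process plot localises the signal:

```{r plot}
library(ggplot2)
autoplot(res)
```

The simulation engine reuses the fit:

```{r sim-engine}
res_sim <- dif_test(dat, covariate = "covariate", model = "2PL",
                    method = "MML", engine = "simulation", R = 500,
                    seed = 7, fit = res$fit)
tidy(res_sim)
```

And a null dataset is (correctly) not rejected:

```{r null}
dat0 <- sim_dataset(n_persons = 1000, n_items = 10, model = "2PL",
                    covariate = "categorical", seed = 43)
tidy(dif_test(dat0, covariate = "covariate", model = "2PL", method = "MML"))
```

## Monte Carlo study driver

`study_grid()` crosses design conditions (model, sample size, covariate
type, impact, DIF target and direction, estimation route, engine) and
`run_study()` tabulates rejection rates over replicates, with per-replicate
RNG streams that make every cell reproducible in isolation and independent
of the worker count:

```{r study, eval = FALSE}
grid <- study_grid(model = "2PL", n_persons = c(500, 1000),
                   n_items = 10, covariate = "categorical",
                   impact = FALSE, dif = c("none", "intercept"),
                   estimation = "MML", engine = "pooled")
run_study(grid, reps = 200, seed = 1)
```

(Not run here: a grid of this size takes a few minutes.)

## Design notes and limitations

* **Quadrature, not adaptive integration.** A fixed 61-node grid on
  $[-6, 6]$ keeps every fit deterministic and makes the score identities
  exact at the discretised optimum. Abilities far outside $\pm 6$ are not
  represented.
* **EM plus polish.** EM alone approaches the optimum slowly near the end;
  the quasi-Newton polish drives the projected gradient below $10^{-3}$ so
  the score identities hold to the tolerance the tests assume. Parameters
  can legitimately end on their box bounds (notably 3PL guessing values at
  the lower bound under MML); there the identity holds for the projected
  gradient only, which is one practical argument for a guessing prior.
* **Item-parameter scores only.** In multiple-group fits the impact
  parameters are estimated and their scores are computed (for gradient
  diagnostics), but the invariance tests use the item-parameter components
  only.
* **Binary responses, no missing data.** Polytomous models and missing
  responses are out of scope.
* **Guessing DIF is hard.** Power against DIF in $c_j$ is much lower than
  against slope or intercept DIF at comparable sample sizes; this is a
  property of the statistics, not of the implementation.
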