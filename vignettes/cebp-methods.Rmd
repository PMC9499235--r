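---
title: "Estimating causal effects of somatic mutations on cancer biological processes"
author: "cebp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects of somatic mutations on cancer biological processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cebp)
```

## The problem

Tumor cohorts carry hundreds of recurrently mutated genes, most of them
passengers. Association tests between a gene's mutation status and a
phenotype are confounded twice over: by the *observed* mutation background
(mutations co-occur through shared mutational processes) and by *unobserved*
drivers such as micro-environment stress that influence both a gene's chance
of mutating and the phenotype itself. `cebp` estimates the **average
treatment effect (ATE)** of a single gene's mutation status $M \in \{0,1\}$
on the activity $Y$ of a cancer biological process (e.g. DNA replication or
the epithelial–mesenchymal transition),

$$\mathrm{ATE} = \mathbb{E}\left[Y_i(m=1) - Y_i(m=0)\right],$$

under a structural causal model in which a latent confounder $Z$ drives the
observed mutation background $X$ (the binary mutation matrix of the other
genes), the treatment $M$, and — together with $M$ — the outcome $Y$. $X$
plays a double role: it is an observed confounder and a *proxy* for $Z$,
which makes the posterior over $Z$ recoverable from data.

The package has two stages: a per-sample **activity score** built from
expression data (the outcome $Y$), and a **variational-autoencoder causal
model** that learns $Z$ from $(X, M, Y)$ and predicts both potential
outcomes for every sample.

## Stage 1: process activity by core-gene regression

For a pathway with $P$ genes and expression matrix $U \in
\mathbb{R}^{N\times P}$ we compute the Pearson correlation matrix $R$ with
two-sided $p$-values $S$ (from the $t$ transform with $N-2$ degrees of
freedom), then score each gene by its significance-gated correlation sum

$$g^{\mathrm{scor}}_j = \sum_{i \ne j} r_{ij}\,\mathbf{1}[s_{ij} < \alpha],
\qquad \alpha = 10^{-3},$$

and keep the $\lfloor P/2 \rfloor$ genes with the highest scores as **core
genes**. The per-sample activity is the scalar regression coefficient
linking the sample's core-gene vector $u$ to the cohort-mean core profile
$K$:

$$y_i = \arg\min_y \lVert y\,u_i - K \rVert^2 = \frac{\langle u_i,
K\rangle}{\langle u_i, u_i\rangle}.$$

Three numerical choices deserve a note:

* **Regression direction.** The definition above (the package default,
  `activity_direction = "as_printed"`) scales *inversely* with the sample:
  doubling a sample's core expression halves its activity
  ($y(cu) = y(u)/c$). The `reversed` option minimizes
  $\lVert u_i - y K\rVert^2$ instead and scales proportionally. Both are
  exposed because the verbal description of the score ("regression
  coefficient between the sample and the mean profile") does not pin down
  regressand versus regressor; the direction used is recorded in the
  output's provenance sidecar. All relative statements (rankings,
  group comparisons) are unaffected up to sign.
* **Diagonal and sign.** The self-correlation $r_{jj}=1$ is excluded from
  the score: it would add the same constant to every gene and cannot change
  the selection. Correlations are summed *signed*; a gene strongly
  anti-correlated with the rest lowers its own score. An absolute-value
  variant was considered and rejected to keep the printed definition.
* **Degenerate genes.** Zero-variance genes get $r=0$, $p=1$ against all
  partners, so they can never pass the significance gate; all-zero samples
  are reported as errors rather than producing infinite activities.
* **Ties** in core selection are broken by ascending gene index, making the
  selection deterministic.

## Stage 2: the variational causal model

With the observations $(x_i, m_i, y_i)$, the generative model is

$$p(z) = \mathcal{N}(0, I_d), \quad
p(x|z) = \prod_j \mathrm{Ber}(\sigma(f_x(z)_j)), \quad
p(m|z) = \mathrm{Ber}(\sigma(f_m(z))),$$
$$p(y|z,m) = \mathcal{N}\!\left(m\,f_{y_1}(z) + (1-m)\,f_{y_0}(z),\;
\varepsilon^2\right),$$

with a fixed outcome standard deviation $\varepsilon$. The approximate
posterior $q(z|x,m,y)$ is a diagonal Gaussian whose parameters come from a
shared representation $g(x,y)$ followed by arm-specific heads $f_0/f_1$
(softplus keeps the standard deviations positive). Two auxiliary networks
$q(m|x)$ and $q(y|x,m)$ are trained alongside so the model can infer the
posterior when $y$ or $m$ is withheld. Main networks use `hidden_depth`
ELU hidden layers of `hidden_width` units (defaults 3 × 200); the
treatment networks $q(m|x)$ and $p(m|z)$ use a single hidden layer. A
technical note: a literal Bernoulli parameterized by an ELU output is not a
valid probability map (ELU ranges over $(-1,\infty)$), so $f_m$ uses ELU
hidden activations with a final sigmoid.

Training minimizes the negative ELBO

$$-\sum_i \mathbb{E}_{q}\left[\log p(x_i|z) + \log p(m_i|z) + \log
p(y_i|m_i,z)\right] + \mathrm{KL}\!\left(q(z|x_i,m_i,y_i)\,\Vert\,
\mathcal{N}(0,I)\right) - \log q(m_i|x_i) - \log q(y_i|x_i,m_i)$$

with the Gaussian KL in closed form (variance reduction over a Monte Carlo
KL; identical in expectation), one reparameterized draw per step, and Adam
(learning rate $10^{-3}$, weight decay $10^{-4}$ applied as an L2 term
inside the update). Data are split 70/10/20 into train/validation/test by a
seeded shuffle; early stopping monitors the validation objective and the
parameters of the best validation epoch are returned. Parameters are
tracked as an exponential moving average over epochs (Polyak averaging,
decay 0.9): the outcome heads oscillate noticeably from epoch to epoch late
in training, and validating/returning the averaged parameters removes that
oscillation from the final estimate without changing what is being
optimized. The validation
objective is evaluated with a reparameterization draw *fixed once per run*:
with a fresh draw each epoch, Monte Carlo noise (not model quality)
dominates epoch-to-epoch differences and triggers patience far too early.

After training, both potential outcomes are predicted for every sample by
drawing `n_mc_samples` (default 100) latents from the posterior conditioned
on the sample's observed $(x, y, m)$ and averaging each outcome head over
the draws; the ATE is the mean of $\hat y_i(1) - \hat y_i(0)$ over **all**
$N$ samples (the $1/N$ form of the estimand; a flag restricts to the test
split). Conditioning on the observed $y, m$ is the default inference route;
imputing them through the auxiliary networks is available for samples
without outcomes.

### The fixed outcome variance matters

$\varepsilon$ is not a nuisance constant: it controls whether the latent
code is tempted to memorize outcome noise. If $\varepsilon$ is at or below
the true residual noise level, encoding a sample's noise $r$ into a spare
latent dimension buys $r^2/(2\varepsilon^2)$ nats of reconstruction while
costing about $r^2/2$ of KL — a flat or profitable direction of the
objective. The result is a posterior that "explains" outcome noise through
arm-specific channels, and because each outcome head is trained only on its
own arm, the cross-arm (counterfactual) predictions inherit systematic,
run-dependent offsets: we observed inflated and unstable ATEs exactly in
this regime. The package therefore defaults to $\varepsilon = 2$ —
comfortably above the noise level of a unit-scale outcome, making noise
memorization strictly unprofitable; the value is configurable
(`outcome_sd`) and recorded in provenance.

### Replicates and seeds

ATEs are reported as mean ± sample standard deviation over
`n_replicates` (default 10) independent training runs with seeds
`base_seed + 0..R-1`, the convention used for all reported effects. In
`rank_mutations()` each candidate gene's replicate seeds are offset by a
fixed fold of its candidate index so no two genes share network
initializations.

## The synthetic-data generator

Because real cohort claims require protected data, validation rests on a
generator that realizes the assumed causal structure with known ground
truth:

* `simulate_confounded()`: $z_i \sim \mathcal{N}(0, I_d)$ ($d=5$),
  proxies $x_{ij} \sim \mathrm{Ber}(\sigma(a_j + b_j^\top z_i))$ over
  $K=50$ genes, treatment $m_i \sim \mathrm{Ber}(\sigma(-0.5 + c^\top
  z_i))$ and outcome $y_i = \tau m_i + w^\top z_i +
  \mathcal{N}(0, 1)$ for $N = 2000$ samples. The true ATE is exactly
  $\tau$ (default 0.5). Treatment and outcome loadings are aligned
  ($\lVert c\rVert = 0.8$, $\lVert w\rVert = 0.4$), which biases the naive
  difference in means by $\approx 0.28$ — verified against a $10^6$-draw
  Monte Carlo oracle of the generative law, not against any fitted model.
  Proxy loadings ($\lVert b_j\rVert \approx 3$) make $Z$ recoverable from
  $X$: this is the proxy-sufficiency assumption of the causal model made
  concrete. With weak proxies (e.g. $\lVert b_j\rVert = 1.5$) the linear
  $R^2$ of $w^\top z$ given $X$ is only 0.66 and *no* estimator — the
  package's or any other — can close more than about two-thirds of the
  naive bias; the default was chosen so that the scenario actually tests
  deconfounding rather than an identification impossibility. Baseline
  logits $a_j$ are spread so gene mutation rates range over roughly
  1–40%, honoring the pipeline's 1% rate floor.
* `simulate_pathway()`: a planted block of $\lfloor P/2\rfloor$ core genes
  shares a per-sample factor $t_i \sim \mathcal{N}(0,1)$ with loading 1.8
  against noise sd 0.2 (strong preset, signal-to-noise 9) on a baseline of
  10 expression units; non-core genes are independent noise. Expression is
  kept nonnegative by a constant shift, which preserves all correlations
  exactly. Core-gene selection should recover the planted block and the
  estimated activity should track $t_i$ (inversely, under the default
  direction).
* `simulate_cohort()`: a full mutation table with named candidate genes of
  specified true effects plus background proxies, and the activity they
  generate — the end-to-end ranking scenario.

What the generator does *not* emulate: mutational signatures, gene length
effects, expression normalization artifacts, subclonal structure, or
nonlinear outcome surfaces. Passing tests show the machinery recovers known
effects under the model's own assumptions (linear-Gaussian outcome, proxy
sufficiency); they do not certify TCGA-scale biology.

## Candidate selection and group comparison

Candidates are chosen by mutation rate — either the top-$k$ genes (the
top-200 convention for large cohorts) or all genes above a rate threshold
(7% or 1% conventions) — and every treatment or confounder gene must clear
a 1% mutation-rate floor. For each candidate, the observed confounder
matrix contains the 200 highest-rate remaining genes (fewer, with a
warning, in small tables). Reported alongside each ATE is a Mann–Whitney U
comparison of activity between mutated and non-mutated groups (exact
enumeration for min(n) ≤ 8 without ties, otherwise the normal approximation
with midrank ties and continuity correction; raw two-sided p-values, as is
conventional for this comparison — a Benjamini–Hochberg column can be added
by the caller).

## Problem sizes used by the test-suite and acceptance script

The package defaults are the reference settings of the method (width 200, latent 20,
up to 300 epochs). The automated checks run a documented desk-scale
profile — hidden width 64, batch 256, at most 250 epochs, patience 30,
5 training seeds, $N=2000$, $K=50$ — sized so desk-scale validation stays
fast while leaving every scientific property intact. The acceptance script regenerates all inputs from its `--seed` and
recomputes every reported number at run time.

## Known limitations

* Single-gene treatments only; bundled mutation sets are out of scope.
* The ATE is on the activity scale of stage 1, whose absolute magnitude
  depends on the regression direction; comparisons across pathways should
  use ranks or signs, not raw magnitudes.
* Individual-level treatment effects are predicted internally but no
  confidence intervals are attached to them; only replicate spread of the
  cohort ATE is reported.
* The VAE's deconfounding is as good as the proxy information in $X$; with
  weak proxies residual confounding is irreducible and the estimate
  degrades gracefully toward the naive contrast.

## A worked miniature

```{r example, eval = FALSE}
library(cebp)

# known-truth cohort: KEY1 carries a true effect of 0.5, NUL1/NUL2 none
cohort <- simulate_cohort(
  taus = c(KEY1 = 0.5, NUL1 = 0, NUL2 = 0),
  cfg = causal_sim_config(n_samples = 1000, n_confounder_genes = 30,
                          seed = 7))

cfg <- cebp_config(hidden_width = 32, epochs = 100, patience = 20,
                   n_replicates = 3, n_confounders = 25, latent_dim = 10)
tab <- rank_mutations(cohort$mutation, cohort$activity,
                      c("KEY1", "NUL1", "NUL2"), cfg)
tab  # the planted KEY1 ranks first (see README for the printed table)
```
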