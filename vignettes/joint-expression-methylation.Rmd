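---
title: "Joint empirical Bayes modeling of expression and promoter methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint empirical Bayes modeling of expression and promoter methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmex)
```

## The problem

Promoter CpG-island methylation is a repressive epigenetic mark: increased
methylation generally accompanies transcriptional silencing, and global
hypomethylation is a hallmark of many cancers, including cell lines that
have acquired resistance to endocrine therapy. Asking *which genes change
in both expression and promoter methylation between two conditions* — a
drug-sensitive and a drug-resistant line, say — requires combining two
noisy probe-level microarray platforms with very different designs: the
expression platform has several probes per gene and replicate arrays,
while the methylation platform has several promoter fragments per gene
but no replication at all. Analyzing genes one at a time wastes the
shared structure; `ebmex` instead pools information across all genes with
a hierarchical empirical Bayes model and reports, for every gene, a full
bivariate posterior distribution of its expression change and methylation
change.

## The model

For gene $i$, expression probe $j = 1..J_i$, replicate $k = 1..K$ and
condition $l \in \{1, 2\}$, log2 expression intensities follow

$$G_{ijkl} = \mu_{il} + b_{ij} + \epsilon_{ijkl}, \qquad
b_{ij} \sim N(0, \sigma^2),\; \epsilon_{ijkl} \sim N(0, \delta^2),$$

and log2 methylation intensities for probe $h = 1..H_i$ follow

$$M_{ihl} = \eta_{il} + a_{ih} + d_{ihl}, \qquad
a_{ih} \sim N(0, \omega^2),\; d_{ihl} \sim N(0, \tau^2).$$

The probe effects $b_{ij}$, $a_{ih}$ absorb the systematic probe-to-probe
offsets that dominate probe-level array data. The two platforms are
coupled at the gene level:

$$(\mu_{i1}, \mu_{i2}, \eta_{i1}, \eta_{i2})^t \sim N(\mu, \Sigma),$$

with $\Sigma$ a free $4\times4$ covariance whose off-diagonal
$2\times2$ block carries the expression–methylation coupling. Stacking
each gene's data as $D_i = (G_i^t, M_i^t)^t$ with a 0/1 design matrix
$\Delta_i$ gives a standard Gaussian linear mixed model per gene, so the
posterior of the coefficient vector $\beta_i$ is Gaussian with

$$K^*_i = (\Delta_i^t \Sigma_e^{-1} \Delta_i + \Sigma_p^{-1})^{-1}, \qquad
K_i = K^*_i(\Delta_i^t \Sigma_e^{-1} D_i + \Sigma_p^{-1} \mu^*).$$

All inference flows from the bivariate posterior of the *changes*
$(\mu_{i2} - \mu_{i1},\ \eta_{i2} - \eta_{i1})$, a linear contrast of
$\beta_i$.

### Row and column conventions

The stacking order is fixed so $\Delta_i$ is reproducible: expression
rows are ordered probe (outer), condition (middle), replicate (inner);
methylation rows probe (outer), condition (inner). Columns are
$(\mu_{i1}, \mu_{i2}, \eta_{i1}, \eta_{i2}, b_1..b_{J_i}, a_1..a_{H_i})$,
so each row has exactly two ones. $N_i = 2K J_i$ and $M_i = 2H_i$.

## Estimation

The hyperparameters $\theta = (\mu, \Sigma, \sigma^2, \delta^2, \omega^2,
\tau^2)$ are estimated by maximum likelihood with an EM algorithm that
treats $\beta_i$ as missing. The E-step is the exact Gaussian posterior
above; the M-step maximizers are closed-form moment matches:

* $\hat\mu$ — average over genes of the posterior mean of
  $(\mu_{i1}, \mu_{i2}, \eta_{i1}, \eta_{i2})$;
* $\hat\Sigma$ — average posterior second moment of that 4-vector about
  $\hat\mu$ (posterior covariance plus squared deviation);
* $\hat\sigma^2, \hat\omega^2$ — average posterior second moment of the
  probe effects over all probes of each platform;
* $\hat\delta^2, \hat\tau^2$ — expected residual sum of squares over the
  platform's observation count, expanded as
  $\|y - X m_i\|^2 + \mathrm{tr}(X^t X V_i)$.

These forms were derived from the complete-data likelihood and verified
two independent ways: against a Monte-Carlo maximization of the expected
complete-data log likelihood on a small fixture, and by the EM ascent
property (the observed-data log likelihood, computed through the Woodbury
identity on the marginal covariance $\Delta \Sigma_p \Delta^t + \Sigma_e$,
must never decrease; the fitter hard-errors if it does).

**Initialization** (a free design choice; the likelihood surface is well
behaved here but a sensible start saves iterations): method of moments.
Condition means come from probe-averaged gene means, $\Sigma$ from their
across-gene sample covariance, $\delta^2$ from within probe-by-condition
replicate scatter, and $\tau^2$ from cross-condition probe differences
within genes — each such difference has variance $2\tau^2$ about the
gene's mean difference, which sidesteps the absence of methylation
replicates. Probe-effect variances are between-probe variances with the
error contribution subtracted, floored at $10^{-4}$.

**Convergence**: relative log-likelihood change below $10^{-8}$, default
cap 500 iterations (fits in this document's regimes converge in 10–60).
$\hat\Sigma$ is symmetrized each step and eigenvalue-clipped at
$10^{-10}$ if a boundary estimate drifts; variance updates are floored at
$10^{-10}$ with a warning.

## Nine-category classification and FDR

Each axis of the change posterior is cut at $\pm C \hat s$, where
$\hat s$ is the sample standard deviation (computed over all modeled
genes, $n-1$ denominator) of the posterior mean change on that axis and
$C = 1.5$ by default. The $3 \times 3$ grid crosses expression status
(DN / NG / UP) with methylation status (HO / NM / HR), and each gene
receives the posterior probability of all nine rectangles, computed with
a deterministic bivariate-normal quadrature (`mvtnorm`'s Miwa scheme;
infinite limits are clamped 40 posterior SDs out, far below double
precision). The nine probabilities sum to one within $10^{-6}$ by
construction; rectangles are half-open so they partition the plane, the
boundary carrying no mass.

Genes are assigned under three rules — plain maximum probability, and
maximum probability required to exceed 0.6 or 0.7, with sub-threshold
genes left unassigned. Argmax ties (probability ~0 events) break to the
first label in the fixed order DN/HO, DN/NM, DN/HR, NG/HO, … For a
category $s$ and cutoff $\kappa$, the posterior-probability FDR of the
selection $\{P_i^s \ge \kappa\}$ is estimated as
$\widehat{\mathrm{FDR}} = D(\kappa)/K$ with
$D(\kappa) = \sum_i (1 - P_i^s)\,\mathbf{1}[P_i^s \ge \kappa]$ and $K$
the number selected — the standard posterior-expected false-discovery
proportion. (The ratio form is the only internally consistent reading of
the estimator; an unnormalized $D(\kappa)$ is not a rate.)

## Downstream summaries

* **Global correlations**: Pearson correlation across genes of posterior
  mean expression versus methylation within each condition, and of the
  posterior mean changes between conditions.
* **Gene-specific correlations**: the off-diagonal of the relevant
  $2\times2$ posterior covariance, normalized — for the change pair and,
  as an exported alternative, for each condition's level pair
  $(\mu_{il}, \eta_{il})$. Both interpretations are emitted because a
  "per-gene correlation in condition $l$" can reasonably mean either.
* **Overlap tables**: cross-tabulation of expression direction between
  two analyses sharing a gene universe, restricted to a methylation
  stratum (e.g. hypomethylated in both).
* **Score contrasts**: ratio of mean nonnegative per-gene scores (such
  as a histone-mark level) between two categories, with a seeded
  percentile bootstrap CI (10,000 resamples by default). A bootstrap is
  used because no analytic CI is natural for a ratio of means of skewed
  scores; the estimate is scale-equivariant.

## The synthetic-data generator

`generate_dataset()` samples exactly the generative model: gene-level
4-vectors from $N(\mu, \Sigma)$, probe effects and errors from their
normal laws, assembled into the package's table formats with all-present
calls (optionally corrupted at a configured absent rate to exercise the
filter). Defaults mirror the motivating study's structure: $K = 4$
expression replicates, one methylation replicate, 2–3 probes per gene
per platform, log2 intensities around 7 (expression) and 9
(methylation), across-gene SD ~1, probe-effect SD 0.5, error SDs
0.35/0.45, and a weak negative cross block
($\Sigma_{12} \approx -0.1\sqrt{\Sigma_{1,jj}\Sigma_{2,kk}}$) matching
the weak negative expression–methylation coupling typical of promoter
arrays. An optional mixture displaces a fraction of genes to shifted
change centers so that datasets contain genuinely regulated genes with
known labels for calibration studies.

What the generator does *not* emulate: array spatial artifacts,
normalization residue, probe sequence effects, non-Gaussian tails, or
negative probe-probe correlation within a gene (the model implies a
positive one). Passing tests therefore certify the estimator and its
calibration *under the model*, not robustness to real-array pathologies.

## Numerical choices

* All per-gene solves are Cholesky factorizations of the
  $(4 + J_i + H_i)$-dimensional posterior precision; $\Sigma_e$ is
  diagonal, so no $n_i \times n_i$ matrix is ever inverted.
* The marginal likelihood uses the matrix determinant lemma and Woodbury
  identity on the same small factorization.
* Genes are conditionally independent given $\theta$: results are
  invariant to gene ordering (to summation round-off) and the E-step is
  trivially parallelizable.
* Present-call filtering defaults to *per condition*: at least
  `min_present` "P" calls within each condition's replicates, because
  both condition means must be estimable. The pooled variant of the rule
  is available via `per_condition = FALSE` since the filter's original
  description does not distinguish the two.
* Probes mapping to multiple genes are rejected at construction; missing
  values are not supported (the error-covariance block structure assumes
  complete vectors).

## Problem sizes used in the checks

The test-suite and the reproduction script operate at deliberately
moderate scales chosen to exercise the asymptotics that matter:
50 random small blocks for posterior-oracle equivalence, 20 datasets of
200 genes for EM ascent, 5 datasets of 2,000 genes for hyperparameter
recovery (the study's own scale is ~4,000 genes; recovery error shrinks
as $1/\sqrt{I}$, so 2,000 already sits well inside the stated bands),
$10^6$-draw Monte Carlo for the rectangle probabilities, and 20 datasets
of 300 genes for FDR calibration at $\kappa = 0.9$.

## Known limitations

* No standard errors on $\hat\theta$ are produced.
* The model shares one probe-effect variance per platform across all
  genes; strongly heteroskedastic platforms would violate this.
* Posterior-probability FDR calibration is exact only when the model
  holds; the mixture-displaced generator already induces a (mild,
  measurable) prior misspecification.
* One-gene datasets are refused: the across-gene moments that define
  both the prior and the grid need at least two genes (realistically,
  hundreds).

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 500, seed = 1)
d <- generate_dataset(cfg)
blocks <- build_gene_blocks(d$expr, d$meth)$blocks
fit <- em_fit(blocks)
cls <- classify_genes(blocks, fit)
cls$table                       # 3x3 counts, "max / >0.6 / >0.7" per cell
correlation_summary(cls$posteriors, cls$diffs)$global_diff
fdr_report(cls$probs, "NG/NM", kappa = 0.9)
```
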