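---
title: "Genomic selection on structured inbred panels: models, designs, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection on structured inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models inside `huskgs`, the design
decisions that were genuinely open, the simulator that provides ground truth,
and — importantly — what the package's passing tests do and do not establish
about real data.

## The mixed model

Everything rests on the single-kernel mixed model applied to per-line trait
means:

$$y = X\beta + u + \varepsilon, \qquad
u \sim N(0, K\sigma_u^2), \qquad \varepsilon \sim N(0, I\sigma_e^2)$$

with one record per line (the random-effect design is the identity; replicated
multi-environment observations are averaged upstream by `line_means()`, an
unbalanced-tolerant mean that uses whatever observations a line has). $X$
holds an intercept and, by default, the three leading marker-derived principal
components; $K$ is the VanRaden additive relationship matrix from all markers.
The BLUP $\hat u$ is the vector of genomic estimated breeding values, and
$h^2 = \sigma_u^2/(\sigma_u^2+\sigma_e^2)$ is the narrow-sense heritability of
the line means.

**Estimation.** Variance components are estimated by REML (an `"ml"` switch
exists; REML is the default because it is what the standard genomic-selection
tool chain fits). The implementation is spectral: $K$ is eigendecomposed once,
$y$ and $X$ are rotated into the eigenbasis, where the covariance of the
rotated data is diagonal, and the restricted likelihood — profiled over
$\beta$ and the residual scale — collapses to a one-dimensional function of
the variance ratio $\lambda = \sigma_u^2/\sigma_e^2$. That function is
maximised by a 100-point grid over $\log_{10}\lambda \in [-10, 10]$ followed
by local refinement to $|\Delta\log\lambda| < 10^{-6}$. The search is
derivative-free and fully deterministic, and $\hat\lambda$ may land on either
boundary: heritability estimates of 0 (pure noise) or $\approx 1$ (noiseless
genetic signal) are reported as such, with no interior forcing. The profiled
objective is exported as `restricted_loglik()` so tests can compare it against
a dense matrix-form evaluation (determinants and solves of
$V = \lambda K + I$) that shares no code with it.

**Kernel standardisation.** `reml_fit()` divides the kernel by its mean
diagonal before fitting and reports the factor as `kernel_scale`. Predictions
and BLUPs are invariant to proportional rescaling of $K$, but the variance
components are not, and the choice of scale decides what $h^2$ means. Fully
inbred panels are the motivating case: with every locus homozygous, the
VanRaden diagonal is close to $1 + F = 2$, so on the raw kernel the component
ratio understates the genetic fraction of phenotypic variance by exactly
$t/(2-t)$ for a true fraction $t$ — a target of 0.5 would be reported as 0.33.
On the standardised kernel $\sigma_u^2$ is the average per-line additive
variance and $h^2$ is the genetic fraction of line-mean variance, which is
what a heritability estimate is for. `kinship()` itself remains exactly
VanRaden method 1, so its output matches hand evaluation of the formula.

**gBLUP prediction.** For a masked (unphenotyped) line $i$, the model is
fitted on the training lines only and the BLUP is extended through the
kinship cross-block:
$\hat u_{test} = \hat\sigma_u^2 K_{test,train} V_{train}^{-1}(y - X\hat\beta)$.
Genotypes — hence kinship rows and PC scores — of selection candidates are
always available in genomic selection, so using them is not phenotype
leakage; test phenotypes are never touched, and a dedicated test corrupts
them and asserts bit-identical predictions. Predicted phenotypes include the
fixed part $x_i\hat\beta$ by default (`include_fixed = FALSE` gives the
breeding value alone). The gBLUP/ridge-regression duality — predictions equal
ridge estimates of per-marker effects with penalty $\sigma_e^2 c/\sigma_u^2$
when $K = ZZ'/c$ — is verified to $10^{-6}$ on random fixtures.

**Numerical safety.** A ridge of $10^{-8} \times$ mean diagonal is added
before decomposition; eigenvalues below $-10^{-6}$ (relative) raise an error.
PC score signs are fixed by making each column's largest-magnitude entry
positive, so results are identical across linear-algebra backends.

## The four prediction models

* `QTN10` — marker-assisted selection. A PC-adjusted single-marker ordinary
  least squares scan is run **inside the training set of every split**, the
  ten smallest p-values are selected (ties broken by chromosome and position,
  so selection is deterministic), and a joint OLS of the training phenotype
  on the ten dosages predicts the test lines. Joint OLS, rather than summing
  marginal effects, is this package's choice; collinear selections are
  dropped with a warning. The scan is a transparent top-$k$ selector, not a
  re-implementation of any published multi-locus GWAS program: the
  marker-assisted comparison needs a reasonable ranking of candidate markers,
  and a fixed-effect scan provides one with no hidden iteration.
* `PC_ONLY` — OLS on the leading principal components.
* `KINSHIP` — gBLUP with an intercept-only fixed part.
* `PC_PLUS_KINSHIP` — gBLUP with the PCs as fixed covariates; the selected
  model for the assessment designs.

PCs are computed from all lines' genotypes (training and testing), as is
standard when candidates' genotypes exist before their phenotypes; only PC
*effects* are estimated on training data. With very small training sets (deep
within-subpopulation masking of a 27-line subpopulation) the PC design can
exceed the available degrees of freedom; the PC count is then truncated to
`n_train - 3`, possibly to zero, with a warning — this keeps the full
cross-validation factorial runnable instead of dropping its most interesting
cells.

## Cross-validation designs

Three scenarios: `WHOLE` (test lines drawn from the entire panel),
`WITHIN_SUBPOP` (test and training both inside one target subpopulation), and
`ACROSS_SUBPOP` (test lines from the target subpopulation; training on its
remainder plus every other subpopulation, supporting up to 100% masking of
the target). Test-set size is round-half-away-from-zero of
proportion × pool — the rounding rule is this package's decision, stated
because fractional sizes matter for 27- and 67-line subpopulations — clamped
so training is never empty where it must not be. Model comparison shares one
split per replicate across all models (a paired design, reducing the variance
of model contrasts); the default 20 replicates at 20% testing and the
assessment default of 100 replicates over proportions 0.1–0.9 mirror the
standard design for this kind of panel.

Accuracy is the Pearson correlation between predicted and observed line
means; cells whose correlation is undefined (constant predictions, tiny test
sets) are recorded as missing, excluded from means, and counted in
`summarize_cv()`'s `n_effective`.

Seeding is hierarchical and content-addressed: every cell derives its RNG
seed from the master seed plus its coordinates (scenario, subpopulation,
proportion, replicate) via `cell_seed()`, so any single cell reproduces in
isolation and whole runs are byte-identical under a fixed master seed. The
global RNG stream of the caller is left untouched.

Orchestration is exposed as plain R functions — `heritability_report()`,
`run_model_comparison()`, `run_gblup_assessment()`, with CSV/JSON writers —
rather than a shell executable; for an R analysis package the functions and
this vignette are the interface.

## The simulator

`simulate_genotypes()` draws a Balding–Nichols panel: each marker has an
ancestral frequency $p_0 \sim U(0.05, 0.5)$, and each differentiated
subpopulation draws its own frequency from
$\mathrm{Beta}\!\big(p_0\tfrac{1-F_{ST}}{F_{ST}},
(1-p_0)\tfrac{1-F_{ST}}{F_{ST}}\big)$, which has mean $p_0$ and variance
$F_{ST}\,p_0(1-p_0)$. A subpopulation named `MIXED` is built as per-line
admixture of the differentiated groups (proportions
$\sim \mathrm{Dirichlet}(1,\dots,1)$), giving it genuinely intermediate
kinship. Lines are fully inbred by default (`inbreeding = 1`: dosages 0/2
only). Markers whose panel-wide MAF falls below 5% are resampled up to 100
times, then dropped with a message. The defaults — 498 lines split
27/67/193/211, 2000 markers, $F_{ST} = 0.15$ — emulate a maize association
panel; no quantitative differentiation value is published for such panels, so
0.15 was chosen once as a realistic magnitude for maize germplasm groups, and
the realised value is checked against it with a Weir–Cockerham estimator
(treating each inbred line as one allele draw).

`simulate_phenotypes()` draws an additive polygenic trait: QTL sampled
uniformly from the polymorphic markers, effects either Gaussian or (default)
geometric-decay — magnitudes spanning two orders with random signs, i.e. a
few moderate QTL plus many small ones, the architecture described for
polygenic ear-protection traits in maize. True breeding values are exact
dosage-weighted sums. Residual noise is calibrated so that the **line-mean**
heritability equals the target: the plot-level residual SD is the line-mean
residual SD times $\sqrt{n_{env} n_{rep}}$. Heritability is defined and
calibrated at the line-mean level because that is the scale the pipeline
analyses. The default 2 environments × 3 replicates mirror a two-location,
three-replicate field design; environment main effects are shared across
lines and therefore cancel from line-mean variance.

`simulate_reference_panel()` bundles the default panel with four traits at
target heritabilities 0.45 (HL), 0.60 (HW), 0.70 (HN), 0.80 (HT), with
baselines and genetic SDs giving plausible husk-trait scales (lengths and
widths in cm, a layer count, a thickness below a centimetre), and serialises
everything to the package's plain-text formats plus a ground-truth JSON.

### Problem sizes used by the test suite and acceptance script

Oracle equivalences run on 10 fixtures of n = 40 (REML vs a 10,000-point
dense grid) and n = 60 (gBLUP vs ridge). Parameter recovery uses the full
498-line panel with 200-QTL traits, 20 seeds per heritability level. Model
ranking and the accuracy-decline trend use a 500-QTL Gaussian-effect trait
with 50 paired and 9 × 100 splits respectively; the subpopulation contrasts
use 100 replicates per cell. The acceptance script reports 20-replicate model
comparisons and 100-replicate assessment cells. These sizes make every run
deterministic and desk-scale while keeping Monte-Carlo error well below the
effect sizes being asserted.

## What the simulation does and does not establish

The simulator was designed so that each claim the pipeline makes can be
checked against ground truth. Passing tests establish that the estimator
machinery is correct (oracle equivalences), that heritability is recovered
without bias at panel scale, that accuracy declines as the testing proportion
grows, that marker-assisted selection loses badly to kinship models on
genuinely polygenic traits, and that a small subpopulation is predicted
better with external training lines than with its own five training lines.

Three features of real panels are deliberately absent, and they bound what
passing (or failing) tests can say:

* **No linkage disequilibrium.** Markers are independent and QTL are markers.
  gBLUP must therefore estimate ~2000 independent effects, which caps
  whole-panel accuracy near $\sqrt{nh^2/(nh^2+M)}$ and makes per-trait
  accuracy at a fixed heritability sensitive to the luck of the QTL draw —
  with one trait realisation per heritability level, the expected
  heritability-accuracy ordering can invert for individual seeds even though
  it holds in expectation.
* **Homogeneous effects across subpopulations.** QTL effects are global, with
  no dominance, epistasis, genotype-by-environment interaction, or
  LD-phase differences between groups. External training lines consequently
  always add information; the real-data phenomenon where a large
  subpopulation predicts *better* without outside lines cannot arise here,
  because nothing makes outside lines misleading.
* **Kinship saturates the structure signal.** The VanRaden matrix of a
  Balding–Nichols panel encodes subpopulation structure completely, so PC
  covariates add estimation noise but no information, and `PC_PLUS_KINSHIP`
  ties with `KINSHIP` to within a few thousandths of a correlation unit
  rather than beating it. On real panels, where the kinship estimate and the
  structure axes carry partly distinct information, the PC-augmented model
  can genuinely lead.

## Known limitations

Single trait, single kernel: no multi-trait or multi-kernel models, no
Bayesian-alphabet methods, no dominance or epistatic relationship matrices,
no spatial or environment-specific random effects. The association scan is a
fixed-effect screen, not a multi-locus model. The exact kinship variant used
by some established pipelines is not published in formula form; VanRaden
method 1 is the default here, with `centered_ip` (per-marker standardised)
as the alternative, and gBLUP accuracy is insensitive to the difference.
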