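---
title: "A constrained IDE model of ROP1 polarity: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A constrained IDE model of ROP1 polarity: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropide)
```

## The model

Active ROP1 on the pollen tube membrane is described by a concentration
profile $R(x)$ on the arc $[-L_0, L_0]$, with the apical tip at $x = 0$ and
Dirichlet conditions $R(\pm L_0) = 0$. At steady state, superlinear positive
feedback, linear negative feedback and lateral diffusion balance:

$$-D_1 R'' = -k_{nf} R + k_{pf}\Big(1 - \frac{\int R}{R_{tot}}\Big) R^\alpha .$$

The depletion factor $1 - \int R / R_{tot}$ caps the positive feedback when
a large share of the free pool $R_{tot}$ already sits on the membrane. The
assumptions behind this form are: deactivation proportional to local
activity; activation growing like $R^\alpha$ with $\alpha > 1$ (superlinear
self-recruitment); spatially homogeneous rates; and a well-mixed cytosolic
pool, so depletion enters only through the integral.

Every positive solution is a scaled copy of a single canonical shape,

$$R_{\lambda,\mu}(x) = \lambda\, U_\alpha(\mu x), \qquad
\mu = \sqrt{k_{nf}/D_1},$$

where $U_\alpha$ solves the reference problem $-u'' = -u + u^\alpha$,
$u(\pm c) = 0$. The peak scale $\lambda$ solves the scalar calibration
equation

$$\frac{k_{nf}}{k_{pf}} - \lambda^{\alpha-1}
  + \lambda^{\alpha} \sqrt{D_1/k_{nf}}\; \frac{|U_\alpha|}{R_{tot}} = 0,$$

with $|U_\alpha| = \int U_\alpha$. A positive solution exists iff the
discriminant

$$\Lambda = \frac{k_{nf}}{k_{pf}} - \frac{1}{\alpha}
  \Big(\frac{\alpha-1}{\alpha}\sqrt{k_{nf}/D_1}\,
  \frac{R_{tot}}{|U_\alpha|}\Big)^{\alpha-1}$$

is non-positive: $\Lambda < 0$ gives two candidate peaks (a low and a high
bell), $\Lambda = 0$ a unique tangency solution, $\Lambda > 0$ none. In
shape coordinates, existence is the linear constraint
$\mu R_{tot} - \lambda |U_\alpha| > 0$: the membrane content
$\lambda|U_\alpha|/\mu$ cannot exceed the free pool. The membrane fraction
$r = \lambda|U_\alpha|/(\mu R_{tot})$ of any valid steady state obeys
$r^{\alpha-1}(1-r) \le (\alpha-1)^{\alpha-1}/\alpha^{\alpha}$
($\approx 0.5824$ at $\alpha = 1.2$, not 0.58 as a two-digit rounding would
suggest).

## Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| $\alpha$ | superlinearity of positive feedback | 1.2 | — |
| $D_1$ | lateral diffusion coefficient | 0.2 | working units |
| $R_{tot}$ | total free ROP1 | 30 | intensity·µm |
| $L_0$ | membrane half-length | 15 | µm |
| $k_{nf}$, $k_{pf}$ | feedback rates (estimated) | — | 1/working time |

The defaults are the wild-type working values; $\alpha$ is fixed because it
is confounded with $\mu$ given a single profile, and $R_{tot}$ is fixed
because membrane data alone cannot identify the cytosolic pool. $D_1$ is
quoted in the source literature without a fully consistent unit, so all
quantities are treated as working units; positions are µm and intensities
are on the boundary-normalized scale. Only the ratio structure matters for
the shape: $k_{nf}/k_{pf}$ controls the peak height, $\mu = \sqrt{k_{nf}/D_1}$
the width.

## Estimation

**Single tube (CNLS).** Observations $y_j = \lambda U_\alpha(\mu x_j) +
\varepsilon_j$ with i.i.d. errors of variance $\sigma^2$. The constrained
least-squares problem is solved in the reparametrization
$\nu = \mu/\lambda$, which maps the existence constraint to the box
$\nu > |U_\alpha|/R_{tot}$; the optimizer is Levenberg–Marquardt with box
bounds (`minpack.lm::nls.lm`), bounds offset by $10^{-8}$ to keep the
feasible set open. Starting values are moment-style: $\tilde\lambda =
\tilde y_0 / U_\alpha(0)$ from the observation nearest the tip (ties broken
toward the smaller $|x|$, then the smaller $x$ — the rule is arbitrary but
must be deterministic), and $\tilde\mu = \tilde\lambda |U_\alpha| /
\sum_{i\ge2} y_{(i)}\delta_i$ from a left-Riemann estimate of the membrane
integral, $y_{(i)}$ being the intensities ordered by position. Initial
values need feasibility, not accuracy, so the crude Riemann sum is kept as
stated and clipped into the constraint set when noise pushes it out. If the
default start fails or lands on the constraint boundary, five
deterministically perturbed restarts are tried and the best residual sum of
squares kept — the calibration equation's two-root structure means the RSS
surface can be bimodal. $\hat\sigma^2 = \mathrm{RSS}/(n-2)$ (two shape
parameters). The asymptotic covariance of $(\hat\lambda,\hat\mu)$ is the
plug-in $\hat\sigma^2 (J^\top J)^{-1}$ with $J$ the Jacobian of the model
curve, i.e. $\hat\sigma^2 \hat K^{-1}/n$ with $\hat K$ the sample mean of
the gradient outer products; intervals are normal-theory. When a fit sits on
the constraint boundary the covariance is withheld: the normal asymptotics
do not apply there, the case is flagged (`on_boundary`) and has not been
seen away from adversarial inputs.

**Population (CMM).** Tubes $i = 1,\dots,m$ carry their own shapes
$\theta_i = (\lambda_i, \mu_i)$, drawn from a population with mean
$\theta_0$ and covariance $\Sigma_0$; only these two moments are assumed,
never a parametric family. The estimator averages the per-tube CNLS fits:
$\hat\theta_0 = m^{-1}\sum_i \hat\theta_i$ (unweighted even under unequal
$n_i$, for fidelity to the published estimator), pools
$\hat\sigma^2 = \sum_i \mathrm{RSS}_i / \sum_i (n_i - 2)$, and corrects the
between-tube sample covariance for estimation noise:

$$\hat\Sigma_0 = \widehat{\mathrm{cov}}(\hat\theta_i)
 - \hat\sigma^2 \frac{1}{m}\sum_i T_i^{-1}, \qquad T_i = J_i^\top J_i .$$

The correction can overshoot at small $m$, so a non-PSD result is projected
by clipping negative eigenvalues to zero (idempotent on PSD inputs; the
pre-clip eigenvalues are reported). The covariance of $\hat\theta_0$ is the
simple-mean CLT estimate $\widehat{\mathrm{cov}}(\hat\theta_i)/m$ — the
per-tube scatter already contains estimation noise, which is exactly what
the mean inherits. Rates and their intervals follow by the delta method
through the map $(\lambda,\mu)\mapsto(k_{nf},k_{pf})$, with a
central-difference Jacobian (relative step $10^{-6}$). Internally the
parameter order is $(\lambda, \mu)$ everywhere, and all matrices carry
dimension names; published summaries with either ordering can be read off
unambiguously. Tubes whose fit fails are dropped with a warning and
reported, never silently.

## The synthetic-data generator

`simulate_tube()` draws $y_j$ on the uniform grid over $[-15, 15]$ µm with
steps 0.6, 0.3, 0.1 (sizes $n$ = 51, 101, 301) and Gaussian noise
($\sigma$ = 0.2 or 0.4 in the standard designs); Gaussianity is an
assumption beyond the mean/variance specification of the observation model,
made because the interval procedures are normal-theory anyway.
`simulate_population()` draws shapes from a bivariate normal truncated to
the constraint set by rejection (the standard design — SDs 0.06 with
correlation 0.8 around $(\lambda_0,\mu_0) = (0.6, 1)$ — sits far from the
boundary, so acceptance is essentially 1; the sampler aborts below 1%).
The standard population cases are $m = 10$ tubes at $n$ = 51 or 101 and
$m = 50$ at $n = 301$. `simulate_raw_matrix()` emulates unprocessed
exports for the preprocessing stage: 12 tubes on a common 173-point grid of
step 0.1205 µm centred on the tip, a per-tube baseline offset drawn from
0.1–0.3 of the tube's peak, 1% outliers at 5$\sigma$, and 25% missing cells
at random. Baseline and outlier settings are invented fixtures — chosen to
look like relative-intensity microscopy exports — not measured quantities.

What the generator does **not** emulate: spatially correlated or
heteroscedastic noise, tube-to-tube grid misalignment beyond missingness,
drift along the scan, or any growth dynamics — the model is stationary.
Passing tests therefore demonstrate correctness of the estimators under the
stated observation model, not robustness to every artifact of real
microscopy.

## Preprocessing

Raw relative intensities do not vanish at the membrane edges, while the
model's profiles must. Two steps bridge the gap. First, iterative-PCA
imputation/denoising on the tube-by-position matrix: missing cells start at
column means, then {center columns, rank-$k$ truncated SVD, refill only the
missing cells} iterates to a fixed point, and a final rank-$k$ projection
replaces all cells (this is what removes outliers from observed entries).
Column centering is used because row centering would subtract the bell
shape itself. Second, boundary normalization
$y = (\tilde y - \bar y_B)/\bar y_B$ with $\bar y_B$ the pooled mean over
all tubes and positions with $|x| > 8$ µm; the boundary-region mean of the
output is zero by construction. The formula pools across tubes (a per-tube
variant is offered as an option); negative values are kept, since the
observation model permits negative noise excursions around zero.

Normalization divides intensities by $\bar y_B$, which only rescales
$\lambda$: if data are divided by $R_0$, the fitted rates on the new scale
relate to the old by $(\tilde k_{nf}, \tilde k_{pf}) =
(k_{nf},\, k_{pf} R_0^{\alpha-1})$, provided the free pool is rescaled with
the data ($R_{tot}/R_0$) — the pool is an intensity-scale quantity too.
`rescale_rates()` implements the shift.

## Numerical choices

- **BVP solver.** Damped-Newton collocation on a uniform second-order
  finite-difference mesh (default 3001 points on $[-15, 15]$), seeded with
  the closed-form infinite-domain ground state
  $u_\infty(x) = ((\alpha+1)/2)^{1/(\alpha-1)}
  \operatorname{sech}^{2/(\alpha-1)}((\alpha-1)x/2)$. The seed matters: the
  BVP also admits the trivial solution $u \equiv 0$, and an unseeded Newton
  run can fall into it. Convergence is declared at residual $10^{-10}$
  (reached in 3–4 iterations); iterating further only churns rounding noise
  amplified by the $1/h^2$ stencil. Discretization leaves the solution
  accurate to about $10^{-4}$ relative at the default mesh.
- **Domain half-width.** $U_\alpha$ decays exponentially, so it is solved
  once on $c = 15$ and reused for every $\mu$ via cubic-spline
  interpolation (zero outside $[-c, c]$). Against the closed form, the
  finite-domain solution differs by about $u_\infty(c)$ — the truncated
  tail — which is $3\times10^{-4}$ at $c = 15$ but $0.02$ at $c = 10$:
  sub-0.1% agreement claims only make sense for $c \ge 15$.
- **Quadrature.** $|U_\alpha|$ is the composite trapezoid on the solver
  mesh; Simpson is computed alongside and agrees to $10^{-6}$ at the
  default mesh, confirming the discretization is not limiting. The
  calibration root $\lambda = 0.6$ at the wild-type rates reproduces only
  if the mass is accurate to ~0.1%, which both rules achieve.
- **Root bracketing.** The calibration equation's left side falls to a
  minimum at $\lambda^* = \frac{\alpha-1}{\alpha}\mu R_{tot}/|U_\alpha|$
  and rises beyond, so the two roots are bracketed on $(0, \lambda^*)$ and
  $(\lambda^*, \lambda_{max})$ with
  $\lambda_{max} = \mu R_{tot}/|U_\alpha|$, the point where the membrane
  mass would exhaust the pool (the left side is back at $k_{nf}/k_{pf} > 0$
  there, so the bracket is valid). Tangency is declared at
  $|\Lambda| \le 10^{-9}$ — exact tangency is measure-zero, but the case is
  part of the model's contract.
- **Iterative-PCA stopping rule.** The EM-style iteration converges
  linearly, so the remaining error is roughly (last increment)/(1 − rate);
  with rates near 0.99 a $10^{-6}$ relative-change threshold can stop
  ~$10^{-4}$ away from the fixed point. The default tolerance is therefore
  $10^{-8}$ (relative Frobenius change on the imputed block) with a
  500-iteration cap; hitting the cap returns the current state with a
  warning and `converged = FALSE` rather than failing. Mask patterns that
  leave a column observed in only a few tubes slow the fixed point by
  orders of magnitude — raise `max_iter` for such instances.
- **Degenerate inputs.** Non-positive Riemann sums in the starting values
  fall back to $\tilde\mu = 1$ with a warning; constraint-violating shapes
  abort naming the violated inequality; a non-positive boundary baseline
  aborts normalization; populations whose truncation acceptance falls below
  1% abort as infeasible designs.

## Verification scale

The test suite exercises the estimators at reduced Monte-Carlo scale chosen
to keep a full run around a minute: 200 replicates for the single-tube
study ($n = 301$, $\sigma = 0.2$; bias under 1%, coverage within
[0.91, 0.99]) and 200 replicates of the $m = 50$, $n = 301$ population case
(mean, covariance entries, rates and coverage checked against the
generating values at Monte-Carlo precision). These scales estimate coverage
to about ±1.5% and are the package's verification surface; they are
deliberately smaller than a publication-grade 10,000-replicate study, which
the same code reproduces by raising the replicate count.

## Known limitations

- The boundary (constraint-saturated) case is detected and flagged but not
  given valid inference; its nonstandard asymptotics are out of scope.
- Only $g_n(u) = u$ and $g_p(u) = u^\alpha$ mechanisms are implemented; no
  Michaelis–Menten or other saturating laws, no time-dependent dynamics.
- Pooled boundary normalization leaves per-tube baseline offsets of the
  order of the baseline spread in the data; on the synthetic raw design
  this shifts the recovered population $\mu$ by up to ~0.1. The end-to-end
  pipeline test tracks this as an explicit degradation bound (0.15) on top
  of the clean-pipeline error; per-tube normalization reduces the shift at
  the cost of inflating the apparent $\lambda$ spread.
- The covariance of the population mean uses the simple-mean CLT; a refined
  small-$m$ expansion is not implemented.
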