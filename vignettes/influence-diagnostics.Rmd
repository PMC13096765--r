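---
title: "Influence diagnostics for clock-reset multistate Cox models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Influence diagnostics for clock-reset multistate Cox models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msinfluence)
```

## The model

A multistate model tracks a patient through discrete health states. The
built-in preset is a five-state breast-cancer progression graph:
post-surgery (1), local relapse (2), distant relapse (3), cancer death (4)
and other-cause death (5), with nine permitted transitions (four out of
surgery, three out of local relapse, two out of distant relapse; both death
states absorbing). Each permitted transition $g$ carries a proportional
hazards model on the *clock-reset* scale,

$$\lambda_g(t) = \lambda_{g,0}(t)\,\exp(\beta^\top Z_{g,k}),$$

where $t$ is months since the patient entered the transition's origin
state, $\lambda_{g,0}$ is an unspecified baseline hazard, and $Z_{g,k}$ is
the transition-specific covariate vector of patient $k$. The expanded
design is produced by `expand_covariates()`: each model coefficient is a
(covariate, transition-set) pair, so a single coefficient can be shared
across several transitions, or a covariate can be excluded from transitions
it should not affect (in the preset mapping, age acts only on the
transitions into other-cause death, mirroring how such cohorts are usually
modelled).

All transitions are fitted jointly by maximizing the generalized log
partial likelihood

$$\ell_P(\beta) = \sum_g \sum_{k:\,d_{g,k}=1}
  \Big[ Z_{g,k}^\top\beta - \log\!\!\sum_{l \in R(t_{g,k})}\!\!
  \exp(Z_{g,l}^\top\beta) \Big],$$

where the risk set $R(t_{g,k})$ contains the records of transition $g$
whose clock-reset interval $(\text{entry}, \text{exit}]$ covers $t_{g,k}$.
Censored records appear only through risk sets. Only event records
contribute terms of their own: the inner sum is restricted to
$d_{g,k} = 1$, and every downstream sum in the package follows the same
convention.

### Data conventions

Input files are the de-facto long format for multistate data: one row per
patient-at-risk-for-transition with columns `id, from, to, trans, Tstart,
Tstop, status` plus covariates. The reader derives the clock-reset record
time as `Tstop − Tstart`; the study-time origin is retained only so a
write/read round trip reproduces the file exactly. Times are months
throughout, stored as reals without rounding.

Two preparation rules reflect how relapse data are recorded in practice.
When local and distant relapse are registered at the same visit,
progression is taken to be sequential (local before distant) and
`resolve_simultaneous_relapse()` adds 0.1 months to the distant-relapse
time so no interval has zero length; a local relapse recorded strictly
after a distant relapse is dropped. `truncate_covariate()` winsorizes a
covariate from above (e.g., recoding all tumour sizes above 80 mm to
80 mm), the standard guard against leverage from extreme measurements.

### Estimation

`fit_mscox()` runs Newton–Raphson on the analytic score and Hessian with
step-halving, starting from $\beta_0 = 0$ (configurable), for at most 50
iterations. Ties are handled in the Breslow manner — tied events share the
full risk-set denominator — because the partial likelihood above is a plain
product over events; no Efron option is provided. Risk-set membership uses
$(\text{entry}, \text{exit}]$ with ties at event times included, the same
convention the Nelson–Aalen denominator uses, so the cumulative baseline
$\hat\Lambda_{g,0}(t) = \sum_{t_{g,k}\le t} d_{g,k} / \sum_{l\in R}
\exp(\hat\beta^\top Z_{g,l})$ is consistent with the fit. Baselines are
computed per transition after convergence and enter no influence formula —
every diagnostic below depends on $\hat\beta$ alone.

Numerical choices that matter:

* Every risk-set denominator is evaluated with a log-sum-exp shift, so the
  linear predictor can be arbitrarily large (contaminated covariates
  produce $\eta$ in the hundreds) without overflow; all downstream
  quantities are ratios and therefore shift-invariant.
* The variance $V = -\ddot\ell_P^{-1}$ is obtained by Cholesky solves
  against the symmetrized negative Hessian, never by forming an explicit
  elementwise inverse.
* Convergence is declared when $\max_j |U_j| \le 10^{-8}$. When covariates
  are large, the score's floating-point accuracy floor can sit *above*
  that tolerance: the iteration then makes exactly zero representable
  progress in $\ell_P$. In that situation the fit is accepted once the
  Newton decrement $U^\top(-\ddot\ell_P)^{-1}U$ — the expected remaining
  log-likelihood gain, which is invariant to covariate scaling — is below
  the same tolerance. Clean data never trigger the fallback; it exists so
  that heavily contaminated cohorts (the very ones the diagnostics are
  for) can be fitted at all.
* A singular Hessian (collinear design within the events' risk sets) and
  persistent failure of step-halving are reported as errors, not warnings.

## Global influence: case deletion

Only patients can be deleted coherently from a multistate trajectory —
removing a transition would change the parameter space — so case deletion
works patient-wise. Patient $i$'s score contribution sums their own event
records across the transitions they belong to:
$U_i(\hat\beta) = \sum_g U_{g,i}(\hat\beta) I_{gi}$, where $I_{gi}$
indicates membership in transition $g$. Deliberately, $U_i$ ignores the
patient's presence in *other* patients' risk sets; that is exactly the
information the one-step approximation trades away, and the gap to an
exact refit is what the one-step quality checks measure.

From $U_i$:

* one-step deleted estimate $\hat\beta_{(i)}^{(1)} = \hat\beta - V U_i$;
* one-step likelihood displacement
  $LD_i^{(1)} = 2[\ell_P(\hat\beta) - \ell_P(\hat\beta_{(i)}^{(1)})]$, with
  $\ell_P$ always evaluated on the full data;
* one-step generalized Cook distance
  $D_i^{(1)} = U_i^\top V U_i / p$.

`global_influence(..., exact = TRUE)` additionally refits without each
patient. Exact deletion removes *all* of the patient's records across all
transitions and refits warm-started at $\hat\beta$; refits are independent
per patient, so execution order cannot affect results, and the test suite
confirms the answer matches a cold start. The number of distinct patient
ids is used as $M$; for the five-state workflow, where everyone starts in
state 1, this equals the number of records of the initial transitions, and
it remains well-defined for graphs where it would not.

## Local influence: case-weight perturbation

Each component of $\ell_P$ carries equal weight. Local influence asks how
sensitive $\hat\beta$ is to infinitesimal reweighting: perturb the weights
by $\omega$, let $\hat\beta_\omega$ solve the perturbed score equations,
and measure the curvature of the influence surface
$f(\omega) = 2[\ell_P(\hat\beta) - \ell_P(\hat\beta_\omega)]$ at the null
perturbation $\omega_0$. With
$\Delta = \partial^2 \ell_P(\beta|\omega) / \partial\beta\,
\partial\omega^\top$ evaluated at $(\hat\beta, \omega_0)$, the conformal
normal curvature in unit direction $h$ is

$$B_h = \frac{|h^\top B h|}{|\mathrm{tr}\,B|},\qquad
  B = \Delta^\top \ddot\ell_P^{-1} \Delta,$$

bounded in $[0,1]$ and invariant to reparameterizations of $\beta$
(rescaling a covariate leaves every curvature unchanged — a tested
property). Since $\ddot\ell_P$ is negative definite, $B$ is negative
semidefinite and $\mathrm{tr}\,B < 0$ whenever $\Delta \ne 0$; the index
curvatures $B_i = |b_{ii}/\mathrm{tr}\,B|$ therefore sum to one, and the
absolute values in the definitions are applied exactly as written.

Three schemes differ in what gets a weight:

* **Scheme I — (transition, patient).** One weight per long-format record,
  $r = N$, null perturbation $\omega_0 = \mathbf{1}$. The Jacobian column
  of an event record is $v_{gk}\,U_{g,k}(\hat\beta)$ with
  $v_{gk} = 1 - \exp(Z_{g,k}^\top\hat\beta) / \sum_{l\in R}
  \exp(Z_{g,l}^\top\hat\beta)$; censored records keep (zero) columns, since
  they carry weights even without likelihood terms of their own. Columns
  are ordered transition-major with file order within transition, and that
  ordering is carried into all outputs so per-transition index plots line
  up.
* **Scheme II — transition.** One weight per transition, $r = G$, weights
  entering as $1 + (N_g/N)\,\omega_g$ with $\omega_0 = \mathbf{0}$ (the
  asymmetry with Schemes I/III is kept as defined); the column for
  transition $g$ is $(N_g/N) \sum_{k} U_{g,k}(\hat\beta)$.
* **Scheme III — patient.** One weight per patient, $r = M$,
  $\omega_0 = \mathbf{1}$; the column for patient $i$ is exactly the
  patient score $U_i$. Consequently $|b_{ii}| = p\,D_i^{(1)}$: the
  patient-level curvature and the one-step Cook distance rank and flag the
  same patients. This identity is asserted to $10^{-10}$ in the tests.

A design point worth recording: in Scheme I the perturbation also enters
the risk-set sums, so the *full* mixed partial of the perturbed objective
contains cross terms linking each record to every event whose risk set
contains it. The closed form $v_{gk} U_{g,k}$ keeps only the own-record
terms, and is what `delta_scheme1()` returns by default — it is the
canonical Jacobian here. The full derivative is available as a labelled
diagnostic (`form = "full"`) and is verified against finite differences of
the perturbed objective, but the two are not asserted equal and the
difference is expected.

Flagging uses the cutoff $\bar B + 2\,\mathrm{sd}(B)$ over the $r$ index
curvatures, with the sample ($n-1$) standard deviation — the usual choice
in the diagnostics literature — and a strict inequality, so a constant
$B_i$ profile flags nothing. `hmax()` returns the unit eigenvector of the
symmetrized $B$ for the largest-magnitude eigenvalue (symmetrization
suppresses rounding-level asymmetry; on an exact tie the lowest column
index wins), with the sign fixed so the largest-magnitude entry is
positive; the index plot of $|h_{max}|$ shows which components drive the
most influential joint perturbation. `random_direction_curvatures()`
evaluates $B_h$ for thousands of random unit directions without forming
the $r \times r$ matrix $B$ (via $h^\top B h = (\Delta h)^\top
\ddot\ell_P^{-1} (\Delta h)$), which keeps the $[0,1]$-bound stress test
cheap even for Scheme I where $r$ is the number of records.

## The synthetic cohort generator

`simulate_cohort()` provides the test bed: known truth, controllable
contamination. Patients start in state 1; from the current state one
latent clock per outgoing transition is drawn with hazard
$\lambda_{g,0}(t)\exp(\beta_{true}^\top Z_g)$, the minimum wins, the clock
resets on entry to the next state (competing risks as independent latent
clocks — the standard intensity-based construction), and the trajectory
stops at an absorbing state or at administrative censoring applied on the
study-time scale. Baselines are constant by default (the diagnostics never
use the baseline's shape, so the simplest sampler consistent with the
semiparametric model suffices); a Weibull shape parameter is available as
a config knob and reduces to the exponential at shape 1.

Default study conditions, chosen once to resemble a breast-cancer cohort
in months:

| quantity | default | why |
|---|---|---|
| covariates | size $\sim$ lognormal($\log 22$, 0.45) mm; high-grade $\sim$ Bern(0.5); age centred, sd 10 y | typical tumour-size distributions concentrate at 15–40 mm with a long right tail |
| effects | size 0.04/mm and grade 0.5 on transitions out of surgery; size 0.015/mm on post-relapse progression/death; age 0.05/y on other-cause death | per-mm and per-year log hazard ratios of realistic magnitude; age restricted to non-malignant mortality |
| baseline rates | $8\times10^{-4}$ to $3\times10^{-2}$ per month depending on transition | relapse hazards are low out of surgery and much higher after distant relapse |
| censoring | uniform on 60–300 months | long-follow-up registry cohorts have median follow-up around 14 years |

Contamination (`inject_outliers()`) emulates the anomalies the
diagnostics target: tumour sizes multiplied by 6 (pushing patients far
above 100 mm), a first-event sojourn shrunk to a fifth ("progressed very
fast"), and optionally inflated post-relapse survival. Targets are drawn
among patients with a relapse event out of state 1, where the distortion
of risk sets is strongest; contaminated ids are returned as ground truth.
Continuous clocks cannot produce tied relapse times, so the 0.1-month rule
is exercised by a dedicated fixture with hand-written ties rather than by
the generator.

What the generator does *not* emulate: the empirical transition
frequencies of any particular registry beyond order of magnitude,
molecular-subtype heterogeneity (e.g., hormone-receptor strata with
different baselines — real analyses should fit strata separately), missing
data, or interval censoring. Passing tests therefore show that the
formulas and their implementation are correct and that the diagnostics
have power against covariate/timing contamination of this kind — not that
they will flag every clinically meaningful anomaly in real data.

## Validation, problem sizes, and limitations

The test suite validates each layer against an independent oracle:
analytic score and Hessian against central finite differences on 50 random
small cohorts ($n \le 30$, $p \le 3$, $G \le 4$); the $G = 1$ special case
against an independently implemented proportional-hazards fit (Breslow
ties) to $10^{-6}$ in $\hat\beta$, log-likelihood, $V$ and baseline;
Scheme II/III Jacobians against finite-difference mixed partials of the
perturbed objectives (exploiting that those objectives are linear in
$\omega$, so only $\beta$ is differenced numerically); the Scheme I full
form against a four-point cross difference; curvature arithmetic against
hand-computed $2\times 2$ cases. Simulation-backed properties use
$n = 200$–$500$ cohorts: one-step vs. exact deletion agreement, the
Remark-type identity between Cook distances and Scheme III curvatures,
the $[0,1]$ curvature bound over $10^4$ random directions per scheme,
rescaling invariance, detection power on 100 contaminated replicates
($n = 300$, 2 contaminated patients), and coefficient recovery over 200
clean replicates ($n = 500$). These sizes give each check stable behaviour
while keeping the full suite to a few minutes.

Known limitations, by construction: Breslow ties only; no stratified
baselines beyond per-transition; no time-varying coefficients; no
robust/sandwich variance; no interval censoring; no group deletion and no
deletion of single (transition, patient) records; no covariate- or
censoring-perturbation schemes. The flagging cutoff
$\bar B + 2\,\mathrm{sd}(B)$ is a screening device, not a test with a
controlled error rate — flagged components deserve manual inspection, not
automatic removal, and `run_compare()` exists to show what removal would
do rather than to recommend it.
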