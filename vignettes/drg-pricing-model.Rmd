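---
title: "A three-stage game model of DRG medical-service pricing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-stage game model of DRG medical-service pricing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgpricing)
```

## The model

Prospective payment under diagnosis-related groups (DRGs) fixes one price
per disease group before treatment. `drgpricing` models the setting of that
price as a game between a **government–patient alliance** (the purchaser
side, whose objective is total social welfare) and a **medical
institution** (the provider, whose objective is profit), on a single
disease market with

* demand $Q = a - bp + cq$, where $p$ is the treatment price, $q$ the
  service-quality level, $b$ the price sensitivity of demand and $c$ the
  patients' quality preference;
* institution cost $C = F + \tfrac12\gamma q^2 Q$: a fixed cost plus a
  per-case cost quadratic in quality, with quality-cost coefficient
  $\gamma$.

The three stakeholder objectives are patient utility (consumer surplus
under the linear demand curve) $U_p = \int_0^Q \frac{a + cq - t}{b}\,dt -
pQ = \frac{Q^2}{2b}$, institution profit $\pi = (p - \tfrac12\gamma q^2)Q -
F$, and social welfare $WF = U_p + \pi$ — the price transfer cancels, an
identity the test suite asserts to $10^{-12}$. All quantities are plain
real numbers: the model is unit-free (no currency is attached), and demand
is returned as its raw linear value, with admissibility ($Q \ge 0$,
$p, q \ge 0$, profit $\ge 0$) carried as explicit flags rather than clamped
into the primitives, so that first-order conditions stay algebraically
exact.

### Stage 1: the alliance leads

The alliance posts $p$; the institution follows on $q$. Profit maximization
gives the follower's first-order condition
$$\tfrac32 c\gamma q^2 + \gamma(a - bp)q - cp = 0,$$
whose unique non-negative root is the closed-form best response
implemented in `follower_quality_response()` (for $c = 0$ the response is
$q = 0$). The leader problem $\max_p WF(p, q(p))$ has no tractable closed
form, so `solve_stage1()` solves it numerically (see *Numerical choices*)
and certifies the result with two residuals: the analytic follower FOC and
a central-difference leader FOC through the response curve.

### Stage 2: the institution leads

The institution commits to $q$; the alliance follows on price. The
alliance's welfare FOC is exactly
$$\frac{\partial WF}{\partial p} = -b\left(p - \tfrac12\gamma q^2\right),$$
so the *derived* response is marginal-cost pricing $p = \tfrac12\gamma
q^2$. Substituting it into profit gives $\pi \equiv -F$: under the stated
objectives the institution-led game is structurally degenerate — the leader
is indifferent over quality. `solve_stage2(mode = "derived")` detects this
(objective spread below `degeneracy_tol` across a quality grid), flags the
solution `degenerate`, and returns the smallest quality by tie-break. This
degeneracy is a *finding* of the implementation, not an error state, and it
is asserted by the tests.

The package therefore also implements a second reading of the stage-2
price response, $p = \tfrac12 cq^2 + cq + (a-1)/b$, behind
`mode = "as_printed"` (the default for the scenario engine). This literal
reading does not follow from the welfare objective above — it can return
negative prices, which the solvers flag rather than hide — but it is the
reading under which the institution-led equilibrium price rises with the
quality-preference coefficient $c$, the documented qualitative behaviour of
the quality-preference scenario. Both readings are kept side by side and no
intent is guessed; the mode is recorded in every solution.

Under `as_printed`, demand along the response is $Q(q) = 1 - \tfrac12 bcq^2
+ c(1-b)q$, and the institution's profit is usually negative inside the
admissible region with its supremum on the zero-demand boundary $q_0$
(where $\pi = -F$). The default stage-2 search interval is therefore
$[0, q_0]$ — the admissible region itself — rather than the marginal-cost
box used in stage 1: a box that stops short of $q_0$ would exclude the
maximizer. Boundary solutions are reported with `interior = FALSE` and
their one-sided leader FOC residual; interior solutions (which arise for
other parameter combinations, e.g. when $c$ approaches $\gamma$) must pass
the `foc_tol` certificate.

### Stage 3: bargaining and the co-payment ratio

The two equilibria are normalized to unit-quality prices $p_i^* = p_i/q_i$
(this requires $q_i > 0$; a zero-quality equilibrium is a degeneracy error
by design) and combined by the Rubinstein alternating-offers solution over
the range $[\min(p_1^*, p_2^*), \max(p_1^*, p_2^*)]$. With discount
factors $\theta_1$ (alliance) and $\theta_2$ (institution), the first
proposer's equilibrium surplus share is $s = (1 -
\theta_{\text{opponent}})/(1 - \theta_1\theta_2)$. The default convention
(`split`) places the price at $\bar p = \text{hi} - s(\text{hi} -
\text{lo})$ with the alliance proposing first: a fully impatient opponent
concedes the proposer's preferred endpoint, symmetric patience approaching
one yields the midpoint, and $\bar p$ moves monotonically toward the more
patient party's preferred end. A `literal` convention reproduces the
alternative combination $p_1^* + s\,p_2^*$ for traceability; it is not a
convex combination of the endpoints and triggers an out-of-range warning
when it leaves the bargaining interval, which is why `split` is the
default.

Given $\bar p$, the insurance stage chooses the co-payment ratio $\lambda
\in [0, 1]$ (patients pay $\lambda \bar p$ out of pocket) minimizing the
social-welfare loss of insurance
$$WL(\lambda) = \tfrac12(1-\lambda)^2 b +
\delta(1-\lambda)(a - b\lambda)\bar p + \tfrac12 R \lambda^2 \sigma^2,$$
the sum of the moral-hazard deadweight loss, the government's expected
opportunity cost (with disease incidence $\delta$), and the patients'
risk-bearing cost (absolute risk aversion $R$, price variance $\sigma^2$).
The deadweight-loss term $\tfrac12(1-\lambda)^2 b$ is used verbatim as
stated despite its dimensional oddity; no re-derivation is attempted. $WL$
is quadratic with curvature $b + 2b\delta\bar p + R\sigma^2 > 0$, so the
unconstrained minimizer
$$\lambda^* = \frac{b + \delta\bar p(a + b)}{b + 2b\delta\bar p + R\sigma^2}$$
is unique; `optimal_copay()` reports it both raw and clamped to $[0,1]$.
On $[0,1]$ the loss is U-shaped exactly when $\lambda^*_{\text{raw}} < 1$
and monotonically decreasing otherwise; the risk-aversion threshold where
the regimes switch, obtained by solving $\lambda^*_{\text{raw}} = 1$, is
$$R_{\text{crit}} = \frac{\delta\bar p(a - b)}{\sigma^2},$$
a derived (not printed) expression, labelled as such, positive only when
$a > b$. Violations of $WL \ge 0$ or of non-negative insured demand at
$\lambda^*$ are flagged in the solution, not forbidden: no parameter range
guaranteeing them is part of the model statement.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `a, b, c, gamma, F` | market primitives (unit-free) | preset `0.3, 0.3, 0.6, 10, 0` | the packaged simulation scenario |
| `theta1, theta2` | bargaining patience, $[0,1)$ | `0.5, 0.5` | symmetric mid-patience baseline |
| `delta, R, sigma2` | incidence, risk aversion, price variance | `0.1, 1, 1` | moderate incidence, unit risk scale |
| `p_max, q_max` | leader search box | derived (see below) | covers the admissible region |
| `tol` | 1-D optimizer tolerance | `1e-10` | well below reporting precision |
| `foc_tol` | interior-FOC certificate | `1e-6` | matches central-difference accuracy |
| `degeneracy_tol` | flat-objective spread | `1e-9` | far below any real profit variation |
| `n_grid` | oracle grid points | `1001` | step $10^{-3}$ of the normalized range |

The default stage-1 box is the fixed point of "price at most the choke
price at maximal quality, marginal cost at most the price": $q_{\max} =
\frac{c + \sqrt{c^2 + 2ab\gamma}}{b\gamma}$, $p_{\max} = (a + c\,q_{\max})/b$,
which satisfy $p_{\max} = \tfrac12\gamma q_{\max}^2$; at $p_{\max}$ the
follower response drives demand exactly to zero, so the box closes the
admissible region with no slack.

## Numerical choices

* **Leader optimization.** The leader objectives can be bimodal (an
  interior profit peak competing with the zero-demand boundary), so the
  maximizer scans 201 equally spaced points, refines every scanned local
  maximum with golden-section/parabolic search (`stats::optimize`), and
  always keeps the interval endpoints as candidates. Ties are broken by
  larger objective, then smaller argument.
* **Admissibility tolerance.** The search region and the grid oracle admit
  $Q \ge -10^{-9}$: the default box corner and the stage-2 boundary sit
  *exactly* on $Q = 0$, where floating-point rounding can push the computed
  demand a few ulps negative.
* **Consumer surplus** is evaluated in closed form ($Q^2/2b$); a quadrature
  cross-check (`stats::integrate`) lives only in the test suite.
* **Degenerate inputs.** $b \le 0$, $\gamma \le 0$ are constructor errors;
  $c = 0$ gives the exact zero-quality response; $q \le 0$ at the
  normalization step and $\theta_1\theta_2 \ge 1$ are explicit degeneracy
  errors; a zero-curvature welfare loss ($b = \delta = R\sigma^2 = 0$) is a
  degenerate-objective error.
* **Determinism.** Pipelines and sweeps are pure functions of their
  configuration; CSV exports carry a config hash and package version but no
  timestamp, so identical configs produce bit-identical files. All
  randomness in the package flows through the single seed of
  `generate_fixtures()`, which saves and restores the global RNG state.

## The fixture generator and what the tests show

`generate_fixtures()` draws full parameter sets from ranges that bracket
the packaged scenario values — $a \in [0.1, 1]$, $b \in (0, a]$ (demand
more sensitive to the intercept than to price, keeping choke prices
moderate), $c \in [0.05, 1.5]$, $\gamma \in [1, 20]$, $F \in [0, 0.02]$,
$\theta \in [0, 0.95]$, $\delta \in [0, 0.3]$, $R \in [0, 5]$,
$\sigma^2 \in [0.1, 4]$, $\bar p \in [0.5, 4]$ — and keeps sets whose
stage-1 equilibrium passes every admissibility flag. These are synthetic
study conditions: they probe the solvers across the admissible parameter
space, but they do not emulate estimated elasticities, hospital cost
accounts or claims data. Passing tests certify internal correctness
(closed forms solve their FOCs, nested solvers find the same optima as
exhaustive search, classifications match empirical curve shapes) — not
that the model's qualitative conclusions hold for any real DRG market.

Problem sizes used by the test and acceptance campaigns: 200 random
parameter sets for the co-payment checks ($\lambda$-grid step $10^{-5}$),
50 for the Stackelberg solver-vs-oracle checks (grid step $10^{-3}$
normalized), 100 points for the welfare identity.

## Scenario presets and sweep findings

Three presets ship with the package (`inst/extdata/scenarios/`): `fig1`
(price vs price sensitivity $b$, stage-1 game), `fig2` (price vs quality
preference $c$, stage-2 game, `as_printed`), `fig3` (welfare loss vs
$\lambda$ for a low/high risk-aversion pair around $R_{\text{crit}}$; its
$b = 0.15 < a$ makes the threshold positive, and $\bar p = 2$, $\delta =
0.1$, $\sigma^2 = 1$ follow the worked co-payment example). No axis ranges
for the sweeps are part of the model statement, so the presets use
admissible ranges chosen at runtime, and the reporting surface is the
monotonicity/shape *report* (direction, Spearman sign, oracle
recomputation), not specific curve values.

Two findings deserve emphasis:

```{r}
rep_b <- sweep_report(sweep_price_vs_b(drg_preset("fig1"), oracle_points = 3))
rep_b[c("direction", "expected", "oracle_direction")]
```

* The stage-1 equilibrium price is **decreasing** in $b$ under the stated
  welfare/profit objectives — the oracle confirms the solver — whereas the
  documented expectation for this scenario is a positive relationship
  (the anti-Ramsey claim). That expectation rests on printed closed-form
  equilibrium expressions that are typographically corrupted beyond
  recovery and could not be re-derived from the objectives; the sweep
  report records both the observed and the expected direction rather than
  reconciling them silently.
* The stage-2 `derived` mode is degenerate (flat profit), so the positive
  price/quality-preference relationship of the `fig2` scenario is only
  reproducible under the `as_printed` response — which is why that mode is
  the scenario default, with the degeneracy of the exact reading retained
  as a tested, documented result.

## Known limitations

* Single disease market, single institution: no competition, no capacity
  constraints or queuing, no multi-disease portfolios.
* No estimation: $\theta$, $\delta$, $R$, $\sigma^2$ are inputs, never
  fitted to claims data; no nonlinear insurance schedules.
* The stage-2 `as_printed` response is a literal reading kept for its
  qualitative behaviour; its negative-price region is flagged, not
  resolved.
* Whether the bargained price entering the insurance stage is a total or a
  unit-quality price is ambiguous in the model statement; the pipeline
  passes $\bar p$ through unchanged.
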