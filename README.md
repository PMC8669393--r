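# drgpricing

Game-theoretic solvers for prospective medical-service pricing under
diagnosis-related groups (DRGs).

Under DRG payment, a regulator must fix one prospective price per disease
group. Set it too low and hospitals avoid complex patients (adverse
selection); set it too high and expenditure escapes control. `drgpricing`
implements a three-stage bargaining model of this price-setting problem
between a *government–patient alliance* and a *medical institution*, for
health-economics and policy-modelling work:

1. **Stage 1 — alliance leads.** On a linear market with demand
   `Q = a − b·p + c·q` and institution cost `C = F + ½γq²Q`, the alliance
   posts the treatment price `p` to maximize social welfare
   `WF = ∫₀^Q (a + cq − t)/b dt − F − ½γq²Q` (consumer plus producer
   surplus); the institution responds with the profit-maximizing service
   quality, the closed-form root of `(3/2)cγq² + γ(a − bp)q − cp = 0`.
2. **Stage 2 — institution leads.** The institution commits to quality `q`
   and the alliance responds on price. Two response readings are provided
   (`derived`, the exact welfare first-order condition `p = ½γq²`, which
   makes the leader's profit structurally flat at `−F` — detected and
   flagged; and `as_printed`, the literal response
   `p = ½cq² + cq + (a−1)/b` that underlies the quality-preference sweep).
3. **Bargaining + insurance.** The two equilibria, normalized to
   unit-quality prices `p* = p/q`, are combined by the Rubinstein
   alternating-offers split with discount factors `θ₁, θ₂`; the co-payment
   ratio `λ ∈ [0,1]` then minimizes the welfare loss of insurance
   `WL(λ) = ½(1−λ)²b + δ(1−λ)(a−bλ)p̄ + ½Rλ²σ²`, with closed form
   `λ* = (b + δp̄(a+b)) / (b + 2bδp̄ + Rσ²)` and the risk-aversion
   threshold `R_crit = δp̄(a−b)/σ²` separating a U-shaped loss from a
   monotonically decreasing one.

Every solver reports first-order-condition residuals and admissibility
flags, and is cross-checked by an independent brute-force grid oracle
(`brute_force_equilibrium()`, grid minimization for `λ*`). A scenario
engine runs config-driven pipelines and parameter sweeps with monotonicity
reports and deterministic CSV export; `generate_fixtures()` draws seeded
admissible parameter sets for property testing.

## Worked example

```r
library(drgpricing)

run_pipeline(drg_preset("fig1"))
#> DRG pricing pipeline
#>   stage 1 (alliance leads):    p = 0.446448, q = 0.103381
#>   stage 2 (institution leads): p = 13.8044, q = 6.40219 [as_printed]
#>   bargained unit price p_bar = 2.87696
#>   optimal co-payment lambda* = 0.320937 (U_shaped)
```

With market parameters `a = 0.3, b = 0.3, c = 0.6, γ = 10, F = 0`: the
welfare-maximizing alliance would post `p ≈ 0.446` and the institution
would answer with quality `q ≈ 0.103`; with the institution leading (literal
price-response reading) the equilibrium sits on the zero-demand boundary at
a much higher price. Rubinstein bargaining with `θ₁ = θ₂ = 0.5` settles the
unit-quality price at `p̄ ≈ 2.88`, and with incidence `δ = 0.1`, risk
aversion `R = 1` and price variance `σ² = 1` patients optimally pay about
32% of the bill out of pocket.

The insurance stage alone, at `b = 0.3, δ = 0.1, p̄ = 2, a = 0.3, R = 1,
σ² = 1`:

```r
optimal_copay(copay_params(a = 0.3, b = 0.3, delta = 0.1, R = 1,
                           sigma2 = 1, p_bar = 2))
#> Optimal insurance co-payment ratio
#>   lambda* = 0.295775 (raw 0.295775), WL = 0.147887
#>   shape on [0,1]: U_shaped; R_crit = 0; FOC residual 5.55e-17
```

i.e. `λ* = 0.42/1.42 ≈ 0.2958`, confirmed by grid minimization of `WL`.

A thin command-line front end lives at `inst/cli/drgpricing.R`
(`Rscript inst/cli/drgpricing.R run --preset fig1`, `... sweep --preset
fig2 --out sweep.csv`, etc.).

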