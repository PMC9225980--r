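# crstab — structural sensitivity of consumer-resource models in equilibrium

`crstab` is for theoretical ecologists and food-web modellers who want to
know what an eigenvalue computed from an observation-based (Lotka-Volterra
type) food web model can — and cannot — say about the resilience of the
nonlinear ecosystem it portrays.

Observation-based food web models assume proportional interaction terms,
because those can be parameterized directly from measured biomasses and
feeding rates; the real part of the dominant Jacobian eigenvalue,
Re(λ), is then used as a measure of engineering resilience. `crstab` makes
the structural side of that inference explicit for the classical
two-species family: the Lotka-Volterra model (LV), its logistic-growth
extension (LVV), the Rosenzweig–MacArthur model (RM, Holling type II
consumption) and the Rosenzweig–MacArthur–Scheffer model (RMS, type III
top-consumer loss plus a chemostat influx `+lK`). For each nonlinear model
it constructs counterpart systems with proportional terms parameterized so
that the equilibrium densities and material fluxes are preserved exactly,

    r_lin = r (1 − A*/K),   g_lin = g/(A* + a),   F_lin = F Z*/(Z*² + z²),

and compares local stability and bifurcation structure of parent and
counterpart along environmental gradients: carrying capacity `K`
(eutrophication, 0–10) and top-consumer pressure `F` (0–0.3). It detects
transcritical (predator invasion), Hopf, fold (saddle-node) and — by
trajectory classification, since local analysis cannot see it —
homoclinic bifurcations.

## A worked example

The RM model at `K = 5` and its fully linearized counterpart describe the
same equilibrium but opposite dynamical verdicts:

```r
library(crstab)
p  <- cr_params(K = 5)                        # reference parameter set
eq <- closed_form_equilibria("RM", p)[[1]]
eq
#> <cr_equilibrium> A*=1 Z*=1.56 branch=1

eigen_pair(cr_jacobian("RM", p, eq))
#> <cr_eigen> lambda = 0.071875+0.129505i, 0.071875-0.129505i  (dominant Re = 0.071875)
classify_regime(cr_jacobian("RM", p, eq))
#> [1] "unstable_focus"

lin <- linearize("RM", p, eq, "LV")
lin
#> <cr_linsys RM_LV>  r_lin=0.4  g_lin=0.25  F_lin=0
#>   retained: none;  parent eq A*=1 Z*=1.56
classify_regime(cr_jacobian("RM_LV", lin, eq))
#> [1] "neutral_center"
```

The nonlinear model sits beyond its paradox-of-enrichment threshold — a
small perturbation spirals out onto a limit cycle (Re(λ) = 0.072) — while
the counterpart fitted to the very same biomasses and fluxes reports the
neutral stability typical of LV systems. The threshold itself:

```r
detect_hopf("RM", cr_params(), gradient_spec("K"))
#> <cr_event> hopf at param = 2.65306 (branch 1, tol 1e-06)
```

Gradient sweeps (`sweep_gradient`), fold and homoclinic detection for the
bistable RMS model (`detect_fold`, `detect_global`), phase portraits
(`nullclines`, `trajectory`, `plot_phase`) and the virtual-sampling stage
(`sample_observation`, `fit_linear_from_observation`) are described in the
vignette `vignettes/structural-sensitivity.Rmd`. A thin command-line
wrapper lives at `inst/cli/crstab.R` (`sweep`, `bifurcations`, `compare`,
`phase`, `sample`, `fit-linear`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the bifurcation
thresholds of the reference analyses — the LVV/RM invasion thresholds and
their linearized counterparts along `K`, the RM Hopf point, and the RMS
fold pair, Hopf point and homoclinic window boundaries along `F` at
`K = 10` — and writes them as JSON, one numeric value per target.
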