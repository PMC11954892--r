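# asymkin

Kinetic analysis of substrate inhibition (SI) in bi-substrate enzymes caused
by **asymmetric cooperativity**: substrates bind in random order, but the two
binding orders induce different conformational changes, carry unequal
homotropic cooperativity, and only the donor-first ternary complex is
productive. The motivating system is a plant UDP-glucose-dependent
glucosyltransferase (acceptor: the hydroxycoumarin scopoletin; donor:
UDP-glucose) whose SI is relieved — paradoxically — by competitive
apocarotenoid effectors acting as placeholders in the acceptor site.

The package is for enzymologists analysing steady-state rate matrices of
SI-prone bi-substrate enzymes, and for modellers exploring how binding-order
asymmetry, placeholder effectors, hydrolase side activity and slow conformer
transitions shape observed kinetics.

## Models

Acceptor titration at fixed donor (two Hill coefficients, shared K_S):

    v(S) = v_max (S/K_S)^n / (1 + (S/K_S)^n + (S/K_S)^x)

`n` = productive-branch, `x` = non-productive-branch Hill coefficient;
`x > n` yields SI with an optimum at `K_S (n/(x-n))^(1/x)`, `n = x` is a
saturating Hill curve. Donor titration: `v(U) = v_max U^h / (K_U^h + U^h)`
(Michaelis–Menten at `h = 1`). Per-donor-level maxima follow
`v_max(U) = v_max_inf U/(K_D + U)`. The allosteric descriptors obey
`αL = (S/K_S)^n`, `α = (S/K_S)^(n-1)`.

A mass-action ODE simulator (deSolve) realizes the full mechanism — random
binding, ordered productivity, dead-end ternary complex with slow
interconversion, placeholder effector, UDP-glucose glucohydrolase side
activity, product inhibition, timed pre-incubation protocols — with a
rapid-equilibrium closed form as an independent testing oracle.

## Worked example

Generate a synthetic 5 × 5 × 5 concentration matrix (acceptor and donor
grids of 5–100 µM, five replicates, 8% multiplicative noise) and run the
matrix analysis:

```r
library(asymkin)
ds  <- generate_matrix_dataset(noise = noise_model(cv = 0.08, seed = 42))
fit <- global_matrix_fit(ds, fit_options(seed = 42))
print(fit)
#> <matrix_fit> global mode; 5 donor levels; 125 observations
#> shared: K_S = 20.69 uM, n = 0.99 , x = 2.04
#> donor saturation: v_max_inf = 1154.1 , K_D = 17.73 uM
#> unit Hill coefficient at 13.4 uM acceptor
```

The generating truth (K_S = 20 µM, n = 1, x = 2, v_max_inf = 1157
nmol/min/mg, K_D = 19 µM) is recovered within a few percent: `K_S` is the
shared acceptor half-saturation constant, `x > n` quantifies the
non-productive branch's excess cooperativity (hence SI), and `v_max_inf` is
the maximal rate the enzyme would reach if no SI occurred. The fitted
parameters put the acceptor optimum at

```r
optimum_acceptor(acceptor_params(v_max = 1157, K_S = 20, n = 1, x = 2))
#> [1] 20
```

i.e. rates decline above ~20 µM acceptor. The full report adds the
Lineweaver–Burk pattern and AICc model selection (on noise-free data the
donor titrations classify as non-competitive; with n = 1, x = 2 the
asymmetric law coincides algebraically with classical single-site SI, so
parsimony selects the 3-parameter model):

```r
rep <- run_matrix_analysis(ds, analysis_config(seed = 42))
render_report(rep)
#> Shared acceptor parameters (global fit):
#>   K_S = 20.69 uM   n = 0.9901   x = 2.044
#>   ...
#> Donor saturation: v_max_inf = 1154.1, K_D = 17.73 uM
#> Model selection (U =   100 uM): classic_si
```

Mechanism phenomenology from the documented reference parameterization:

```r
mech <- reference_mechanism()
rate_substrate_scan(mech, c(5, 10, 25, 50, 100), D = 100)   # non-monotone: SI
effector_dose_response(mech, A = 68, D = 100, C_grid = c(0, 20, 60, 100, 500))
hydrolase_dose_response(mech, D = 100, C_grid = c(0, 20, 60, 100, 500))
```

A thin command-line wrapper covers the same workflow
(`exec/asymkin generate|fit|simulate|report`).

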