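# cleftflux

Analytical reaction–diffusion model of ligand flux across a synaptic cleft,
with a finite-difference cross-check solver.

## The problem

During neuromuscular transmission, a vesicle bursts at the pre-synaptic
membrane and releases acetylcholine into the ~50 nm cleft; the transmitter
diffuses across and is captured by receptors on the post-synaptic membrane.
The same transport problem describes Ca²⁺ crossing the dyadic cleft of a
cardiac myocyte. The quantity that matters physiologically is the **response
function J(t)**: the total flux of ligand absorbed by the receptor patch of
one release site as a function of time.

`cleftflux` computes J(t) for an idealised but quantitatively meaningful
model: the cleft is the slab 0 ≤ z ≤ L_z between two parallel membranes,
laterally periodic with periods L_x, L_y. Each unit cell carries a centred
release disk of radius R on the face z = 0, through which ligand enters as a
transient flux u(t) = e^(−t/t₀), and a centred absorbing sink disk of radius
a on the face z = L_z, representing the receptors. Everywhere else both
membranes reflect.

## The method

The concentration obeys ∂C/∂t = D∇²C with C(r, 0) = 0 and mixed boundary
conditions (prescribed flux on the release disk, C = 0 on the sink disk,
reflecting elsewhere). In Laplace space the solution is a double cosine
series

  Ĉ(r, s) = Σ_{l,m} [α_lm e^(γ_lm z) + β_lm e^(−γ_lm z)]
            cos(2πlx/L_x) cos(2πmy/L_y),
  γ_lm(s) = √(s/D + (2πl/L_x)² + (2πm/L_y)²).

The mixed condition on the sink is closed with the **constant-flux
approximation**: the unknown absorption flux density Q(s) is taken uniform
over the disk and fixed by requiring the disk-averaged concentration to
vanish. The source and sink disk indicators enter through their cosine
coefficients q_lm and p_lm (computed by analytic-in-y, Gauss–Legendre-in-x
quadrature, validated against an independent Bessel closed form), and the
total flux has the closed form

  Ĵ(s) = πa² Q(s),
  Q(s) = û(s) · [Σ p_lm q_lm / (ε_l ε_m γ_lm sinh γ_lm L_z)] /
               [Σ p_lm² cosh γ_lm L_z / (ε_l ε_m γ_lm sinh γ_lm L_z)],

with ε₀ = ½, ε_l = 1 otherwise and û(s) = 1/(s + 1/t₀). Time-domain curves
come from Gaver–Stehfest inversion at real s nodes. Key identities the
implementation reproduces: ∫₀^∞ J dt = πR²t₀ (ligand conservation,
independent of a) and the scaling law J₁(D₂t) = J₂(D₁t) whenever
D₁t₀₁ = D₂t₀₂.

An independent explicit finite-difference solver (`fd_response_curve()`,
quarter-cell symmetry, C++ core) integrates the same boundary-value problem
in the time domain as a cross-check, and closed-form calculators connect
receptor microphysics to the sink parameters: the partially-absorbing-disk
rate constant 1/k = 1/(4Da) + 1/(πκa²), the dilute equivalent-sink radius
a ≈ N_rec·a₀, and the homogenised face reactivity K = N_rec k₀/[S(1−f_rec)].

## Worked example

```r
library(cleftflux)

geom <- cleft_geometry()        # Lx = Ly = 500, Lz = 50, R = 20, a = 10 nm
pars <- transport_params()      # D = 1e5 nm^2/ms, t0 = 1 ms

rc <- response_curve(default_time_grid(200), geom, pars)
rc
#> Response curve (analytic): 200 times in [0.001, 100] ms; peak J = 249.8 at t = 0.6517 ms
#>   a = 10 nm, R = 20 nm, D = 100000 nm^2/ms, t0 = 1 ms

cons <- conservation_integral(geom, pars)
sprintf("integral J dt = %.2f vs pi R^2 t0 = %.2f (rel. error %.2e)",
        cons$integral, cons$expected, cons$rel_error)
#> "integral J dt = 1256.83 vs pi R^2 t0 = 1256.64 (rel. error 1.50e-04)"

binding_rate_constant(D = 1e5, a = 10, kappa = Inf)   # Smoluchowski disk, 4Da
#> [1] 4e+06
```

The curve rises once ligand has crossed the 50 nm cleft, peaks near 0.65 ms
at J ≈ 250 (in units of the release amplitude × nm²), and decays as the
exponential release empties; its time integral recovers the released total
πR²t₀ ≈ 1256.6 to 0.015%. Larger sinks give higher, earlier peaks; slower
diffusion or slower release delay the response in the exact correspondence
of the scaling law.

A command-line front end is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "cleftflux", package = "cleftflux"))') \
  --mode both --a 10 --t0 1 --D 1e5 --grid 64x64x16:2 --out runs/
```

writes `response_analytic.csv`, `response_fd.csv` (columns `time_ms, flux`),
run-metadata JSON and a comparison summary; `--mode validate` runs the
model's internal invariant checks and exits non-zero on failure; `--rates`
exposes the receptor-rate calculators.

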