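# releasemix

Model-supported design of drug-release profiles from blends of polymeric
microparticle formulations.

Controlled-release systems built on biodegradable microparticles (for
example porous PLGA spheres loaded with a hydrophobic drug such as
curcumin) show release kinetics that depend strongly on how the drug was
encapsulated. Instead of re-engineering a single formulation for every
desired profile, a small library of formulations can be *blended*:
`releasemix` fits a first-order kinetic model to each formulation's
cumulative release curve, predicts any blend's release by mass-weighted
superposition, and inverts the prediction to design the blend fractions
that best achieve a target profile. It is aimed at formulation scientists
and modellers who have per-formulation release data (or raw UV–vis
absorbance series) and want quantitative, reproducible blend design.

## The model

Each formulation follows non-linear first-order release

```
Cr(t) = a (1 − exp(−b t)),   Cr(0) = 0,
```

with asymptote `a` (percent of loaded drug, or µg per aliquot — plateaus
slightly above 100 % are kept, not renormalised) and rate constant `b`
(1/h). A blend with mass-percent weights `Cn` (`Cn ≥ 0`, `Σ Cn = 100`)
releases the convex combination

```
Cr(t) = Σ Cn · an (1 − exp(−bn t)) / Σ Cn ,
```

and on the mass scale the blend's released µg is the `Cn`-weighted
average of the per-formulation released amounts for equal aliquot
masses. Inverse design minimises the squared deviation from a target
curve over the weight simplex; since the model is linear in the weights
this convex problem is solved exactly. A quantification layer converts
absorbance to released mass (Beer–Lambert, withdrawal-corrected mass
balance, encapsulation efficiency), and a synthetic-data generator
provides curves, formulation sets and full sampling protocols with known
ground truth.

## Worked example

Encode three published single-formulation release behaviours (72 h
released amounts of 3491, 291.3 and 42.47 µg for equal 5 mg aliquots of
oil-phase, water-phase and nano-emulsion encapsulations) and predict the
four classic blends at 72 h:

```r
library(releasemix)

rates <- c(0.03, 0.4, 0.6)          # representative rate constants, 1/h
vals  <- c(3491, 291.3, 42.47)      # released µg at 72 h, per formulation
a     <- vals / (1 - exp(-rates * 72))
oil   <- formulation("CUR-oil",   a = a[1], b = rates[1], scale = "mass_ug")
water <- formulation("CUR-water", a = a[2], b = rates[2], scale = "mass_ug")
ne    <- formulation("CUR-NE",    a = a[3], b = rates[3], scale = "mass_ug")

for (w in list(c(50, 50, 0), c(50, 0, 50), c(0, 50, 50), rep(100/3, 3)))
  print(signif(predict_mixture_mass(
    mixture_spec(list(oil, water, ne), w), t = 72), 4))
#> [1] 1891      # 50/50 oil/water
#> [1] 1767      # 50/50 oil/NE
#> [1] 166.9     # 50/50 water/NE
#> [1] 1275      # equal thirds
```

The 50/50 oil/water blend releases 1891 µg at 72 h — the arithmetic mean
of its components — while the equal-thirds blend gives 1275 µg: blending
a slow, high-capacity formulation with fast, low-capacity ones yields
intermediate profiles tunable by the weights.

Fitting and inverse design on synthetic data with known truth:

```r
curve <- generate_release_curve(
  first_order_params(a = 90, b = 0.1),
  noise = noise_model("proportional_gaussian", sigma = 0.05, seed = 42))
fit_first_order(curve)
#> First-order fit: a = 93.1742, b = 0.0971929 /h | RSS = 27.27,
#>   R2 = 0.9966, adj R2 = 0.9949 | n = 7, converged in 6 iter

slow <- formulation("slow", a = 70, b = 0.02)
fast <- formulation("fast", a = 105, b = 0.3)
tt <- c(1, 2, 4, 8, 24, 48, 72)
target <- release_curve(tt, predict_mixture_percent(
  mixture_spec(list(slow, fast), c(30, 70)), tt))
design_mixture(list(slow, fast), target)$weights
#> slow fast
#>   30   70
```

The noisy fit recovers the generating parameters to a few percent (the
expected precision at 5 % measurement noise), and the designed weights
recover the generating 30/70 split exactly on a noiseless target.

See `vignettes/release-kinetics.Rmd` for the full account of the model,
its assumptions, parameter defaults and limitations, and
`inst/cli/releasemix.R` for a thin command-line wrapper
(`fit | predict | design | simulate | run`).

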