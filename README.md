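# pamdct — one-step material decomposition for grating-based phase-contrast CT

Grating-interferometer CT measures two channels per view: log-normalized
absorption `M` (line integrals of the attenuation coefficient μ) and the
refraction angle `θ` (the detector-axis derivative of the line-integrated
refractive-index decrement δ).  At a monochromatic working energy both
coefficient maps are linear combinations of two basis materials,

    μ = μ₁ f + μ₂ g        δ = δ₁ f + δ₂ g,

so the object is described by two fraction maps `(f, g)`.  The classical
decompositions are two-step — decompose in the projection domain and then
reconstruct, or reconstruct μ and δ and then decompose per pixel — and both
amplify noise, through the running-sum inversion of the derivative or
through the Hilbert-kernel FBP.

`pamdct` implements the **one-step PAMD-SART reconstruction**: both
fraction maps are recovered directly from `(M, θ)` by minimizing

    Σ_φ ‖M^φ − (μ₁A^φf + μ₂A^φg)‖² + ‖θ^φ − (δ₁D A^φf + δ₂D A^φg)‖²
        + R(f) + R(g)

with view-wise coupled SART updates: per view, the absorption residual and
the boundary-anchored inversion of the phase residual are combined into
per-channel ray residuals

    A^φ(f − f⁽ᵐ⁾) ≈ (δ₂e_M − μ₂e_{D⁻¹θ}) / (μ₁δ₂ − μ₂δ₁),

backprojected with SART normalizations, followed by Chambolle
total-variation denoising of the fraction maps after every sweep.  The
package also provides both two-step baselines (Shepp-Logan and
Hilbert-kernel FBP, TV-regularized SART variants, projection- and
image-domain decomposition), synthetic phantoms with a bundled material
table, a photon-noise simulator, and a quantification layer that converts
fraction maps to electron density, effective atomic number
(`Z = (Σ ωⱼ Zⱼ^2.94)^(1/2.94)`) and virtual monochromatic attenuation via a
photoelectric + Klein-Nishina model — including the conditioning study and
dual-energy comparison that motivate the phase-absorption approach.

For the models, solver design decisions and validation protocol, see the
methods vignette (`vignettes/pamd-sart-methods.Rmd`).

## Worked example

Why one energy with two channels beats two energies with one channel —
conditioning of the 1-mm water/PMMA thickness systems:

```r
library(pamdct)
stability_demo()
#> Two-material decomposition stability
#>   system                cond(2)      angle      solution (cm)
#>   dual_energy             36.96      3.70° (0.0962, 0.1045)
#>   phase_absorption        11.66      9.93° (0.0982, 0.1022)
```

The phase-absorption system is three times better conditioned; both
systems solve to about 1 mm of each material, but the dual-energy solution
is visibly more perturbed by the 3-digit rounding of its inputs.

Simulate a noisy scan of the head phantom and decompose it in one step:

```r
ph   <- make_forbild_like(128, pixel_size = 1.024 / 128)
geo  <- scan_geometry(n_views = 180, n_det = 256, det_pitch = 0.004,
                      image_side = 128, pixel_size = 1.024 / 128)
pair <- add_noise(simulate_sinograms(ph, geo), photon_count = 1e6, seed = 1)
opts <- solver_options(n_iter_max = 20, stop_rule = "max_iter",
                       view_order = "random", seed = 1)
res  <- run_pamd_sart(pair, geo, opts)
res
#> <decomposition_result> pamd_sart: 128 x 128 maps, 20 iterations
sprintf("PSNR bone: %.1f dB, water: %.1f dB",
        psnr(res$f_star, ph$f), psnr(res$g_star, ph$g))
#> "PSNR bone: 49.3 dB, water: 44.2 dB"
```

`res$f_star` and `res$g_star` are the bone and water fraction maps
(dimensionless, near 0/1 in pure regions); `res$convergence` logs one row
per sweep (data-fidelity residuals, TV strengths).  Quantify the result:

```r
co <- default_quant_coefficients()     # working-energy calibration
q  <- maps_from_basis(res, ph$basis, co, E_virtual = 12)
mean(q$Z[ph$g == 1 & ph$f == 0], na.rm = TRUE)
#> 7.460   # effective Z of the water interior; theory 7.417
```

`q` also holds the electron-density map (`rho_e`, e/cm³) and the virtual
12 keV attenuation image; pixels without a physical solution (empty
background) are `NA` and counted in `q$n_masked`.

A thin command-line wrapper covers the same pipeline
(`inst/cli/pamdct.R`; subcommands `simulate`, `decompose`, `quantify`,
`metrics`, `demo-stability`), with multi-page TIFF + YAML sidecar files as
the on-disk format.

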