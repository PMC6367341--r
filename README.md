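# quenchbind

Analysis of small-molecule binding to serum albumin from fluorescence
quenching, time-resolved fluorescence, site-marker competition, circular
dichroism and structural models — the standard spectroscopic workflow used to
characterise how a ligand (a drug, a food colorant, a metabolite) binds the
main carrier protein of blood plasma.

## The scientific problem

When a ligand binds human serum albumin (HSA) it quenches the intrinsic
tryptophan fluorescence. A titration of ligand against protein answers, in
order:

1. **How strongly does it bind?** The Stern–Volmer slope (`F0/F = 1 +
   K_SV·[Q]`) gives the quenching constant; the double-logarithm plot
   (`log10((F0−F)/F) = log10 Ka + n·log10[Q]`) gives the association constant
   `K_a` and the number of binding sites `n`.
2. **By what mechanism?** Static (ground-state complex) quenching shows
   `K_SV` falling with temperature and an unchanged fluorescence lifetime;
   dynamic (collisional) quenching shows the opposite. Lifetimes come from
   multi-exponential tail fits of time-correlated single photon counting
   (TCSPC) decay histograms, summarised as the amplitude-weighted mean
   `τ̄ = Σ αᵢτᵢ`.
3. **Driven by which forces?** A van't Hoff fit of `ln K_a` against `1/T`
   yields ΔH and ΔS; their signs discriminate electrostatic, hydrophobic and
   hydrogen-bond/van-der-Waals interactions, and ΔG = −RT·ln K_a confirms
   spontaneity.
4. **At which site?** Competitive displacement against markers of known
   pockets (warfarin for Sudlow's site I, ibuprofen for site II, dansyl amino
   acids) localises the ligand.
5. **With what structural consequences?** Mean residue ellipticity at 208 nm
   from circular dichroism tracks α-helix content; Kabsch superposition,
   RMSD/radius-of-gyration time series and polar-contact screens quantify the
   structural models.

Every analysis function takes a data frame first and returns a tibble (or a
small S3 fit object with `tidy()`, `glance()` and `autoplot()` methods), and
every synthetic-data generator is seeded and deterministic, so whole analyses
are reproducible end to end.

## Worked example

Simulate a three-temperature titration (0.2% multiplicative noise), fit the
quenching and binding constants at each temperature:

```r
library(quenchbind)

titration <- gen_titration(noise_cv = 0.002, seed = 7)
constants <- quench_table(titration)
constants
#> # A tibble: 3 × 11
#>   temperature_K    K_SV K_SV_se sv_intercept sv_r_squared     K_a K_a_se     n
#>           <dbl>   <dbl>   <dbl>        <dbl>        <dbl>   <dbl>  <dbl> <dbl>
#> 1           298 125980.    496.        1.01         1.000  91780.  4725. 0.973
#> 2           304 110524.    870.        0.998        1.000 111301.  9941. 1.00
#> 3           310  99680.    407.        1.01         1.000  82324.  3789. 0.983
#> # ℹ 3 more variables: n_se <dbl>, dlog_r_squared <dbl>, affinity_class <chr>
```

Thermodynamics from a measured `K_a` series (here a published-style triple):

```r
ka <- tibble::tibble(temperature_K = c(298, 304, 310),
                     K_a = c(1.14e5, 1.03e5, 0.85e5))
vant_hoff(ka)
#> van't Hoff fit over 3 temperatures:
#>   dH = -18.748 +/- 3.56 kJ/mol, dS = 34.027 +/- 11.7 J/mol/K, R^2 = 0.96516
#>   dominant force: electrostatic; spontaneous: TRUE
#> # A tibble: 3 × 4
#>   temperature_K    K_a dG_kJ_mol ln_K_a_fitted
#>           <dbl>  <dbl>     <dbl>         <dbl>
#> 1           298 114000     -28.8          11.7
#> 2           304 103000     -29.2          11.5
#> 3           310  85000     -29.3          11.4
```

Lifetimes corroborate the mechanism — the mean lifetime barely moves on
binding, so the quenching is static:

```r
free  <- fit_decay(gen_decay(seed = 1), n_components = 3)
bound <- fit_decay(gen_decay(components = tibble::tibble(
  tau_ns = c(3.23, 5.32, 6.96), alpha = c(0.33, 0.03, 0.64)), seed = 2),
  n_components = 3)
comparison <- compare_lifetimes(free, bound)
comparison
#> # A tibble: 1 × 4
#>   tau_free tau_bound relative_change static_supported
#>      <dbl>     <dbl>           <dbl> <lgl>
#> 1     5.59      5.74          0.0269 TRUE

classify_mechanism(constants[, c("temperature_K", "K_SV")],
                   lifetime_change = comparison$relative_change)
#> [1] "static"
```

Site localisation and conformational read-out:

```r
assign_site(gen_competition(seed = 3))$site
#> [1] "site_I"

helix_change(gen_cd())
#> # A tibble: 3 × 4
#>   label      mre_208 helix_pct delta_helix_pct
#>   <chr>        <dbl>     <dbl>           <dbl>
#> 1 spectrum_1 -19103.      52.1            0
#> 2 spectrum_2 -18282.      49.2           -2.83
#> 3 spectrum_3 -17830.      47.7           -4.39
```

The same stages run end to end with `run_pipeline()`, which accepts tibbles or
CSV/PDB paths, records per-stage errors without aborting the rest, and writes
a deterministic JSON report via `write_report()`.

## License

MIT (see `LICENSE`).
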