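# smlmdemix

Spectral demixing and post-processing for split-channel single-molecule
localization microscopy (SMLM) in R.

## The problem

Multi-color SMLM with spectrally close far-red fluorophores (e.g. AF647,
CF660C, CF680) can be done in a single acquisition by splitting the emission
with a dichroic mirror into a short- (λ<sub>S</sub>) and a long-wavelength
(λ<sub>L</sub>) channel imaged side by side on one camera. Each molecule is
then localized twice, with photon counts I<sub>S</sub> and I<sub>L</sub>,
and its species is identified from the ratio

> r = I<sub>L</sub> / I<sub>S</sub>,

which depends only on the emission spectrum and the splitting dichroic.
Classical demixers take the output coordinates from a single channel, wasting
the other channel's photons: since localization precision is
σ = σ<sub>0</sub>/√I for I detected photons and PSF width σ<sub>0</sub>,
that costs up to a factor √(1 + r) in precision. `smlmdemix` implements the
photon-budget-preserving alternative: the demixed coordinate is the
photon-weighted mean of the two channel localizations,

> X = w<sub>S</sub> X<sub>S</sub> + w<sub>L</sub> X<sub>L</sub>,
> &nbsp;&nbsp; w<sub>c</sub> = I<sub>c</sub> / (I<sub>S</sub> + I<sub>L</sub>),

whose precision is exactly σ<sub>0</sub>/√(I<sub>S</sub> + I<sub>L</sub>) —
as if no splitter were present. The ratio-dependent residual chromatic shift
of the weighted mean is registered against the (chromatic-free) simple mean
of the two channels and removed by a polynomial field fit, giving
nanometer-scale chromatic correction from the data alone.

Around this core the package provides the full processing chain for split
acquisitions: localization-table I/O, channel ROI splitting and
registration, per-frame mutual-nearest-neighbor pairing (which doubles as a
powerful background/noise filter: a reliable molecule must appear in both
channels in the same frame), sector-based species assignment on the
bivariate photon-count histogram, cross-talk estimation from single-label
samples, consecutive-frame re-localization refinement
(σ = σ<sub>psf</sub>/√N<sub>ph</sub>), drift correction by time-binned image
cross-correlation on the sum of all demixed channels, Fourier ring
correlation (FRC 1/7) resolution estimates, particle profile statistics, and
a ground-truthed blinking-emitter simulator that generates every fixture
used in the tests.

## Worked example

Two fluorophore species with ratios r = 0.6 and r = 3.5 at the *same* true
position, 2000 photons per event split binomially between the channels, PSF
FWHM 300 nm (σ<sub>0</sub> ≈ 127.4 nm), and a constant chromatic offset of
(24, 8) nm on the λ<sub>L</sub> channel:

```r
library(smlmdemix)
library(dplyr)

cfg <- two_species_scenario(n_detections = 5000)
sim <- simulate_acquisition(cfg, seed = 42)

pairing <- pair_localizations(sim$table_s, sim$table_l, tolerance = 100)
labeled <- assign_species(pairing$pairs, two_species_sectors())
demixed <- demix_coordinates(labeled, method = "wmean_chroma",
                             chroma_degree = 0)

demixed |>
  group_by(species) |>
  summarise(n = n(), centroid_x = mean(x), centroid_y = mean(y),
            precision_x = sd(x))
#> # A tibble: 2 × 5
#>   species     n centroid_x centroid_y precision_x
#>   <chr>   <int>      <dbl>      <dbl>       <dbl>
#> 1 blue     5000       12.0       4.00        2.86
#> 2 red      5000       12.0       4.03        2.86
```

Both species land on the same corrected centroid (the residual
inter-species offset is far below 1 nm) and the x-precision of 2.86 nm
matches the full-photon-budget bound σ<sub>0</sub>/√2000 = 2.85 nm. Compare
the classical single-channel ("brightest") output on the same pairs:

```r
demix_coordinates(labeled, "brightest") |>
  group_by(species) |>
  summarise(centroid_x = mean(x), precision_x = sd(x))
#> # A tibble: 2 × 3
#>   species centroid_x precision_x
#>   <chr>        <dbl>       <dbl>
#> 1 blue      24.0            3.24
#> 2 red        0.00544        3.62
```

The two species are read from opposite channels, so the full 24 nm chromatic
error reappears between them, and the precision is 14–27% worse. The
break-even analysis behind these trade-offs is available in closed form:
`demix_precision()` and `break_even_ratio()` (the simple mean beats the
brightest channel exactly up to r = 3).

A command-line wrapper covering the whole workflow
(`simulate`, `pair`, `demix`, `crosstalk`, `refine`, `drift`, `render`,
`frc`, `radial`, `sideview`, `wavelength`) is installed at
`system.file("cli", "smlmdemix.R", package = "smlmdemix")`.

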