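# pupilbench

Benchmarking classical luminance-based pupil light models against
pupillometry data.

## What this is for

The steady-state human pupil diameter has been modeled since 1926 by
closed-form functions of photopic luminance — Holladay, Crawford,
Moon & Spencer, De Groot & Gebhard, Stanley & Davies, Barten,
Blackie & Howland, and the unified formula of Watson & Yellott, which adds
adapting-field size $\alpha$ (deg²), observer age $y$ and the number of
exposed eyes:

$$D_{SDW}(L, \alpha, e) = 7.75 - 5.75\,
  \frac{(L\alpha e/846)^{0.41}}{(L\alpha e/846)^{0.41} + 2}, \qquad
  D_{WY} = D_{SDW} + (y - y_0)\left[0.02132 - 0.009562\,D_{SDW}\right]$$

with $y_0 = 28.58$ years and $e = 0.1$ (one eye) or $1$ (both). All of
these models see the stimulus only through a V(λ)-weighted quantity. Under
melanopsin-rich (short-wavelength) light at constant luminance the
sustained pupil constriction is systematically stronger than any of them
predicts, which matters whenever a multi-channel LED luminaire is used to
engineer spectra at fixed luminance and chromaticity.

`pupilbench` is for vision and lighting researchers who want to quantify
those prediction errors: it provides the model library with
adaptation-field angle conversions, spectral stimulus characterization
(luminance, CIE 1931/1976 chromaticity, CCT/duv, receptor-weighted
radiances), a pupillometry preprocessing pipeline (blink and quality
filtering, velocity-percentile outlier rejection, interpolation,
Savitzky–Golay smoothing with an unsmoothed 3 s lead-in), a
prediction-error benchmark with repeated-measures ANOVA
(Mauchly/Greenhouse–Geisser, Bonferroni pairwise tests), and a seeded
synthetic cohort generator with ground truth for validating the pipeline
end to end.

## Worked example

Predict the pupil diameter for a 100 cd/m² stimulus filling a 53.13°
circular-equivalent field, viewed binocularly by a cohort of mean age
22.2 years:

```r
library(pupilbench)

predict_diameter("crawford", 100)
#> crawford: 3.006 mm

predict_diameter("watson_yellott",
                 viewing_conditions(100, benchmark_field(),
                                    age_years = 22.2, eyes = 2))
#> watson_yellott: 3.019 mm
#>   (base diameter D_SDW: 2.974 mm)
```

(The Crawford value is 3.00649 mm at full precision — the printed
three-decimal display rounds down where the original report rounded up.)

Simulate a 20-subject study (seven stimuli: 450/530/610/660 nm chromatic
plus ~2000/5000/10000 K Planckian-locus mixtures of a 15-channel LED
luminaire, each preceded by a 300 s anchor), clean every trace, and
benchmark three models:

```r
stimuli <- study_stimuli()                 # 7 stimuli at 100 cd/m^2
cohort  <- generate_cohort(20, stimuli, seed = 303)
write_cohort(cohort, "cohort/")
report  <- run_full_benchmark("cohort/")
subset(report$errors,
       exposure_time_s == 300 & stimulus %in% c("led450", "led610"))
#>         model_id stimulus exposure_time_s mean_error_mm sd_error_mm  n
#>         crawford   led450             300        -0.905       0.640 20
#>         crawford   led610             300        -2.579       0.539 20
#>  degroot_gebhard   led450             300        -0.730       0.640 20
#>  degroot_gebhard   led610             300        -2.404       0.539 20
#>   watson_yellott   led450             300        -0.892       0.640 20
#>   watson_yellott   led610             300        -2.566       0.539 20

report$anova[["300"]]$pairwise   # Bonferroni pairwise t-tests, 300 s
#>              pair mean_diff_mm      t df         p p_bonferroni
#>  led450 vs led610       -1.677 -17.52 19 3.467e-13     7.28e-12
#>  ...
```

The `mean_error_mm` column is predicted − measured on absolute diameters.
The load-bearing number is the ≈1.7 mm separation between the 450 nm and
610 nm conditions, identical for every model: it is the melanopsin-driven
sustained constriction that no luminance-only model can see, and the
repeated-measures ANOVA flags it on the baseline-corrected diameters. The
overall negative offset is a property of the synthetic generator (its
subjects re-dilate to a dim baseline between stimuli — see the vignette),
so the spread across stimuli, not the absolute error level, is the
meaningful readout. All numbers above are from the seeded run shown and
reproduce bit-for-bit.

A thin CLI over the same functions is installed at
`inst/cli/pupilbench` (`predict`, `metrics`, `preprocess`, `simulate`,
`benchmark` subcommands).

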