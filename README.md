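# coiwave

Quantifies how intracardiac electrograms (iEGMs) change in the minutes
after an atrial ablation, and whether those changes predict lesion
transmurality — the question that matters for intraprocedural guidance of
pulsed field ablation (PFA), where bipolar electrogram abolition alone is
an unreliable endpoint.

The package is aimed at cardiac electrophysiology researchers and signal
methodologists. It implements, as tested R functions:

* **QRS-gated atrial windowing** — adaptive slope-threshold R-peak
  detection on a 10 Hz high-passed ECG, then a 150 ms analysis window
  `[R − 200 ms, R − 50 ms)` per beat;
* **10-second segmentation with artifact exclusion** — segments aligned to
  the ablation instant; a segment is dropped when strictly more than 20%
  of its beats are contaminated (rail contact, 8x amplitude outliers,
  saturation overlap); unipolar data are only valid from 30 s
  post-ablation (amplifier saturation after PFA);
* **db6 wavelet multiresolution analysis** — 9 dyadic detail levels at
  1 kHz; the high-frequency preset D1–D3 spans 62.5–500 Hz and captures
  the depolarization spike of bipolar iEGMs, the low-frequency preset
  D6–D9 spans ~0.98–15.6 Hz and captures the current-of-injury (COI)
  baseline shift of unipolar iEGMs; reconstruction is exact
  (sum of details + approximation = input);
* **peak-to-peak feature series** — per-segment medians of per-beat
  peak-to-peak sub-band amplitudes, normalized to a pre-ablation
  reference (bipolar HF) or to the first valid post-ablation value
  (unipolar LF);
* **group statistics** — linear mixed-effects model
  `value ~ time * group + (1 | animal)` (REML, Satterthwaite ANOVA) on
  30 s–3 min post-ablation, per-timepoint t / Mann-Whitney tests chosen by
  normality and variance checks, per-lesion recovery slopes;
* **early transmurality calls** — the normalized unipolar LF value near
  60 s post-ablation, thresholded by Youden's J: fast COI recovery
  indicates a nontransmural PFA lesion;
* **a synthetic signal generator** — three-channel 1 kHz recordings with
  ground-truth beat times, group-dependent effect trajectories (COI level
  `f + (j − f)·exp(−(t−30)/τ)`, HF survival `p − (p − d)·exp(−t/τ)`),
  post-PFA amplifier saturation, movement artifacts and per-animal
  amplitude effects, so the whole pipeline is testable without animal
  recordings.

## Worked example

Simulate a small cohort (12 PFA lesions, half transmural, plus 8 RFA
lesions, 200 s of post-ablation recording, 5 animals) and run the whole
pipeline:

```r
library(coiwave)

cfg <- pipeline_config(
  generator = generator_config(duration_post_s = 200),
  cohort = list(n_pfa_trans = 6, n_pfa_nontrans = 6,
                n_rfa_trans = 4, n_rfa_nontrans = 4),
  seed = 1
)
res <- run_pipeline(cfg)
res
#> cohort_result: 20 lesions, 5 animals
#> mixed-effects comparisons:
#> # A tibble: 4 × 4
#>   comparison            channel_band    p_time p_interaction
#>   <chr>                 <chr>            <dbl>         <dbl>
#> 1 PFA_trans_vs_nontrans bipolar_HF   2.56e-63      1.74e-64
#> 2 PFA_trans_vs_nontrans unipolar_LF  1.04e-79      5.49e-15
#> 3 PFA_vs_RFA            bipolar_HF   1.03e- 1      1.35e- 1
#> 4 PFA_vs_RFA            unipolar_LF  2.08e-33      5.51e-13
#> transmurality calls (threshold 0.773): balanced accuracy 1.00
```

Reading the output: on the unipolar low-frequency band the
time-by-group interaction for transmural vs nontransmural PFA lesions is
p ≈ 5e-15 — the two groups recover their current of injury at different
rates over 30 s–3 min, the effect the method exploits. The calibrated
decision rule (normalized LF value near 60 s, threshold 0.773) classifies
every simulated lesion correctly. Median per-lesion recovery slopes make
the asymmetry concrete: −0.0041/s for nontransmural vs −0.0025/s for
transmural PFA lesions on the LF band, while the bipolar HF band recovers
only for nontransmural PFA (+0.0014/s vs −0.00002/s).

```r
autoplot(res, band = "unipolar_LF")      # group medians with IQR ribbons
tidy(fit_lme(...)); glance(fit_lme(...)) # broom-style access to the LME
```

Individual stages are exported (`detect_qrs()`, `mra_decompose()`,
`build_feature_series()`, `per_timepoint_test()`, ...) and documented;
the vignette in `vignettes/coi-dynamics.Rmd` explains the model, the
parameter choices and the generator's scope.

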