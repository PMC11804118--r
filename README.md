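# epilfp

Headless analysis of local field potential (LFP) recordings from epilepsy
animal models: automatic epileptiform spike detection, zero-phase bandpass
filtering, spike-morphology slope metrics, inter-channel spike coincidence,
and Pearson correlation — plus a seeded synthetic LFP generator with planted
ground truth, so every analysis can be validated end to end without access
to annotated animal recordings. It is written for electrophysiologists and
analysis engineers who want the classic interactive spike-analysis workflow
as a scriptable, reproducible library with a command-line entry point.

## The method

An epileptiform spike is a transient deflection above the recording
baseline, sharp in shape, 20–80 ms long, typically followed by a slow wave.
Detection applies three thresholds jointly:

* **moving amplitude threshold** — within each 1-s analysis window,
  threshold = *p*% of the window's maximum rectified amplitude (for
  *p* = 60 and a 1-mV window maximum: 0.6 mV), tracking the large amplitude
  variation of epileptiform activity;
* **fixed amplitude floor** — a minimum acceptable amplitude in mV; the
  per-sample effective threshold is max(moving, fixed);
* **temporal threshold** — a minimum distance between consecutive spikes,
  enforced greedily in descending amplitude order so polyphasic complexes
  count once, at their dominant deflection.

Around the detector: 10–100 Hz bandpass filtering with exact zero phase
(forward–reverse–forward application of a least-squares/Hann FIR or
Butterworth IIR design); slope metrics (rising, descent, overall) of the
averaged spike waveform; one-to-one coincidence matching of two channels'
spike trains within a time window, reported as
100·n_matched/n_ref; and Pearson's
r = Σ(aᵢ−â)(bᵢ−b̂)/((n−1)·σ_A·σ_B) between channels. The methods vignette
(`vignettes/epilfp-methods.Rmd`) documents every convention and default.

## Worked example

Simulate a 60-s recording (1 kHz, ~30 planted 1-mV spikes on 0.05-mV
band-limited noise), detect with the standard settings, and analyze:

```r
library(epilfp)

sim <- simulate_channel(synth_spec(duration = 60, seed = 42), animal_id = "R01")
det <- detect_spikes(sim$recording, "ch1",
                     percent = 40, fixed_thr = 0.1, min_dist = 0.1)
det
#> <spike_detection> channel 'ch1', span [0, 60) s
#>   thresholds: moving 40% / fixed 0.1 mV / refractory 0.1 s
#>   28 spike(s), rate 0.467 /s, amplitude 0.988 [0.775, 1.169] mV

score_detection(sim$truth$time_s, det$events$time_s, tol = 0.01)
#> # A tibble: 1 × 6
#>   n_true n_detected n_matched precision recall    f1
#>    <int>      <int>     <int>     <dbl>  <dbl> <dbl>
#> 1     28         28        28         1      1     1

spike_morphology(sim$recording, det)
#> <spike_morphology> channel 'ch1', 28 epoch(s) averaged (0 edge-dropped)
#>   rising 98.63 mV/s, descent -49.51 mV/s, overall 65.88 mV/s
#>   support: 10.0 ms before to 20.0 ms after the peak
```

All 28 planted spikes are recovered with no false positives, and the average
waveform reproduces the planted template's analytic slopes (100 mV/s rise
over 10 ms, −50 mV/s fall over 20 ms) to within ~1.5%. Coincidence between a
simulated channel pair with a planted 60% recurrence probability:

```r
pair <- simulate_pair(synth_spec(duration = 120, seed = 42))
ref  <- detect_spikes(pair$reference,  "ref",  40, 0.1, 0.1)
comp <- detect_spikes(pair$comparison, "comp", 40, 0.1, 0.1)
spike_coincidence(ref, comp, window = 0.1)
#> <spike_coincidence> window 0.1 s, span [0, 120) s
#>   36 / 49 reference spikes coincident = 73.47% (0.3000 matches/s; 56 comparison spikes)
```

(73% on 49 reference spikes is within sampling error of the planted 60%
plus the expected chance coincidences of the independent comparison spikes;
the test suite checks the binomial recovery on ~200-spike runs.)

Every result type has `tidy()` (event/pair/waveform tables), `glance()`
(one-row summary) and `autoplot()` (ggplot2) methods, and
`write_result()`/`read_result()` persist results as self-describing JSON
with `experiment` and `analysis` sections under deterministic
`{analysis}_{animal}[_{channel}].{ext}` names.

### Command line

```sh
Rscript inst/cli/lfp-analyze simulate --duration 60 --seed 42 --animal R01 --outdir out
Rscript inst/cli/lfp-analyze detect --in out/recording_R01_ch1.csv --fs 1000 \
    --percent 40 --fixed 0.1 --mindist 0.1 --animal R01 --outdir out
Rscript inst/cli/lfp-analyze morph --in out/recording_R01_ch1.csv --fs 1000 \
    --detection out/detection_R01_ch1.json --animal R01 --outdir out
```

Subcommands: `simulate`, `filter`, `detect`, `morph`, `coincide`,
`correlate`. Flags override a JSON `--config` file, which overrides the
defaults; logs go to stderr (`--quiet` silences them).

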