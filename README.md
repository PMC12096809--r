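# vocsel

Selectivity of cortical responses to bat vocalizations: stimulus
synthesis, spiking-unit simulation, pure-tone tuning metrics,
response-strength preference indices, and single-trial spike-pattern
classification into call categories.

## What it is for

Auditory neuroscientists comparing how specifically single cortical units
encode behaviorally distinct call types — echolocation clicks,
appeasement calls, aggression trains — need two complementary selectivity
measures per unit:

* **Response strength.** Spikes are counted in 2-ms bins of the
  trial-summed PSTH inside a shared response window. The category
  preference index counts categories whose summed response reaches at
  least 50 % of the maximum: `PIcat = #{c : R_c >= 0.5 max_c R_c}`, from 1
  (fully selective) to 3 (unselective); `PIcall` is the analogous count
  over the five calls of one category (1–5).

* **Temporal spike pattern.** Each single-trial PSTH (1-ms bins) is
  convolved with a unit-area Gaussian integration window (2 ms for a fine
  temporal code, 200 ms for a rate-like code) and assigned to the class of
  the Euclidean-nearest template drawn from the other presentations
  (forced choice on ties). 10,000 resamples build a row-stochastic
  confusion matrix `P`, summarized per row by the selectivity index
  `SI = max(p) − (mean(rest) + sd(rest))`, with maximum 1 and chance
  value 0.

Because the underlying recordings are not shared, the package also ships a
synthetic stimulus library (15 calls, 3 × 5, at 192 kHz) and an
inhomogeneous-Poisson unit simulator with frontal-auditory-field-like
(tonic, 35-ms latency, jittery) and dorsal-auditory-cortex-like (phasic,
6-ms latency, envelope-locked) presets, so every stage is testable end to
end. Pure-tone tools recover the standard tuning metrics (FRA, BF, CF,
Q10dB, latency, response duration) from a 5–80 kHz, 1/8-octave × 80–15 dB
grid.

## Worked example

```r
library(vocsel)

lib <- synth_call_library(seed = 1)
lib
#> <call_library> 15 calls in 3 categories
#>   echolocation echo_1 echo_2 echo_3 echo_4 echo_5 (1.6-2.8 ms)
#>   appeasement  app_1 app_2 app_3 app_4 app_5 (27.3-45.3 ms)
#>   aggression   aggr_1 aggr_2 aggr_3 aggr_4 aggr_5 (139.8-260.2 ms)

man <- call_manifest(lib)
categories <- setNames(man$category, man$call_id)

unit <- dac_profile(unit_id = "example")          # phasic, envelope-locked
protocol <- trial_protocol(post_stimulus_ms = 450, n_trials = 20, seed = 5)
responses <- lapply(lib$calls, simulate_call_response,
                    profile = unit, protocol = protocol)

pref <- preference_result(responses, categories)
pref
#> <preference_result> PIcat = 1; PIcall: echolocation=4, appeasement=5, aggression=5
pref$window
#> <response_window> [54.0, 316.0) ms (262.0 ms)

cm <- confusion_matrix(responses, categories, level = "category",
                       integration_window_ms = 200, window = pref$window,
                       n_resamples = 10000, seed = 42)
cm
#> <confusion_matrix> category level, 200-ms integration, 10000 resamples
#>              echolocation appeasement aggression
#> echolocation        0.975       0.025      0.000
#> appeasement         0.053       0.947      0.000
#> aggression          0.002       0.022      0.977

selectivity_index(cm$probs["aggression", ])
#> <selectivity_index> SI = 0.951 (best: aggression)
```

Reading the output: this unit responds most strongly to a single category
(`PIcat = 1`) but to most individual calls within each category
(`PIcall` 4–5); its temporal spike patterns are distinctive enough that
single trials are assigned to the correct category ≥ 95 % of the time, and
the aggression row's SI of 0.95 is close to the theoretical maximum of 1.

`run_pipeline(seed = 1, n_faf = 20, n_dac = 20)` runs the whole chain on
jittered FAF-like and dAC-like cohorts and returns per-unit tables plus
group comparisons (t / Wilcoxon rank-sum / ANOVA + Tukey via the standard
R tests). `tuning_summary(simulate_tone_grid(unit))` returns the pure-tone
metrics for one unit.

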