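# Demo run: two life-stage-like groups through every pipeline stage.
# Calcium: AIB-like contrast (dauer cohorts respond, adult cohorts mostly
# silent). Behavior: dauer-like prolonged CO2-evoked pausing vs adult-like
# transient slowing. Chemotaxis: attraction in dauers/starved adults,
# repulsion in well-fed adults.
seed: 1
out_dir: runs/demo

calcium:
  neuron: AIB
  protocol: {pre_s: 30, pulse_s: 60, post_s: 60, frame_rate: 2}
  groups:
    dauer:
      n_animals: 16
      class_mix: [0.65, 0.05, 0.30]
      amplitude: {kind: uniform, min: 20, max: 35}
    starved_adult:
      n_animals: 16
      class_mix: [0.12, 0.05, 0.83]
      amplitude: {kind: uniform, min: 15, max: 25}
  air_controls: {n_animals: 12}
  analysis:
    k_sd: 3
    clustering: {metric: euclidean, linkage: average}

behavior:
  protocol: {pre_s: 20, pulse_s: 60, post_s: 40, frame_rate: 5}
  groups:
    dauer_like: {preset: dauer_like, n_animals: 12, conditions: [CO2, air]}
    adult_like: {preset: adult_like, n_animals: 12, conditions: [CO2, air]}
  analysis:
    smooth_s: 1
    pause_speed_mm_s: 0.02
    min_bout_s: 0.6
    reversal_angle_deg: 120

chemotaxis:
  groups:
    well_fed_adult: {p_test: 0.25, n_worms: 60, n_plates: 8}
    starved_adult: {p_test: 0.80, n_worms: 60, n_plates: 8}
    dauer: {p_test: 0.82, n_worms: 60, n_plates: 8}

stats:
  plan:
    - {name: aib_peak_dauer_vs_adult, stream: calcium, metric: max_pct,
       test: welch_t, groups: [dauer, starved_adult]}
    - {name: aib_excitatory_fraction, stream: calcium,
       test: fisher_excitatory, groups: [dauer, starved_adult]}
    - {name: speed_early_co2_vs_air, stream: behavior, metric: speed_early,
       test: anova2_sidak}
    - {name: speed_late_co2_vs_air, stream: behavior, metric: speed_late,
       test: anova2_sidak}
    - {name: pause_ratio_co2_vs_air, stream: behavior, metric: pause_ratio,
       test: anova2_sidak}
    - {name: chemotaxis_by_stage, stream: chemotaxis, test: kruskal_dunn}
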