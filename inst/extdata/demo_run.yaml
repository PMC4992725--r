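# Demonstration run: a small simulated cohort driven end to end.
seed: 11
simulate:
  n_pd: 5
  n_hc: 5
  noise_sd: 10
  iron_noise_sd: 5
  repeats: 2
group_compare: [sn_volume_contra, cnr_sn_contra, cnr_lc_contra]
battery:
  - [sn_volume_contra, putamen_contra]
  - [cnr_sn_contra, putamen_contra]
  - [cnr_lc_contra, putamen_contra]
roc:
  measure: sn_volume_contra
  direction: lower
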