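# Reduced-size demo configuration for run_pipeline(); all keys are optional
# and override the defaults of pipeline_config().
cjs:
  models:
    - phi: [site, age]
      p: [site]
    - phi: [age]
      p: [site]
    - phi: []
      p: []
extinction:
  intervals: [15, 10, 5]
  replicates: 2000
abm:
  config:
    days: 60
  replicates: 5
stats:
  adjust: holm
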