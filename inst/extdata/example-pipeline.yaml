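# Example curation pipeline configuration for mscurate-cli.R / read_pipeline_config()
mapping:
  study: [healthy, disease]
  qc: [QC]
  blank: [blank]
steps:
  - name: rt_range_filter
    params: {min_rt: 90}
  - name: qc_presence_filter
    params: {min_qc_dr: 1, require_bracket: true}
  - name: blank_correction
    params: {mode: threshold_subtract, fold_threshold: 10}
  - name: loess_batch_correction
    params: {frac: auto}
  - name: variation_filter
    params: {max_value: 0.2, estimator: robust_rsd}
  - name: prevalence_filter
    params: {lower: 1, upper: 1, threshold: 5, mode: intraclass}
  - name: dratio_filter
    params: {max_ratio: 0.1}
  - name: total_area_normalization
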