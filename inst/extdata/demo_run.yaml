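# Bundled demo configuration: a small serrated-pathway cohort with a planted
# continuum, one chromosome-arm gain and three gene programs. Runs the whole
# pipeline in well under a minute on one CPU.
seed: 1
out_dir: "demo_results"
stages:
  simulate: true
  qc: true
  composition: true
  cnv: true
  score: true
  continuum: true
simulate:
  n_samples_per_stage: {normal: 2, SSL: 2, SSLD: 1, TSA: 1, tumor: 2}
  n_cells_per_sample: 60
  n_genes: 400
  n_continuum_genes: 60
  slope_range: [1, 3]
  nb_dispersion: 0.5
  cnv_segments:
    - arm: "7p"
      copy_ratio: 1.8
      stages: ["tumor"]
  program_defs:
    EMT: {n_genes: 25, log2_elevation: 1.4427, cell_fraction: 0.4, stages: ["tumor"]}
    S: {n_genes: 25, log2_elevation: 1.4427, cell_fraction: 0.15}
    G2M: {n_genes: 25, log2_elevation: 1.4427, cell_fraction: 0.15}
qc:
  min_genes: 50
  max_mito_pct: 20
composition:
  pairs: "normal:SL,SL:tumor"
  merge_sl: true
cnv:
  reference_stage: "normal"
  window: 21
continuum:
  target_subtype: "SLC1"
  reference_stage: "normal"
  alpha: 0.05
  min_samples: 2
  axis: "PC2"
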