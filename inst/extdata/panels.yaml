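# Assay definitions for the three multigene panels.
# Published constants (Oncotype metagene weights and their within-group averaging
# weights, the published 20*(RSu - 6.7) rescale form) are packaged verbatim from
# Paik et al. 2004. Quantities the vendors never published (subtype centroids, ROR
# weights, 0-100 rescale constants, gene70 template/cutoff) are SYNTHETIC
# stand-ins: structurally faithful, auditable, and swappable for real values.
# truth_rescale blocks are the synthetic "vendor" 0-100 maps used by the cohort
# generator; they were calibrated once so default cohorts span roughly 5-95.
prosigna:
  panel_file: prosigna_panel.tsv
  centroids_file: prosigna_centroids_synthetic.tsv
  ror_weights:
    subtype:
      LumA: -0.35
      LumB: 0.35
      Her2E: 0.25
      Basal: 0.25
    proliferation: 0.55
    size: 0.25
  truth_rescale:
    ROR:    {offset: 50.0, slope: 70.0}
    ROR_P:  {offset: 46.0, slope: 32.0}
    ROR_PT: {offset: 45.0, slope: 30.0}
oncotype:
  panel_file: oncotype_panel.tsv
  metagene_weights:
    proliferation: 1.04
    her2: 0.47
    er: -0.34
    invasion: 0.10
    cd68: 0.05
    gstm1: -0.08
    bag1: -0.07
  published_rescale: {offset: -134.0, slope: 20.0}
  truth_rescale: {offset: 50.0, slope: 10.0}
  gstm1_threshold: true
  ctsl2_excluded: true
  gstm1_background: 0.0
  measurement_range: [2.5, 12.5]
mammaprint:
  panel_file: mammaprint_panel_synthetic.tsv
  template_file: gene70_template_synthetic.tsv
  correlation_cutoff: 0.4
aliases_file: gene_aliases.tsv
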