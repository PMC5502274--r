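# Demonstration pipeline: a small synthetic water-deficit study with two
# planted co-response modules, one module-linked anthocyanin-like metabolite,
# and one planted ABRE promoter element.
simulation:
  n_genes: 300
  n_metabolites: 8
  seed: 11
  modules:
    - module_id: M1
      size: 60
      response_pattern: [0.0, 0.3, 1.2, 2.0, 2.5]
    - module_id: M2
      size: 60
      response_pattern: [2.4, 0.1, 1.3, 0.3, 2.1]
  metabolite_links:
    - metabolite_id: anthoA
      module_id: M1
      link_strength: 0.95
    - metabolite_id: prolineB
      module_id: M2
      link_strength: 0.9
  motif_plants:
    - motif: ACGTGKC
      module_id: M1
      carrier_fraction: 0.6
      background_fraction: 0.05
  extra_motifs: [CACGTG, RYCGAC, GCCGCC]
policy:
  n_perm: 1000
network:
  max_genes: 150
outdir: demo_out
seed: 11
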