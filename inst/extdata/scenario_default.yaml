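# Packaged synthetic scenario: 500 proteins, 10% planted chromatin
# binders with contact regions inside IDRs, log2 effect size 2,
# three replicates per peptide fraction.
mode: spacemap
seed: 1
simulate:
  n_proteins: 500
  frac_planted: 0.1
  effect_log2: 2
  contact_class: IDR
  n_replicates: 3
thresholds:
  fc: 1
  tier1_alpha: 0.01
  tier2_alpha: 0.1
max_gap: 10
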