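# Folding demo: 15-residue coarse-grained helix from the extended chain.
# Used by:  Rscript inst/cli/boostmd.R demo-fold --config inst/examples/cg_helix.yaml
seed: 1
system:
  kind: cg_helix
  n_res: 15
simulation:
  timestep: 0.005        # ps
  temperature: 300       # K
  collision_frequency: 1.0
  n_steps: 2000000
  save_interval: 2000
boost:
  mode: dual
  a1: 3.5                # kcal/mol per 5 residues
  a2: 0.2                # kcal/mol per atom
  prerun_steps: 200000
  burn_in_frac: 0.5
analysis:
  native: ideal_helix
  contact_cutoff: 7.0
  min_seq_sep: 2
  bins: 40
output:
  dir: demo_out
  prefix: helix
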