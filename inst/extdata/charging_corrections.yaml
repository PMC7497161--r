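# Charging-correction totals for net-charge-changing perturbations, keyed by
# mutation and cycle context. Terms from external continuum-electrostatics
# runs; only totals are available, folded into dG_pol (the dominant
# polarization term). Perturbations that conserve net charge carry no entry.
- mutation: Asp323Thr
  context: TI-path1
  dG_pol: -0.3
- mutation: Val279Glu
  context: TI-path1
  dG_pol: 1.8
- mutation: Val279Glu
  context: TI-path2
  dG_pol: 3.2
- mutation: Asp323Thr
  context: TI-path2
  dG_pol: -2.7
- mutation: Asp323Thr
  context: bind-path1
  dG_pol: -0.2
- mutation: Asp323Thr
  context: bind-path2
  dG_pol: -0.2
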