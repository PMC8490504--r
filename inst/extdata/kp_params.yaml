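# Default kinetic parameters of the tryptophan/kynurenine network.
# These are this package's own defaults (order-of-magnitude plausible for
# tissue Trp catabolism), versioned here so analyses can pin or override them.
# Units: Vmax mM/h, Km mM, k_clear 1/h, trp_ext mM.
trp_ext: 0.01
epsilon: 0.01
k_clear: 0.5
vmax:
  uptake: 0.05
  TPH: 0.01
  IDO1: 0.03
  TDO2: 0.03
  AFMID: 0.10
  KMO: 0.05
  KYNU_a: 0.02
  KYNU_b: 0.05
  HAAO: 0.10
km:
  uptake: 0.05
  TPH: 0.05
  IDO1: 0.02
  TDO2: 0.02
  AFMID: 0.05
  KMO: 0.01
  KYNU_a: 0.05
  KYNU_b: 0.05
  HAAO: 0.01
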