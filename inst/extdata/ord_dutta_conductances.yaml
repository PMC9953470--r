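# Baseline maximal conductances / permeabilities of the O'Hara-Rudy human
# ventricular myocyte model (endocardial baseline values) together with the
# Dutta et al. CiPA conductance-optimization scalers applied to the five
# repolarization-critical currents. Units follow the original model
# formulation (mS/uF for conductances, cm/s-equivalent permeabilities for
# PCa/PNab/PCab).
model_version: ORd2011-dutta2017-v1
base_conductances:
  GNa: 75.0
  GNaL: 0.0075
  Gto: 0.02
  PCa: 0.0001
  GKr: 0.046
  GKs: 0.0034
  GK1: 0.1908
  Gncx: 0.0008
  Pnak: 30.0
  GKb: 0.003
  PNab: 3.75e-10
  PCab: 2.5e-8
  GpCa: 0.0005
dutta_scalers:
  IKr: 1.013
  IKs: 1.870
  IK1: 1.698
  ICaL: 1.007
  INaL: 2.661
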