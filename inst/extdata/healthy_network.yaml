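# Canonical healthy flexor-extensor CPG configuration.
#
# This file is the single source of truth for the healthy model. Disease
# stages and interventions (see stages.yaml and intervention_config()) are
# declarative transforms applied on top of it; they never edit this file.
#
# Topology (one side of the lumbar cord, flexor-driven architecture):
#   - RG_F / RG_E half-centers (4:1 E:I, 30% / 10% bursting neurons) with
#     recurrent excitation and within-population inhibition.
#   - Mutual RG inhibition through two relay populations: RG_F -> V2b -| RG_E
#     and RG_E -> V1RG -| RG_F.
#   - RG -> V2a -> MNP excitatory output chain on each side.
#   - Reciprocal Ia inhibition: each Ia population is named after the
#     motoneuron pool it inhibits and is excited by the antagonist RG
#     (RG_E -> Ia_F -| MNP_F, RG_F -> Ia_E -| MNP_E) plus a tonic drive.
#   - Recurrent inhibition: MNP -> RC -> MNP on each side.
#   - Cholinergic V0c -> MNP excitation under tonic drive.
#   - V1 inhibition of flexor motoneurons is stronger than of extensor
#     motoneurons (stronger V1 connectivity to flexor pools), which is what
#     makes V1 loss produce flexor-biased activity.
#
# Weights (nS, peak-normalized conductances), probabilities and drives (pA)
# were tuned so the healthy network oscillates at 2-3 Hz with motoneuron
# peak rates below 100 Hz, alternating flexor-extensor output and an
# extensor-dominated step cycle.

drive_sd_fraction: 0.25

neuron_defaults:
  tonic:    {C: 200, gL: 10, EL: -70, DeltaT: 2, Vth: -50, tau_w: 100,
             a: 2, b: 40, Vreset: -58, t_ref: 3, Ee: 0, Ei: -75, Ibias: 0}
  bursting: {C: 200, gL: 10, EL: -58, DeltaT: 2, Vth: -50, tau_w: 280,
             a: 4, b: 75, Vreset: -46, t_ref: 2, Ee: 0, Ei: -75, Ibias: 0}

kinetics:
  exc: {tau_rise: 0.5, tau_decay: 4.0, sign: excitatory}
  inh: {tau_rise: 0.5, tau_decay: 6.0, sign: inhibitory}

populations:
  - {name: RG_F, "n": 60, excitatory_fraction: 0.8, bursting_fraction: 0.30,
     drive_mean: 222}
  - {name: RG_E, "n": 60, excitatory_fraction: 0.8, bursting_fraction: 0.10,
     drive_mean: 310, tonic: {b: 80, tau_w: 400}}
  - {name: V1RG, "n": 25, excitatory_fraction: 0}
  - {name: V2b, "n": 25, excitatory_fraction: 0}
  - {name: V2a_F, "n": 36}
  - {name: V2a_E, "n": 36}
  - {name: V0c_F, "n": 30, drive_mean: 280}
  - {name: V0c_E, "n": 30, drive_mean: 280}
  - {name: Ia_F, "n": 36, excitatory_fraction: 0, drive_mean: 320}
  - {name: Ia_E, "n": 36, excitatory_fraction: 0, drive_mean: 320}
  - {name: RC_F, "n": 25, excitatory_fraction: 0}
  - {name: RC_E, "n": 25, excitatory_fraction: 0}
  - {name: MNP_F, "n": 50, drive_mean: 340, tonic: {t_ref: 7, b: 25, tau_w: 150}}
  - {name: MNP_E, "n": 50, drive_mean: 265, tonic: {t_ref: 7, b: 17, tau_w: 300}}

projections:
  # within-RG recurrent wiring
  - {pre: RG_F, pre_subset: excitatory, post: RG_F, p_connect: 0.15,
     weight_mean: 4.0, weight_sd: 1.0, kinetics: exc}
  - {pre: RG_F, pre_subset: inhibitory, post: RG_F, p_connect: 0.20,
     weight_mean: 3.0, weight_sd: 0.75, kinetics: inh}
  - {pre: RG_E, pre_subset: excitatory, post: RG_E, p_connect: 0.15,
     weight_mean: 0.8, weight_sd: 0.2, kinetics: exc}
  - {pre: RG_E, pre_subset: inhibitory, post: RG_E, p_connect: 0.20,
     weight_mean: 3.0, weight_sd: 0.75, kinetics: inh}
  # mutual RG inhibition via relay populations
  - {pre: RG_F, pre_subset: excitatory, post: V2b, p_connect: 0.28,
     weight_mean: 5.0, weight_sd: 1.25, kinetics: exc}
  - {pre: V2b, post: RG_E, p_connect: 0.28,
     weight_mean: 5.0, weight_sd: 1.25, kinetics: inh}
  - {pre: RG_E, pre_subset: excitatory, post: V1RG, p_connect: 0.28,
     weight_mean: 3.5, weight_sd: 0.9, kinetics: exc}
  - {pre: V1RG, post: RG_F, p_connect: 0.28,
     weight_mean: 6.0, weight_sd: 1.5, kinetics: inh}
  # output chain
  - {pre: RG_F, pre_subset: excitatory, post: V2a_F, p_connect: 0.28,
     weight_mean: 3.0, weight_sd: 0.75, kinetics: exc}
  - {pre: RG_E, pre_subset: excitatory, post: V2a_E, p_connect: 0.28,
     weight_mean: 4.0, weight_sd: 1.0, kinetics: exc}
  - {pre: V2a_F, post: MNP_F, p_connect: 0.28,
     weight_mean: 1.7, weight_sd: 0.42, kinetics: exc}
  - {pre: V2a_E, post: MNP_E, p_connect: 0.28,
     weight_mean: 5.0, weight_sd: 1.25, kinetics: exc}
  # reciprocal Ia inhibition (Ia named after the MNP it inhibits)
  - {pre: RG_E, pre_subset: excitatory, post: Ia_F, p_connect: 0.28,
     weight_mean: 1.5, weight_sd: 0.4, kinetics: exc}
  - {pre: RG_F, pre_subset: excitatory, post: Ia_E, p_connect: 0.28,
     weight_mean: 1.5, weight_sd: 0.4, kinetics: exc}
  - {pre: Ia_F, post: MNP_F, p_connect: 0.28,
     weight_mean: 25.0, weight_sd: 6.0, kinetics: inh}
  - {pre: Ia_E, post: MNP_E, p_connect: 0.28,
     weight_mean: 0.8, weight_sd: 0.2, kinetics: inh}
  # recurrent (Renshaw) inhibition
  - {pre: MNP_F, post: RC_F, p_connect: 0.28,
     weight_mean: 4.0, weight_sd: 1.0, kinetics: exc}
  - {pre: MNP_E, post: RC_E, p_connect: 0.28,
     weight_mean: 4.0, weight_sd: 1.0, kinetics: exc}
  - {pre: RC_F, post: MNP_F, p_connect: 0.28,
     weight_mean: 7.5, weight_sd: 1.9, kinetics: inh}
  - {pre: RC_E, post: MNP_E, p_connect: 0.28,
     weight_mean: 0.7, weight_sd: 0.18, kinetics: inh}
  # cholinergic excitation of motoneurons
  - {pre: V0c_F, post: MNP_F, p_connect: 0.28,
     weight_mean: 2.6, weight_sd: 0.65, kinetics: exc}
  - {pre: V0c_E, post: MNP_E, p_connect: 0.28,
     weight_mean: 1.5, weight_sd: 0.4, kinetics: exc}
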