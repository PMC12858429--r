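# Disease-stage table: per-population cell survival fractions, the scale on
# V1-presynaptic connection probabilities, and the V0c->MNP weight
# multiplier. Editable; fractions are directionally faithful defaults
# (V1 populations affected earliest and deepest, motoneurons and V2a
# interneurons lost only late, cholinergic compensation late), not
# transcriptions of measured counts. Descending drives never change.
healthy: {}
P45:
  v1_projection_scale: 0.5
P63:
  v1_projection_scale: 0.5
  survival: {V1RG: 0.6, Ia_F: 0.55, Ia_E: 0.55, RC_F: 0.55, RC_E: 0.55}
P112:
  v1_projection_scale: 0.5
  survival: {V1RG: 0.5, Ia_F: 0.5, Ia_E: 0.5, RC_F: 0.5, RC_E: 0.5,
             V2a_F: 0.6, V2a_E: 0.6, MNP_F: 0.8, MNP_E: 0.8}
  v0c_weight_scale: 1.5
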