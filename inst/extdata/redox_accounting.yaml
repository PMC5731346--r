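# Per-reaction yields of reducing equivalents for the default TCA network.
# nadh / fadh2 / nadph are produced moles per mole of net flux; negative
# values denote consumption. IDH and reductive carboxylation are booked as
# NADPH (merged into the NADH total by default; see compute_redox_oxphos).
- reaction: PDH
  nadh: 1
- reaction: IDH
  nadph: 1
- reaction: AKGDH
  nadh: 1
- reaction: MDH
  nadh: 1
- reaction: SDH
  fadh2: 1
- reaction: RC
  nadph: -1
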