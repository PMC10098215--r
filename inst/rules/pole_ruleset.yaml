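# Default POLE interpretation ruleset.
# Calls are restricted to canonical exonuclease-domain hotspot protein changes
# with VAF >= 5% supported by reads on both strands, over exons 9-14.
pole_ruleset:
  version: 1
  whitelist:
    - P286R
    - V411L
    - S297F
    - S459F
    - F367S
    - L424I
    - M295R
    - P436R
    - M444K
    - D368Y
    - A456P
  covered_exons: [9, 10, 11, 12, 13, 14]
  vaf_min: 0.05
  require_both_strands: true
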