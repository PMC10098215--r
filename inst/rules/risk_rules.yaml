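# Versioned listing of the risk-stratification rule tables.
# Rules are evaluated in the order listed (advanced -> high ->
# high_intermediate -> intermediate -> low); the first match fires and its id
# is recorded as `fired_rule`. The executable predicates live in the package
# code under the same ids; this file is the inspectable reference.
version: 1
lvsi_semantics:
  esmo2016: "binary; focal or substantial LVSI counts as positive"
  esgo2020: "three-tier; only substantial LVSI is adverse"
esmo2016:
  - id: esmo2016/advanced
    class: advanced_metastatic
    when: "stage III with residual disease, or stage IVA/IVB"
  - id: esmo2016/high_stage_iii
    class: high
    when: "stage III without residual disease"
  - id: esmo2016/high_nonendometrioid
    class: high
    when: "non-endometrioid histotype (stage I-II reached here)"
  - id: esmo2016/high_stage_ii
    class: high
    when: "stage II"
  - id: esmo2016/high_g3_deep
    class: high
    when: "stage I endometrioid, high grade, invasion >= 50%"
  - id: esmo2016/hi_int_g3_superficial
    class: high_intermediate
    when: "stage I endometrioid, high grade, invasion < 50%, any LVSI"
  - id: esmo2016/hi_int_lvsi_positive
    class: high_intermediate
    when: "stage I endometrioid, low grade, LVSI positive (focal/substantial), any depth"
  - id: esmo2016/intermediate_deep
    class: intermediate
    when: "stage I endometrioid, low grade, invasion >= 50%, LVSI absent"
  - id: esmo2016/low
    class: low
    when: "stage I endometrioid, low grade, invasion < 50%, LVSI absent"
esgo2020_unknown:
  - id: esgo2020/advanced
    class: advanced_metastatic
    when: "stage III-IVA with residual disease, or stage IVB"
  - id: esgo2020/high_stage_iii_iva
    class: high
    when: "stage III-IVA without residual disease, any histotype/subgroup"
  - id: esgo2020/high_nonendo_invasive
    class: high
    when: >-
      stage I-II non-endometrioid with myometrial invasion (stage IB-II
      without recorded invasion classifies here too: grid closure for
      degenerate combinations)
  - id: esgo2020/hi_int_substantial_lvsi
    class: high_intermediate
    when: "stage I endometrioid with substantial LVSI, any grade/depth"
  - id: esgo2020/hi_int_ib_high_grade
    class: high_intermediate
    when: "stage IB endometrioid high grade, any LVSI"
  - id: esgo2020/hi_int_stage_ii
    class: high_intermediate
    when: "stage II"
  - id: esgo2020/int_ib_low_grade
    class: intermediate
    when: "stage IB endometrioid low grade, LVSI absent/focal"
  - id: esgo2020/int_ia_high_grade
    class: intermediate
    when: "stage IA endometrioid high grade, LVSI absent/focal"
  - id: esgo2020/int_ia_nonendo_noninvasive
    class: intermediate
    when: "stage IA non-endometrioid without myometrial invasion"
  - id: esgo2020/low
    class: low
    when: "stage IA endometrioid low grade, LVSI absent/focal"
esgo2020_known:
  note: >-
    Same table as esgo2020_unknown with molecular overrides inserted after
    the stage-III/IV rules; stage III/IV class is independent of subgroup.
  overrides:
    - id: esgo2020k/low_pole_early
      class: low
      when: "stage I-II POLE-mutant, no residual disease (includes high grade and stage II)"
    - id: esgo2020k/high_p53abn_invasive
      class: high
      when: >-
        stage I-II p53abn with myometrial invasion (stage IB-II p53abn without
        recorded invasion classifies here too: grid closure)
    - id: esgo2020k/int_p53abn_ia_noninvasive
      class: intermediate
      when: "stage IA p53abn without myometrial invasion"
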