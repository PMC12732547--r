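# Built-in scenario catalogue.
#
# Each group shares a model configuration; "sequences" expands into one
# scenario per emergence order (one character per stage locus).  Stage
# selection: "none" introduces the allele neutrally; "joint" gives it a
# positive viability regime whose fitness dominance equals the locus's
# configured functional dominance (selection coefficient 0.1).  The
# maternal-inhibitor stages are neutral throughout: positive selection on
# the inhibitor drives it to homozygosity, which forecloses the monogenic
# state (a single female dose class cannot split broods).

groups:
  - group: imprinting_fixed
    variant: two_factor
    loci: [e, s, r, g]
    imprinting_fixed: true
    scenarios:
      - name: 1A
        dominance: {s: dominant, r: dominant}
      - name: 1B
        dominance: {s: dominant, r: recessive}
      - name: 1C
        dominance: {s: recessive, r: dominant}
      - name: 1D
        dominance: {s: recessive, r: recessive}
    sequences: [esr, ers, ser, sre, res, rse]
    stage_defaults:
      e: {selection: none, carry_forward: true}
      s: {selection: joint, carry_forward: true}
      r: {selection: joint, carry_forward: true}

  # carried-selection variant: the elimination gene's recessive advantage
  # stays in force while the spermatogenesis gene spreads neutrally; the
  # intermediate stable state then shows the 1/0.9 sex ratio
  - group: carry_forward_variant
    variant: two_factor
    loci: [e, s, r, g]
    imprinting_fixed: true
    scenarios:
      - name: 1B_rs_carry
        dominance: {s: dominant, r: recessive}
    stages:
      - {locus: r, selection: joint}
      - {locus: s, selection: none, carry_forward: true}

  - group: non_imprinting
    variant: two_factor
    loci: [e, s, r]
    imprinting_fixed: false
    scenarios:
      - name: NI
        dominance: {s: recessive, r: recessive}
    sequences: [esr, ers, ser, sre, res, rse]
    stage_defaults:
      e: {selection: none, carry_forward: true}
      s: {selection: joint, carry_forward: true}
      r: {selection: joint, carry_forward: true}

  - group: acquisition
    variant: two_factor
    loci: [e, s, r, g]
    imprinting_fixed: false
    scenarios:
      - name: ACQ
        dominance: {s: recessive, r: recessive, g: recessive}
    sequences: [gsr, sgr, srg, grs, rgs, egs, esg]
    stage_defaults:
      e: {selection: none, carry_forward: true}
      g: {selection: none, carry_forward: true}
      s: {selection: joint, carry_forward: true}
      r: {selection: joint, carry_forward: true}

  # enhanced inhibitor: one dose inactivates two elimination doses; arises
  # by mutation of the standard inhibitor inside the monogenic state
  - group: estar
    variant: two_factor
    loci: [e, s, r, g]
    estar: true
    initial: monogenic
    scenarios:
      - name: ESTAR_dom
        dominance: {s: recessive, r: recessive}
    stages:
      - locus: e
        allele: "e*"
        replace: e
        selection: {dominance: dominant, mu: 0.1}

  - group: one_factor
    variant: one_factor
    loci: [e, s, g]
    imprinting_fixed: true
    scenarios:
      - name: OF
        dominance: {s: recessive}
    sequences: [es, se]
    stage_defaults:
      e: {selection: none, carry_forward: true}
      s: {selection: joint, carry_forward: true}
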