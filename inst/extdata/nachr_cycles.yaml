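# Mutant-cycle definitions over the bundled construct-summary table.
# Paired complementary-subunit mutations (e.g. gG182A/dG188A applied in both
# the gamma and delta subunits) are decomposed into their single-subunit
# constructs, so k counts individual perturbations. Cycles whose single-
# mutant EC50s were never published (the aS268P and gG182I/dG188I series)
# are not representable and are omitted.
cycles:
  - id: aE45A+aP272G
    wt: WT
    singles: [aE45A, aP272G]
    combined: aE45A+aP272G
  - id: aV46A+aI264A
    wt: WT
    singles: [aV46A, aI264A]
    combined: aV46A+aI264A
  - id: aV46A+aP265A
    wt: WT
    singles: [aV46A, aP265A]
    combined: aV46A+aP265A
  - id: aV46A+aP265G
    wt: WT
    singles: [aV46A, aP265G]
    combined: aV46A+aP265G
  - id: aV46A+aP272G
    wt: WT
    singles: [aV46A, aP272G]
    combined: aV46A+aP272G
  - id: aI264A+aP265G
    wt: WT
    singles: [aI264A, aP265G]
    combined: aI264A+aP265G
  - id: aI264A+aP272G
    wt: WT
    singles: [aI264A, aP272G]
    combined: aI264A+aP272G
  - id: aE45A+aV46A
    wt: WT
    singles: [aE45A, aV46A]
    combined: aE45A+aV46A
  - id: aE45A+aV46A+aP272G
    wt: WT
    singles: [aE45A, aV46A, aP272G]
    combined: aE45A+aV46A+aP272G
  - id: aV46A+aI264A+aP265G
    wt: WT
    singles: [aV46A, aI264A, aP265G]
    combined: aV46A+aI264A+aP265G
  - id: aV46A+aI264A+aP272G
    wt: WT
    singles: [aV46A, aI264A, aP272G]
    combined: aV46A+aI264A+aP272G
  - id: aS266A+gG182A/dG188A
    wt: WT
    singles: [aS266A, gG182A, dG188A]
    combined: aS266A+gG182A/dG188A
  - id: aS266A+gE183A/dE189A
    wt: WT
    singles: [aS266A, gE183A, dE189A]
    combined: aS266A+gE183A/dE189A
  - id: aT267A+gG182A/dG188A
    wt: WT
    singles: [aT267A, gG182A, dG188A]
    combined: aT267A+gG182A/dG188A
  - id: aT267A+gF221A/dF227A
    wt: WT
    singles: [aT267A, gF221A, dF227A]
    combined: aT267A+gF221A/dF227A
  - id: aS268A+gG182A/dG188A
    wt: WT
    singles: [aS268A, gG182A, dG188A]
    combined: aS268A+gG182A/dG188A
  - id: aS268A+gK218A/dK224A
    wt: WT
    singles: [aS268A, gK218A, dK224A]
    combined: aS268A+gK218A/dK224A
  - id: aS269A+gG182A/dG188A
    wt: WT
    singles: [aS269A, gG182A, dG188A]
    combined: aS269A+gG182A/dG188A
  - id: aS269A+gK218A/dK224A
    wt: WT
    singles: [aS269A, gK218A, dK224A]
    combined: aS269A+gK218A/dK224A
  - id: aS269A+gL220A/dL226A
    wt: WT
    singles: [aS269A, gL220A, dL226A]
    combined: aS269A+gL220A/dL226A
  - id: aS266A/aT267A+gG182A/dG188A
    wt: WT
    singles: [aS266A, aT267A, gG182A, dG188A]
    combined: aS266A/aT267A+gG182A/dG188A
  - id: aS266A/aT267A+gE183A/dE189A
    wt: WT
    singles: [aS266A, aT267A, gE183A, dE189A]
    combined: aS266A/aT267A+gE183A/dE189A
  - id: aS268A/aS269A+gG182A/dG188A
    wt: WT
    singles: [aS268A, aS269A, gG182A, dG188A]
    combined: aS268A/aS269A+gG182A/dG188A
  - id: aS268A/aS269A+gK218A/dK224A
    wt: WT
    singles: [aS268A, aS269A, gK218A, dK224A]
    combined: aS268A/aS269A+gK218A/dK224A
  - id: aSTSS-GGGG+gG182A
    wt: WT
    singles: [aSTSS-GGGG, gG182A]
    combined: aSTSS-GGGG+gG182A
  - id: aSTSS-GGGG+dG188A
    wt: WT
    singles: [aSTSS-GGGG, dG188A]
    combined: aSTSS-GGGG+dG188A
  - id: aSTSS-GGGG+gG182A/dG188A
    wt: WT
    singles: [aSTSS-GGGG, gG182A, dG188A]
    combined: aSTSS-GGGG+gG182A/dG188A
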