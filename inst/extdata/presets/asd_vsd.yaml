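# Combined atrial + ventricular septal defect scenario.
# Timing fields are fractions of the heartbeat period THB; relaxation onset
# tR is always tC + TC. All chamber rest volumes V0 are 0 mL.
name: asd_vsd
thb_s: 0.8
chambers:
  LA: {EA: 0.2273, EB: 0.209, V0: 0.0, tC_frac: 0.79, TC_frac: 0.11, TR_frac: 0.8}
  LV: {EA: 3.0391, EB: 0.10, V0: 0.0, tC_frac: 0.0, TC_frac: 0.35, TR_frac: 0.4}
  RA: {EA: 0.0429, EB: 0.0636, V0: 0.0, tC_frac: 0.8, TC_frac: 0.1, TR_frac: 0.7}
  RV: {EA: 0.6683, EB: 0.07, V0: 0.0, tC_frac: 0.0, TC_frac: 0.3, TR_frac: 0.4}
valves:
  Rmin: 0.0075
  Rmax: 75006.2
compartments:
  ARSYS:  {R: 0.588, C: 0.96, L: 5.0e-3}
  VENSYS: {R: 0.352, C: 60.0, L: 5.0e-4}
  ARPUL:  {R: 0.104, C: 5.0, L: 5.0e-4}
  VENPUL: {R: 0.0105, C: 16.0, L: 5.0e-4}
shunts:
  RASD: 0.0031
  RVSD: 0.038
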