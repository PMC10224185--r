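# Proton spin-system library for aqueous fecal extracts at pH ~7.4.
#
# Each entry: name, groups (chemical shift in ppm, number of equivalent
# protons), couplings (pair of group indices, J in Hz).  Entries with
# `reference: assigned` carry shifts/J as assigned in the 60 MHz fecal
# spectra; `reference: standard` entries are seeded from standard
# reference compilations (HMDB/BMRB-style values at neutral pH) and were
# not independently assigned at low field.
#
# TSP (chemical-shift and concentration reference, 9 equivalent protons)
# and formate are the internal standards.  Taurine and succinate are not
# part of the 19-metabolite low-field assignment panel but are retained
# because they shape the crowded 2.3-3.5 ppm region.

- name: acetate
  reference: assigned
  groups:
    - {shift_ppm: 1.92, n_protons: 3}          # CH3 singlet
- name: alanine
  reference: assigned
  groups:
    - {shift_ppm: 1.48, n_protons: 3}          # beta CH3, doublet
    - {shift_ppm: 3.78, n_protons: 1}          # alpha CH
  couplings:
    - {between: [1, 2], J_hz: 7.2}
- name: aspartate
  reference: standard
  groups:
    - {shift_ppm: 2.68, n_protons: 1}          # beta CH2 (AB of ABX)
    - {shift_ppm: 2.80, n_protons: 1}
    - {shift_ppm: 3.89, n_protons: 1}          # alpha CH
  couplings:
    - {between: [1, 2], J_hz: 17.4}
    - {between: [1, 3], J_hz: 8.8}
    - {between: [2, 3], J_hz: 3.7}
- name: butyrate
  reference: assigned
  groups:
    - {shift_ppm: 0.90, n_protons: 3}          # terminal CH3, triplet
    - {shift_ppm: 1.56, n_protons: 2}          # middle CH2
    - {shift_ppm: 2.16, n_protons: 2}          # alpha CH2
  couplings:
    - {between: [1, 2], J_hz: 7.4}
    - {between: [2, 3], J_hz: 7.3}
- name: creatine
  reference: standard
  groups:
    - {shift_ppm: 3.03, n_protons: 3}          # N-CH3 singlet
    - {shift_ppm: 3.93, n_protons: 2}          # CH2 singlet
- name: formate
  reference: assigned
  groups:
    - {shift_ppm: 8.44, n_protons: 1}          # CH singlet (internal standard, 1 mM)
- name: glucose
  reference: assigned                          # 3.22/3.38/3.46 assigned; rest standard
  groups:
    - {shift_ppm: 3.22, n_protons: 1}          # H2 (beta)
    - {shift_ppm: 3.38, n_protons: 1}          # H4
    - {shift_ppm: 3.46, n_protons: 1}          # H3/H5
    - {shift_ppm: 3.72, n_protons: 1}          # H6
    - {shift_ppm: 3.84, n_protons: 1}          # H6'
    - {shift_ppm: 4.64, n_protons: 1}          # H1 beta anomer
  couplings:
    - {between: [1, 6], J_hz: 7.9}
    - {between: [1, 3], J_hz: 9.4}
    - {between: [2, 3], J_hz: 9.1}
    - {between: [4, 5], J_hz: 12.3}
- name: glutamate
  reference: standard
  groups:
    - {shift_ppm: 2.08, n_protons: 2}          # beta CH2
    - {shift_ppm: 2.34, n_protons: 2}          # gamma CH2
    - {shift_ppm: 3.75, n_protons: 1}          # alpha CH
  couplings:
    - {between: [1, 2], J_hz: 7.5}
    - {between: [1, 3], J_hz: 6.5}
- name: glycerol
  reference: standard
  groups:
    - {shift_ppm: 3.56, n_protons: 2}          # CH2 (pro-R/pro-S collapsed)
    - {shift_ppm: 3.64, n_protons: 2}
    - {shift_ppm: 3.78, n_protons: 1}          # CH
  couplings:
    - {between: [1, 3], J_hz: 6.5}
    - {between: [2, 3], J_hz: 4.4}
- name: glycine
  reference: standard
  groups:
    - {shift_ppm: 3.56, n_protons: 2}          # CH2 singlet
- name: isoleucine
  reference: assigned                          # 1.00 ppm / 7.05 Hz assigned
  groups:
    - {shift_ppm: 1.00, n_protons: 3}          # delta CH3, doublet (J 7.05)
    - {shift_ppm: 0.93, n_protons: 3}          # gamma' CH3, triplet
    - {shift_ppm: 1.35, n_protons: 2}          # gamma CH2
    - {shift_ppm: 1.97, n_protons: 1}          # beta CH
    - {shift_ppm: 3.67, n_protons: 1}          # alpha CH
  couplings:
    - {between: [1, 4], J_hz: 7.05}
    - {between: [2, 3], J_hz: 7.4}
    - {between: [4, 5], J_hz: 3.9}
- name: leucine
  reference: standard
  groups:
    - {shift_ppm: 0.95, n_protons: 6}          # delta CH3 x2 (collapsed)
    - {shift_ppm: 1.70, n_protons: 3}          # beta CH2 + gamma CH
    - {shift_ppm: 3.72, n_protons: 1}          # alpha CH
  couplings:
    - {between: [1, 2], J_hz: 6.3}
    - {between: [2, 3], J_hz: 7.0}
- name: lactate
  reference: standard
  groups:
    - {shift_ppm: 1.33, n_protons: 3}          # CH3 doublet
    - {shift_ppm: 4.11, n_protons: 1}          # CH quartet
  couplings:
    - {between: [1, 2], J_hz: 6.9}
- name: methionine
  reference: standard
  groups:
    - {shift_ppm: 2.13, n_protons: 3}          # S-CH3 singlet
    - {shift_ppm: 2.16, n_protons: 2}          # beta CH2
    - {shift_ppm: 2.64, n_protons: 2}          # gamma CH2
    - {shift_ppm: 3.86, n_protons: 1}          # alpha CH
  couplings:
    - {between: [2, 3], J_hz: 7.6}
    - {between: [2, 4], J_hz: 6.2}
- name: phenylalanine
  reference: standard
  groups:
    - {shift_ppm: 7.32, n_protons: 2}          # ortho
    - {shift_ppm: 7.42, n_protons: 3}          # meta + para
    - {shift_ppm: 3.98, n_protons: 1}          # alpha CH
    - {shift_ppm: 3.19, n_protons: 2}          # beta CH2
  couplings:
    - {between: [1, 2], J_hz: 7.5}
    - {between: [3, 4], J_hz: 6.0}
- name: propionate
  reference: assigned                          # 1.05 ppm / 7.70 Hz assigned
  groups:
    - {shift_ppm: 1.05, n_protons: 3}          # CH3 triplet (J 7.70)
    - {shift_ppm: 2.18, n_protons: 2}          # CH2 quartet
  couplings:
    - {between: [1, 2], J_hz: 7.70}
- name: threonine
  reference: standard
  groups:
    - {shift_ppm: 1.32, n_protons: 3}          # gamma CH3 doublet
    - {shift_ppm: 4.25, n_protons: 1}          # beta CH
    - {shift_ppm: 3.58, n_protons: 1}          # alpha CH
  couplings:
    - {between: [1, 2], J_hz: 6.6}
    - {between: [2, 3], J_hz: 4.9}
- name: tyrosine
  reference: assigned                          # 6.95 multiplet assigned
  groups:
    - {shift_ppm: 6.95, n_protons: 2}          # 3,5 ring protons
    - {shift_ppm: 7.19, n_protons: 2}          # 2,6 ring protons
    - {shift_ppm: 3.93, n_protons: 1}          # alpha CH
    - {shift_ppm: 3.11, n_protons: 2}          # beta CH2
  couplings:
    - {between: [1, 2], J_hz: 8.5}
    - {between: [3, 4], J_hz: 6.5}
- name: valine
  reference: assigned                          # 1.03 ppm / 7.05 Hz assigned
  groups:
    - {shift_ppm: 1.03, n_protons: 3}          # gamma CH3, doublet (J 7.05)
    - {shift_ppm: 0.98, n_protons: 3}          # gamma' CH3, doublet
    - {shift_ppm: 2.26, n_protons: 1}          # beta CH
    - {shift_ppm: 3.60, n_protons: 1}          # alpha CH
  couplings:
    - {between: [1, 3], J_hz: 7.05}
    - {between: [2, 3], J_hz: 7.0}
    - {between: [3, 4], J_hz: 4.4}
- name: succinate
  reference: standard                          # not in the low-field panel
  groups:
    - {shift_ppm: 2.38, n_protons: 4}          # CH2 x2 singlet
- name: taurine
  reference: standard                          # not isolable at 60 MHz
  groups:
    - {shift_ppm: 3.26, n_protons: 2}          # S-CH2 triplet
    - {shift_ppm: 3.42, n_protons: 2}          # N-CH2 triplet
  couplings:
    - {between: [1, 2], J_hz: 6.6}
- name: TSP
  reference: assigned
  groups:
    - {shift_ppm: 0.00, n_protons: 9}          # (CH3)3Si singlet; 0.0 ppm reference, 0.5 mM
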