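# Default synthetic-cohort design: two groups (control, DSS) x 3 subjects
# x days 0-5, sampled at 60 and 800 MHz.
#
# Baseline concentrations (mM in the measured extract) are plausible
# values for aqueous mouse fecal extracts, with the short-chain fatty
# acids dominant.  Day-5 fold changes encode the colitis direction of
# each metabolite (treated/control); magnitudes are synthetic free
# parameters -- chosen so the treated group separates from day 3 on --
# since the underlying study reports directions, not fold changes.
# Internal standards: TSP 0.5 mM (also the 0 ppm reference) and a 1 mM
# formate spike added to the biological formate background.
#
# noise_snr: peak signal-to-noise ratio of the strongest line of the
# mean control profile (frequency-domain, 128-scan-equivalent quality).

n_per_group: 3
days: [0, 1, 2, 3, 4, 5]
cv_biological: 0.20
onset_day: 2
noise_snr: 300
tsp_mM: 0.5
formate_spike_mM: 1.0

baseline_mM:
  acetate: 8.0
  alanine: 1.5
  aspartate: 0.8
  butyrate: 3.0
  creatine: 0.5
  formate: 0.3
  glucose: 2.0
  glutamate: 2.0
  glycerol: 1.0
  glycine: 1.0
  isoleucine: 0.6
  leucine: 1.0
  lactate: 1.5
  methionine: 0.3
  phenylalanine: 0.4
  propionate: 3.0
  threonine: 0.8
  tyrosine: 0.4
  valine: 0.8
  succinate: 1.0
  taurine: 1.0

fold_day5:
  acetate: 2.0
  succinate: 1.8
  glucose: 1.3
  taurine: 1.3
  butyrate: 0.5
  propionate: 0.7
  isoleucine: 0.7
  valine: 0.7
  leucine: 0.7
  alanine: 0.7
  aspartate: 0.7
  glycerol: 0.7
  threonine: 0.7
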