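# Fork-travel kinetics inputs for the overexpressed CCSER1 allele
# (beta-actin promoter insertion), DT40 cells. Two-sided analysis:
# rightward forks from the 5' initiation zone, leftward forks from the 3'
# zone, 621 kb apart.
doubling_time_min: 744
s_percent: 62.5
locus_length_kb: 621
right:
  velocity_kb_min: 1.9          # median velocity of rightward forks, 5' IZ
  timing_quarters: [26.3, 53.2, 17.6, 2.9]
  timing_unit: percent
left:
  velocity_kb_min: 1.8          # median velocity of leftward forks, 3' IZ
  timing_quarters: [5.7, 20.1, 41.0, 33.2]
  timing_unit: percent
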