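# Fork-travel kinetics inputs for the transcriptionally active DMD allele
# (Tet-promoter insertion), DT40 cells. One-sided analysis: rightward forks
# emanating from the efficient 5' initiation zone.
doubling_time_min: 552
s_percent: 69.4
right:
  velocity_kb_min: 2.1          # median velocity of rightward forks, 5' IZ
  timing_quarters: [2.2, 6.2, 26.2, 65.4]
  timing_unit: percent          # % of forks starting in S1..S4
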