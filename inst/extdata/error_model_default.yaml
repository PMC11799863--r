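# Default execution-error model: per-ligament, per-technique quartile
# summaries (median, Q1, Q3) of angular deviation (degrees) and entry-point
# distance (mm), from the published cadaveric PSI-vs-freehand comparison
# (per-ligament accuracy tables).  Magnitudes are drawn from log-normal
# distributions calibrated to these quartiles.
family: lognormal
groups:
  freehand:
    LCL:
      angular: [17.4, 12.7, 23.8]
      entry: [2.5, 2.2, 5.9]
    PT:
      angular: [20.7, 16.5, 25.2]
      entry: [4.9, 2.5, 5.4]
    MCL:
      angular: [23.8, 17.8, 25.8]
      entry: [6.6, 3.5, 9.0]
    POL:
      angular: [24.7, 21.6, 27.8]
      entry: [10.7, 7.2, 11.3]
  psi:
    LCL:
      angular: [5.7, 3.3, 6.6]
      entry: [4.4, 3.5, 6.3]
    PT:
      angular: [4.4, 2.6, 8.3]
      entry: [5.6, 4.1, 6.8]
    MCL:
      angular: [7.5, 5.4, 8.7]
      entry: [3.8, 3.5, 5.0]
    POL:
      angular: [4.8, 3.2, 10.3]
      entry: [3.9, 3.3, 5.1]
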