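# Linear coefficients of the three-mechanism TBP affinity model.
# These are data, not code. Provenance "calibrated" means they were fitted
# once by calibrateCoefficients(): iterated least squares of the four linear
# coefficients against the -ln KD values of the packaged marker table, on
# flank-context sequences padded to the window length. Re-running
# calibrateCoefficients() on the packaged data reproduces this file.
provenance: calibrated
calibration: >
  Iterated least-squares fit to the 64 allele -ln KD values of the packaged
  marker table (flank contexts centre-padded with 'c' to 26 bp); jackknife
  sd scale set so the IL1B worked-example contexts give ~0.095 ln-units.
intercept: 29.5434760858
weight_slide: 1.95281133957
weight_pwm: 0.0811093865176
weight_bend: -0.0664228754125
sd_model:
  method: jackknife
  scale: 0.0483578236238
window_length: 26
scan_region: [-70, -20]
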