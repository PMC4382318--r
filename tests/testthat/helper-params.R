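# The worked reference scenario used throughout the documentation:
# alpha = 0.05, mu = 75, ICC = 0.006, BCV = 0.1, C80 = 60 (Delta ~ 0.417).
example_params <- function() {
  crt_params(alpha = 0.05, beta = 0.2, mu = 75, icc = 0.006, bcv = 0.1,
             c80 = 60)
}

# A small, cheap scenario for property-style tests.
small_params <- function() {
  crt_params(alpha = 0.05, beta = 0.2, mu = 20, icc = 0.05, bcv = 0.1,
             c80 = 10)
}
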