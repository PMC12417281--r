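# Population AIF functional forms. Times in minutes since bolus arrival.
#
# parker-mixed: two Gaussian bolus passes plus an exponentially decaying
# sigmoid washout (Parker et al., MRM 2006 population average). Describes
# whole-blood concentration; converted to plasma via (1 - hct).
#   A1, A2      : Gaussian areas, mM * min
#   T1, T2      : Gaussian centres, min
#   sigma1/2    : Gaussian widths, min
#   alpha       : sigmoid amplitude, mM
#   beta        : washout decay, 1/min
#   s           : sigmoid steepness, 1/min
#   tau         : sigmoid centre, min
#
# biexponential: classic two-compartment plasma washout (Weinmann-type) with
# a fast bolus ramp; amplitudes already in plasma mM for a standard dose.
#   A1, A2      : amplitudes, mM
#   m1, m2      : decay rates, 1/min
#   m0          : bolus ramp rate, 1/min
parker-mixed:
  coefficients:
    A1: 0.809
    A2: 0.330
    T1: 0.17046
    T2: 0.365
    sigma1: 0.0563
    sigma2: 0.132
    alpha: 1.050
    beta: 0.1685
    s: 38.078
    tau: 0.483
# Weinmann population coefficients at a 0.1 mmol/kg dose.
biexponential:
  coefficients:
    A1: 0.399
    A2: 0.478
    m1: 0.144
    m2: 0.0111
    m0: 25.0
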