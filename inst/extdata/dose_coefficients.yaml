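# Absorbed-dose coefficients for I-131 blood dosimetry, as tabulated in the
# EANM standard operating procedure on pre-therapeutic blood and bone marrow
# dosimetry in differentiated thyroid cancer therapy.
#   dk_beta : Gy mL GBq^-1 h^-1 (blood self-irradiation)
#   dk_gamma: Gy kg^(2/3) GBq^-1 h^-1 (whole-body photon cross-fire)
#   l_phys  : h^-1 (physical decay constant, ln 2 / 8.02 d)
dk_beta: 108.0
dk_gamma: 0.0188
l_phys: 0.00360
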