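# Homogeneous tissue optical properties used by the analytic diffusion
# sensitivity engine: absorption (mua) and reduced scattering (musp)
# coefficients in mm^-1, literature-typical infant head values.
wavelength_nm,mua_mm,musp_mm
780,0.0170,0.95
850,0.0190,0.84
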