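# Molar extinction coefficients of oxy- and deoxy-haemoglobin,
# base-10, cm^-1 / (mol/L). Values from the standard tabulated
# compilation of haemoglobin absorption spectra (Prahl/Cope lineage)
# at the two acquisition wavelengths.
wavelength_nm,eps_hbo,eps_hbr
780,710.0,1075.44
850,1058.0,691.32
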