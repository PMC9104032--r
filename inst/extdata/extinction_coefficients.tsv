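# Base-10 molar extinction coefficients of human hemoglobin, cm^-1 M^-1.
# Compiled tabulation by S. Prahl (Oregon Medical Laser Center), based on
# the data of W. B. Gratzer and N. Kollias; values at the two measurement
# wavelengths of the pipeline. Override with any nonsingular table via
# optics_constants(path = ...).
wavelength_nm	hbo	hbr
760	586	1548.52
850	1058	691.32
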