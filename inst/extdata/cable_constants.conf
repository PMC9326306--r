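# Passive dendritic cable constants used by the attenuation transfer
# function.  Units: membrane_resistivity in Ohm cm^2, axial_resistivity
# in Ohm cm.
membrane_resistivity = 20000
axial_resistivity = 150
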