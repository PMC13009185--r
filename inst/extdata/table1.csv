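specimen_id,habitat,native_d13c,native_d15n,incubated_d13c,incubated_d15n
SO215-D,active,-24.86,9.54,-26.84,10.37
SO215-E,active,-28.9,7.2,-27.35,7.91
SO215-F,active,-28.14,8.67,34.1,10.2
SO215-T1,transition,-22.14,10.73,-23.59,10.29
SO215-T2,transition,-22.21,10.58,-24.86,10.72
SO215-T3,transition,-21.78,11.02,-23.74,10.66
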