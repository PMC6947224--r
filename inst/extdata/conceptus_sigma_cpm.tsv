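sample_id	sigma_cpm
E1-25DA-M	486.84
E2-25DA-M	553.53
E3-25DC-M	573.09
E4-25DC-M	562.53
E5-25DC-M	495.23
E6-25DC-M	539.97
E7-25DC-M	560.64
F1-35DC-M	483.04
F2-35DC-M	468.13
F3-35DC-M	476.91
F4-35DA-M	427.29
F5-35DA-M	482.53
F6-35DA-M	467.04
F7-35DA-M	476.06
F8-35DC-M	523.77
F9-35DA-M	437.24
F10-35DA-M	470.60
E1-25DA-F	0.14
E2-25DA-F	0.14
E3-25DC-F	0.14
E4-25DC-F	0.49
E5-25DC-F	0.37
E6-25DC-F	0.21
E7-25DC-F	0.23
E8-25DC-F	0.00
E9-25DC-F	0.14
E10-25DC-F	0.24
E11-25DA-F	0.60
F1-35DA-F	0.24
F2-35DA-F	0.39
F3-35DA-F	0.57
F4-35DC-F	0.07
F5-35DA-F	1.75
F6-35DA-F	1.01
F7-35DA-F	0.07
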